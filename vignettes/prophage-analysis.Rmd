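---
title: "Comparative prophage genomics and virome quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative prophage genomics and virome quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`prophagetools` implements a complete computational workflow for studying
temperate phages of gut bacteria:

1. **Comparative genomics** — pairwise proteome sharing and whole-genome
   nucleotide identity, clustered into species and genera;
2. **Diversity-generating retroelement (DGR) detection** — template/variable
   repeat (TR/VR) pairs with adenine-polarized mismatches targeting the 3'
   end of genes;
3. **Sequence evidence of prophage activity** — attL/attR direct repeats,
   variable packaging flanks, coverage enrichment, VR read
   hypervariability;
4. **Virome quantification** — read alignment, hit filtering, 50-kb
   normalization, windowed coverage with spurious-pile-up correction, and
   contamination-controlled presence calls;
5. **Cohort statistics** — healthy-versus-IBD prevalence (two-proportion
   z-tests) and abundance (binomial mixed-effect logistic regression);
6. **Synthetic data** — generators for every input, with ground truth.

## Species and genus demarcation

Phages are grouped by two standard taxonomic relations:

* **Species**: nucleotide identity above 95% — computed here over aligned
  regions (maximal exact matches of at least 11 nt, chained colinearly,
  inter-anchor gaps aligned globally), with a companion requirement that
  at least 80% of the shorter genome aligns. The aligned-fraction gate
  exists because identity-over-aligned-regions alone would call two
  genomes sharing one conserved module "the same species". Gaps longer
  than 30 bp are kept only if their own alignment reaches 70% identity:
  chance anchors in biased-composition sequence must not stitch unrelated
  segments into the aligned fraction.
* **Genus**: at least 40% of proteins shared. For each protein of genome A
  its best Smith–Waterman hit (BLOSUM62, affine gaps 11/1) in genome B
  counts as shared when its Karlin–Altschul E-value is at most 1e-3; the
  shared fraction divides by the smaller proteome. The count is
  unidirectional (best hit per query, no reciprocity); clustering uses the
  maximum of the two directions and single linkage, the weakest assumption
  consistent with reporting connected groups.

Both clusterings are single linkage over the threshold relation, so
raising a threshold can only split, never merge, clusters. Genomes of the
same species are forced into the same genus.

Alignment is done in-process with `Biostrings::pairwiseAlignment`
(Smith–Waterman in C) behind a seam that would equally accept an external
aligner; E-values use the standard gapped BLOSUM62 parameters
(lambda 0.267, K 0.041) with the query length times the subject proteome
size as search space. Candidate protein pairs are pre-screened by at least
two shared amino-acid 4-mers, after dropping 4-mers present in a large
fraction of a proteome (compositional bias carries no homology signal).

## ORF calling

`predict_orfs()` is a deliberate, fully specified six-frame caller:
stop-to-stop segments under the bacterial genetic code (table 11), opened
at the leftmost ATG/GTG/TTG, one ORF per stop and frame, minimum 30 aa.
It makes no coding-potential judgement, so its output on real genomes is
somewhat larger than a curated annotation; every quantity built on it
(proteome sizes, shared fractions) uses the same caller on both sides, so
ratios remain meaningful. Exact ORF counts are explicitly not a result of
interest.

## DGR detection

A DGR cassette is called from sequence alone, in three steps:

1. **Candidate repeats** (`find_repeat_pairs`): within-genome repeat pairs
   of 80–150 bp at 75% or more identity, discovered by shared 14-mer
   anchoring — mismatches in a real TR/VR pair sit only at a subset of
   template adenines, so long exact anchors always exist — and extended
   without gaps under a generous X-drop (match +1, mismatch −2, drop 12)
   so clustered internal mismatches do not truncate the repeat. Cassette
   calling evaluates the raw maximal span first and falls back to a
   boundary-polished span (ends required to open with clean matches,
   over-length spans shaved back through their outermost mismatches):
   raw-first preserves genuine edge polymorphisms, the polished fallback
   rescues spans whose chance boundary overshoot would otherwise dilute
   the adenine fraction or overrun the length gate. A few bases of
   boundary jitter remain inherent to any maximal-span detector.
2. **Orientation** (`classify_tr_vr`): of the four hypotheses (either copy
   as template, read on either strand), the one maximizing the fraction of
   mismatched columns whose putative-template base is adenine wins, and is
   accepted when that fraction reaches 0.8 — the operational reading of
   mismatches lying "almost exclusively" at template adenines. Invariant
   repeats and ties are rejected.
3. **Target gene** (`locate_target`): the variable copy must overlap the
   strand-aware 3'-terminal third of an ORF by at least half its length.

Accepted cassettes must be 100–135 bp, the canonical length range for
this element family. No reverse-transcriptase annotation is required for
a call: the repeat signature suffices, and RT presence can be carried as
metadata. Planted-cassette simulations put sensitivity above 95% with no
false calls on cassette-free genomes.

## Virome quantification

Reads (~250 bp) are aligned to every phage reference by seed-and-extend
(shared 12-mers define a diagonal band, polished by local alignment with
match +2 / mismatch −3); hits are retained when the E-value is below 1e-9
and identity strictly above 75%. One read may count for several phages —
quantities are per-phage proportions. Retained counts are normalized by
genome length to a 50-kb reference so proportions are comparable across
phages; the normalized count divided by total reads is the reported
frequency.

Coverage is tallied in non-overlapping 500-bp windows (tiled from
position 0, hit midpoints decide membership). Two defenses target
spurious pile-ups from conserved regions shared with unrelated phages:

* samples whose hits cover fewer than 3 windows are **excluded**;
* when the mean of non-zero windows exceeds 10 times their median, window
  counts above 10x the median are capped at that value (idempotent, never
  increases a count).

A sample is **phage-positive** when the phage's raw hit count is
significantly higher than the summed hit count of two 50-kb bacterial
control regions in the same sample (one-tailed two-proportion z-test,
p < 0.05). Summing the controls implements the "maximal theoretical
contamination" reading and is conservative: a phage exactly at the
per-region contamination level is essentially never called. The test uses
raw counts — rescaled counts would invalidate the binomial variance —
while normalization affects only reported abundances.

## Cohort statistics

Phages positive in fewer than 3% of samples (excluded samples count in
the denominator) are dropped. Prevalence is compared across cohorts with
a two-tailed two-proportion z-test. Abundance, on phage-positive samples
only, is modeled as binomial counts (hits out of total reads) with a
cohort-status fixed effect and a per-patient random intercept
(`lme4::glmer`, Laplace approximation); with one sample per patient the
model reduces to — and is fitted as — ordinary logistic regression. No
multiple-testing correction is applied by default, matching per-phage
reporting; Benjamini–Hochberg is available. Broad-host-range phages whose
host link is unclear are handled by an exclusion list, not hard-coded.

Parameter recovery simulations (status log-odds 1.0, patient SD 0.5, 40
patients per group with 2–3 samples each, 200 replicates) recover the
planted effect within ±0.15, and the degenerate design matches plain
logistic coefficients to 1e-4.

## The synthetic-data model

All validation rests on generated data with known truth, so the
generator's realism matters in specific ways:

* **Gene architecture**: genomes alternate protein-coding genes
  (200–1500 nt) with 20–100 nt stop-dense spacers; all genes are emitted
  co-oriented, as is typical of phage genomes.
* **Reading-frame punctuation**: genes use AT-rich codon choices with a
  structured dipeptide every five residues, drawn from large codon-pair
  families that each place a stop codon in one of the five non-coding
  frames. Real low-GC genomes keep their non-coding frames closed in just
  this statistical sense; without it a six-frame ORF caller drowns real
  genes in open frames. Mutation operators re-draw punctuation dipeptides
  from their own family, so derived genomes keep the property.
* **Genus structure**: members of a genus share a mutated core gene
  repertoire plus member-specific genes; the core fraction is calibrated
  against the package's own `shared_proteins()` measurement until the
  realized sharing hits the requested target (the generator's contract is
  stated in realized, not nominal, terms).
* **Substitution-only errors**: the identity filter at 75% is
  substitution-dominated; indels are available as an option but off by
  default.
* **Cohort**: per-patient intercepts drawn once, per-sample frequencies
  from the logistic model, presence planted per-group, binomial counts
  against the total read count. Default shape (21 + 52 patients, 2–3
  samples each) mirrors a realistic IBD case-control virome cohort.

### The 18-genome panel

`synthetic_prophage_panel()` instantiates the study conditions of a real
prophage collection: 18 genomes in 8 genera with sizes 1/1/6/2/2/4/1/1
and reported genome lengths (31–62 kb); 10 genomes carry one planted DGR
cassette (TR 105–130 bp, 10 randomized adenine sites drawn from the
repeat interior and spread over at least half of it — a mismatch cluster
flush against the boundary would be indistinguishable from sequence
beyond the repeat and unrecoverable by construction); one cross-genus
pair is calibrated to a realized shared-proteome fraction near 26% with
mean amino-acid identity near 39%; and one within-genus pair is built as
a colinear 4%-mutated prefix covering 78% of the genome plus a novel
tail, measuring ~96% identity over ~78% of its length. The panel is a
pure function of its seed.

Two intentional choices deserve note. First, the close pair's aligned
fraction targets 78% rather than 80%: at exactly 80% the species rule
(>95% identity over >=80%) would merge the pair, while the panel must
remain 18 distinct species; 78% keeps both properties and stays within
the tolerance used in validation. Second, the panel plants cassettes in
10 genomes, matching the reported census of 10 DGR-positive phages out
of 18.

What passing tests on this panel shows: the pipeline recovers clusters,
weak homology levels, near-identity structure and planted cassettes at
the stated rates from sequence alone. What it does not show: robustness
to real-genome features the generator does not emulate — mosaicism
gradients, repeated elements, annotation-grade gene calls, indel-rich
divergence, or host-range effects.

## Numerical choices and problem sizes

* Anchor chaining uses a weighted longest-increasing-subsequence DP over
  at most 600 anchors (longest kept); k-mers occurring more than 64 times
  are dropped from seeding tables.
* Genomes sharing less than 2% of the shorter genome in exact matches
  skip chaining entirely; their aligned fraction is the anchor total.
* Validation problem sizes (chosen so the full suite runs comfortably on
  one CPU): 10-kb genomes for cassette simulations (100 replicates),
  count-level Monte Carlo with 300–500 samples for presence-call
  calibration, 200 mixed-model replicates, virome samples of 300–1500
  reads for end-to-end alignment checks.
* Ties in best-hit selection fall to the first subject in input order;
  genus/species numbering is by lexicographically smallest member, so
  partitions are invariant under input permutation.
* Degenerate inputs are first-class: empty FASTA records, N-only genomes,
  zero-read samples, all-zero coverage vectors and single-status cohorts
  all have defined, tested behavior.

## Known limitations

* The z-test compares raw counts of a phage (genome length 31–62 kb)
  against pooled 50-kb controls without length adjustment; for much
  longer phages this is anti-conservative, for shorter ones conservative.
  The pooled-control convention itself doubles the contamination
  baseline, which is deliberate.
* Whether a read hitting two phages should be assigned uniquely is an
  open question of the underlying protocol; per-phage counting is
  implemented and documented.
* The in-process read aligner is a faithful but simple seed-and-extend;
  it is not tuned for speed on million-read samples. Count-level
  simulation covers the statistical calibration at those scales.
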