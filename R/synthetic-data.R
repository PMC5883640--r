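# Synthetic-data generators with known ground truth: phage genomes with
# gene/spacer architecture, genera with controllable shared-protein
# fractions, planted DGR cassettes, hosts with integrated prophages, virome
# read sets and healthy/IBD cohorts.
#
# The sequence composition model is deliberately structured: genes are
# emitted with AT-rich codon usage and regular "punctuation" dipeptides
# whose codons place stop codons in the five non-coding frames, and
# intergenic spacers are stop-dense. This mimics the reading-frame
# punctuation of real low-GC phage genomes, so that a six-frame ORF caller
# produces annotation-scale proteome sizes instead of drowning the real
# genes in open non-coding frames.

syn_cache <- new.env(parent = emptyenv())

codon_model <- function() {
  if (!is.null(syn_cache$model)) return(syn_cache$model)
  gc11 <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(gc11), gc11)
  by_aa[["*"]] <- NULL
  w <- lapply(by_aa, function(cs) {
    ww <- vapply(cs, function(codon) {
      2^sum(strsplit(codon, "")[[1]] %in% c("A", "T"))
    }, numeric(1))
    ww / sum(ww)
  })
  grid <- function(a, b) as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
  # dipeptide families guaranteed to place a stop codon in one off-frame
  fam <- list(
    fwd1 = grid(c("TTA", "CTA", "ATA", "GTA", "CTG", "TTG", "GTG"),
                c("AAA", "AAG", "AAT", "AAC", "ACA", "ACT", "AGA", "AGG",
                  "AGC", "AGT", "ATT", "ATC", "ATA")),
    fwd2 = grid(c("ATT", "AAT", "GAT", "TAT", "TGT", "TCT", "TTT", "CTT",
                  "GTT", "GCT", "ACT", "CCT", "GGT", "CAT", "CGT", "AGT"),
                c("AAA", "AAG", "AAT", "AAC", "AGA", "AGG", "AGC", "AGT",
                  "GAA", "GAG", "GAT", "GAC")),
    rc0  = grid(c("TTA", "CTA", "TCA"),
                c("AAA", "GAA", "GCA", "ATT", "GGA", "TGT", "CCA", "TAT",
                  "AAT", "GAT")),
    rc1  = grid(c("ATT", "GTT", "TTT", "CTT", "GCT", "ACT", "TCT", "CCT",
                  "ACC", "GCC", "TCC", "ATC", "GTC", "TTC", "CTC"),
                c("AAA", "AAG", "AAT", "AAC", "ACA", "AGA", "ATT", "ATG",
                  "ATC")),
    rc2  = grid(c("ATT", "AAT", "GAT", "TAT", "TCT", "TTT", "CTT", "GTT",
                  "GCT", "ACT", "CCT", "GGT", "CAT"),
                c("TAT", "TAC", "CAA", "CAG", "CAT", "CAC"))
  )
  # keep only rc1 pairs whose first codon really ends in TT/CT/TC
  fam$rc1 <- fam$rc1[substr(fam$rc1[, 1], 2, 3) %in% c("TT", "CT", "TC"), ]
  aa_of <- function(codon) unname(gc11[codon])
  model <- list(by_aa = by_aa, w = w, fam = fam, aa_of = aa_of,
                aa_names = names(by_aa))
  syn_cache$model <- model
  model
}

random_codon <- function(model) {
  a <- sample(model$aa_names, 1L)
  sample(model$by_aa[[a]], 1L, prob = model$w[[a]])
}

# gene body as a codon vector (no start/stop), punctuated every 5 residues
gene_codons <- function(n_aa, model = codon_model()) {
  frames <- c("fwd1", "fwd2", "rc0", "rc1", "rc2")
  out <- character(0)
  i <- 1L; slot <- 0L
  while (i <= n_aa) {
    if (i %% 5L == 1L && i <= n_aa - 1L) {
      slot <- slot %% 5L + 1L
      g <- model$fam[[frames[slot]]]
      r <- g[sample(nrow(g), 1L), ]
      out <- c(out, r[[1]], r[[2]]); i <- i + 2L
    } else {
      out <- c(out, random_codon(model)); i <- i + 1L
    }
  }
  out
}

random_gene_dna <- function(n_aa, model = codon_model()) {
  paste0("ATG", paste(gene_codons(n_aa - 1L, model), collapse = ""), "TAA")
}

random_spacer <- function(n) {
  units <- c("TTAA", "TAAT", "ATTA", "TTA", "TAA", "TGA", "AATT", "CTA",
             "TCA", "GTAA", "TAGT")
  s <- paste(sample(units, ceiling(n / 3) + 1L, TRUE), collapse = "")
  substr(s, 1L, n)
}

# assemble genes (+ spacers) into a genome sequence; genes is a character
# vector of gene DNA. Returns list(sequence, gene_starts (0-based), gene_ends)
assemble_genome <- function(genes) {
  parts <- character(0)
  starts <- integer(0); ends <- integer(0)
  len <- 0L
  for (g in genes) {
    sp <- random_spacer(sample(20:100, 1L))
    parts <- c(parts, sp); len <- len + nchar(sp)
    starts <- c(starts, len); ends <- c(ends, len + nchar(g))
    parts <- c(parts, g); len <- len + nchar(g)
  }
  sp <- random_spacer(sample(20:100, 1L))
  parts <- c(parts, sp)
  list(sequence = paste(parts, collapse = ""), gene_starts = starts,
       gene_ends = ends)
}

#' Generate a random phage genome with gene/spacer architecture
#'
#' Alternating protein-coding genes (200-1500 nt) and short stop-dense
#' spacers (20-100 nt), emitted under the package's punctuated AT-rich
#' codon model.
#'
#' @param length_bp approximate genome length (the genome ends at the first
#'   gene boundary past this length).
#' @param id genome identifier.
#' @param seed optional RNG seed.
#' @return list with `genome` (a one-row [phage_genome_set()]) and `genes`
#'   (`data.frame` of 0-based gene `start`/`end`).
#' @export
random_phage_genome <- function(length_bp, id = "synthetic", seed = NULL) {
  with_seed(seed, {
    genes <- character(0); len <- 0L
    while (len < length_bp) {
      naa <- sample(66:500, 1L)
      g <- random_gene_dna(naa)
      genes <- c(genes, g)
      len <- len + nchar(g) + 60L
    }
    asm <- assemble_genome(genes)
    list(genome = phage_genome_set(id = id, sequence = asm$sequence),
         genes = data.frame(start = asm$gene_starts, end = asm$gene_ends))
  })
}

#' Introduce random point substitutions into a DNA sequence
#'
#' @param sequence DNA string.
#' @param rate per-base substitution probability.
#' @param seed optional RNG seed.
#' @return mutated sequence string.
#' @export
mutate_genome_nt <- function(sequence, rate, seed = NULL) {
  with_seed(seed, {
    ch <- strsplit(sequence, "")[[1]]
    i <- which(runif(length(ch)) < rate & ch %in% DNA_BASES)
    if (length(i)) {
      ch[i] <- vapply(ch[i], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  })
}

# mutate a gene at the codon level: a fraction (1 - aa_keep) of residues is
# replaced by a random amino acid, and silent codon re-draws add nucleotide
# divergence without touching the protein. Start/stop preserved. Punctuation
# dipeptides (the gene_codons layout places them at body codons i, i+1 with
# i %% 5 == 1) are mutated by re-drawing from their own stop-seeding family,
# so divergence accumulates without opening the non-coding frames.
mutate_gene <- function(dna, aa_keep = 0.92, silent_rate = 0.3,
                        model = codon_model()) {
  body <- substr(dna, 4L, nchar(dna) - 3L)
  n <- nchar(body) %/% 3L
  cods <- substring(body, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  frames <- c("fwd1", "fwd2", "rc0", "rc1", "rc2")
  i <- 1L; slot <- 0L
  while (i <= n) {
    if (i %% 5L == 1L && i < n) {
      slot <- slot %% 5L + 1L
      if (runif(1) > aa_keep) {
        g <- model$fam[[frames[slot]]]
        r <- g[sample(nrow(g), 1L), ]
        cods[i] <- r[[1]]; cods[i + 1L] <- r[[2]]
      }
      i <- i + 2L
    } else {
      if (runif(1) > aa_keep) {
        a <- sample(model$aa_names, 1L)
        cods[i] <- sample(model$by_aa[[a]], 1L, prob = model$w[[a]])
      } else if (runif(1) < silent_rate) {
        a <- model$aa_of(cods[i])
        cods[i] <- sample(model$by_aa[[a]], 1L, prob = model$w[[a]])
      }
      i <- i + 1L
    }
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}

# realized shared-protein fraction between two genome sequences
measure_sharing <- function(seq_a, seq_b, min_aa = 30L) {
  pa <- predict_orfs(seq_a, min_aa)$protein
  pb <- predict_orfs(seq_b, min_aa)$protein
  sc <- aa_pair_scores(pa, pb)
  r <- shared_from_scores(sc, length(pa), length(pb), 1e-3, "a", "b")
  list(prop = r$prop_shared, identity = r$mean_aa_identity)
}

#' Generate a genus of related phage genomes
#'
#' An ancestor gene repertoire is generated; every member carries a common
#' core (a fraction of the ancestral genes, mutated at the codon level)
#' plus member-specific novel genes. The core fraction is calibrated so
#' that the realized pairwise shared-protein fraction, as measured by
#' [shared_proteins()] on called ORFs, hits `protein_sharing_target`
#' (within about 0.05). Deterministic per seed.
#'
#' @param n_members number of genomes.
#' @param genome_length approximate genome length (bp); scalar or vector
#'   per member.
#' @param protein_sharing_target realized pairwise shared fraction in (0, 1];
#'   0 produces fully independent genomes.
#' @param seed RNG seed.
#' @param aa_keep per-residue retention probability in core genes.
#' @param ids member ids.
#' @param calibrate measure-and-adjust loop on the realized sharing
#'   (skipped for targets 0 and 1 where the construction is forced).
#' @return list with `genomes` (a [phage_genome_set()]) and `truth`
#'   (core fraction used, realized sharing of the first pair).
#' @export
make_genus <- function(n_members, genome_length, protein_sharing_target,
                       seed, aa_keep = 0.92, ids = NULL,
                       calibrate = TRUE) {
  stopifnot(protein_sharing_target >= 0, protein_sharing_target <= 1)
  if (any(genome_length < 2000)) {
    stop("genome_length too small to host a gene repertoire", call. = FALSE)
  }
  lens <- rep_len(genome_length, n_members)
  if (is.null(ids)) ids <- paste0("member", seq_len(n_members))
  with_seed(seed, {
    if (protein_sharing_target == 0) {
      gens <- lapply(seq_len(n_members), function(i) {
        random_phage_genome(lens[i], id = ids[i])$genome
      })
      genomes <- do.call(rbind, gens)
      class(genomes) <- c("phage_genome_set", "data.frame")
      return(list(genomes = genomes,
                  truth = list(core_fraction = 0, realized = 0)))
    }
    ancestor <- build_gene_pool(max(lens))
    s <- min(1, protein_sharing_target * 1.15)  # detection losses offset
    realized <- NA_real_
    for (iter in 1:3) {
      members <- lapply(seq_len(n_members), function(i) {
        member_sequence(ancestor, s, lens[i], aa_keep)
      })
      if (!calibrate || protein_sharing_target >= 0.999) break
      m <- measure_sharing(members[[1]], members[[2]])
      realized <- m$prop
      if (abs(realized - protein_sharing_target) <= 0.04) break
      s <- max(0.05, min(1, s * protein_sharing_target / max(realized, 1e-3)))
    }
    genomes <- phage_genome_set(id = ids,
                                sequence = vapply(members, identity, ""))
    list(genomes = genomes,
         truth = list(core_fraction = s, realized = realized))
  })
}

# ancestor gene repertoire filling roughly target_len
build_gene_pool <- function(target_len) {
  genes <- character(0); len <- 0L
  while (len < target_len) {
    naa <- sample(100:500, 1L)
    g <- random_gene_dna(naa)
    genes <- c(genes, g); len <- len + nchar(g) + 60L
  }
  genes
}

# one genus member: core = first s-fraction of ancestor genes (mutated),
# topped up with novel genes to the length target
member_sequence <- function(ancestor, s, target_len, aa_keep) {
  n_core <- max(1L, round(s * length(ancestor)))
  core <- vapply(ancestor[seq_len(min(n_core, length(ancestor)))],
                 function(g) mutate_gene(g, aa_keep = aa_keep), character(1))
  len <- sum(nchar(core)) + 60L * length(core)
  extra <- character(0)
  while (len < target_len) {
    g <- random_gene_dna(sample(100:500, 1L))
    extra <- c(extra, g); len <- len + nchar(g) + 60L
  }
  genes <- sample(c(core, extra))  # shuffle gene order
  assemble_genome(genes)$sequence
}

#' Plant a DGR cassette into a genome
#'
#' Copies the 3'-terminal region of a suitable forward-strand gene as a
#' template repeat (TR) into an intergenic position, then randomizes the
#' gene copy (the variable repeat, VR) at `n_adenine_sites` positions that
#' are adenines in the TR, drawing replacement bases uniformly. The
#' randomization is redrawn until at least one mismatch exists and no
#' in-frame stop codon is created in the target gene.
#'
#' @param genome one-row [phage_genome_set()] or DNA string.
#' @param tr_length repeat length (bp), 100-135 for a canonical cassette.
#' @param n_adenine_sites number of TR-adenine positions randomized.
#' @param seed optional RNG seed.
#' @param orfs optional precomputed ORF table.
#' @return list with `genome` (updated one-row set) and `cassette` (truth:
#'   0-based `tr_start`, `tr_end`, `vr_start`, `vr_end`, `target_start`,
#'   `target_end`, `target_strand`, `n_changed`).
#' @export
plant_dgr <- function(genome, tr_length = 120L, n_adenine_sites = 10L,
                      seed = NULL, orfs = NULL) {
  seq <- genome_sequence(genome)
  gid <- genome_id_of(genome)
  if (is.null(orfs)) orfs <- predict_orfs(seq)
  with_seed(seed, {
    cand <- orfs[orfs$strand == "+" &
                 (orfs$end - orfs$start) >= 3L * tr_length + 120L, ,
                 drop = FALSE]
    ok <- FALSE
    for (ci in sample(seq_len(nrow(cand)))) {
      orf <- cand[ci, ]
      # codon-aligned VR ending 4 codons before the stop codon
      n_cod <- ceiling(tr_length / 3L)
      vr_end <- orf$end - 15L            # 0-based exclusive
      vr_start <- vr_end - 3L * n_cod
      vr_len <- 3L * n_cod
      vr <- substr(seq, vr_start + 1L, vr_start + vr_len)
      a_pos <- which(strsplit(vr, "")[[1]] == "A")
      # variable sites are drawn from the repeat interior: a mismatch
      # cluster flush against the boundary is indistinguishable from
      # sequence beyond the repeat, for this and any maximal-span detector
      a_pos <- a_pos[a_pos > 8L & a_pos <= vr_len - 8L]
      if (length(a_pos) < max(3L, n_adenine_sites)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("no suitable target gene for a DGR cassette", call. = FALSE)
    # randomize VR at adenine sites, rejecting in-frame stops / zero change.
    # n_adenine_sites = 0 plants an invariant (TR == VR) repeat, which the
    # detector is expected to reject.
    new_vr <- vr
    ok <- n_adenine_sites == 0L
    if (n_adenine_sites > 0L) for (try in 1:200) {
      sites <- sort(sample(a_pos, n_adenine_sites))
      ch <- strsplit(vr, "")[[1]]
      ch[sites] <- sample(DNA_BASES, n_adenine_sites, replace = TRUE)
      changed <- sites[ch[sites] != "A"]
      if (length(changed) == 0L) next
      # realistic cassettes diversify positions spread along the repeat;
      # require the realized mismatches to cover at least half of it (and
      # not collapse to one or two sites) so the variable signal is not
      # confined to a boundary
      if (n_adenine_sites >= 4L) {
        if (length(changed) < max(3L, ceiling(0.4 * n_adenine_sites))) next
        if (diff(range(changed)) < 0.5 * vr_len) next
      }
      new_vr <- paste(ch, collapse = "")
      cods <- substring(new_vr, 3L * seq_len(vr_len %/% 3L) - 2L,
                        3L * seq_len(vr_len %/% 3L))
      if (any(cods %in% STOP_CODONS)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not randomize VR without creating a stop codon",
           call. = FALSE)
    }
    # TR (the untouched template) goes to an intergenic position
    gaps <- intergenic_positions(orfs, nchar(seq))
    gaps <- gaps[abs(gaps - vr_start) > 500L]
    if (length(gaps) == 0L) stop("no intergenic insertion point available",
                                 call. = FALSE)
    p <- sample(gaps, 1L)
    tr <- vr   # template = original gene sequence
    new_seq <- paste0(substr(seq, 1L, p),
                      tr,
                      substr(seq, p + 1L, nchar(seq)))
    shift <- function(x) ifelse(x >= p, x + vr_len, x)
    vr_start2 <- shift(vr_start); vr_end2 <- vr_start2 + vr_len
    t_start <- shift(orf$start); t_end <- shift(orf$end)
    # write the randomized VR into the shifted coordinates
    new_seq <- paste0(substr(new_seq, 1L, vr_start2),
                      new_vr,
                      substr(new_seq, vr_end2 + 1L, nchar(new_seq)))
    out <- phage_genome_set(id = gid, sequence = new_seq)
    cassette <- data.frame(
      genome_id = gid, tr_start = p, tr_end = p + vr_len,
      vr_start = vr_start2, vr_end = vr_end2,
      target_start = t_start, target_end = t_end, target_strand = "+",
      n_changed = sum(strsplit(new_vr, "")[[1]] != strsplit(tr, "")[[1]]),
      stringsAsFactors = FALSE)
    list(genome = out, cassette = cassette)
  })
}

# 0-based positions between called ORFs where an insertion is safe
intergenic_positions <- function(orfs, n) {
  if (nrow(orfs) == 0L) return(seq(100L, n - 100L, by = 50L))
  cov <- integer(0)
  pos <- seq(60L, n - 60L, by = 25L)
  inside <- vapply(pos, function(p) {
    any(orfs$start < p & orfs$end > p)
  }, logical(1))
  pos[!inside]
}

#' Integrate a phage into a host genome
#'
#' `site_specific` mode inserts one copy flanked by an exact direct repeat
#' of `att_length` (the attL/attR signature of integrase-mediated
#' integration); `transposable` mode inserts `n_copies` at random positions
#' without a conserved repeat, emulating replicative transposition.
#'
#' @param host host DNA string or genome row.
#' @param phage phage DNA string or genome row.
#' @param att_length direct-repeat length (site_specific; >= 3).
#' @param mode `"site_specific"` or `"transposable"`.
#' @param n_copies copies inserted in transposable mode.
#' @param seed optional RNG seed.
#' @return list with `host_sequence` and `truth` (per copy: 0-based
#'   `prophage_start`, `prophage_end`; for site_specific also
#'   `att_sequence`, `att_left`, `att_right`).
#' @export
integrate_prophage <- function(host, phage, att_length = 12L,
                               mode = c("site_specific", "transposable"),
                               n_copies = 3L, seed = NULL) {
  mode <- match.arg(mode)
  hseq <- genome_sequence(host); pseq <- genome_sequence(phage)
  if (nchar(pseq) > nchar(hseq)) {
    stop("phage longer than host", call. = FALSE)
  }
  with_seed(seed, {
    if (mode == "site_specific") {
      stopifnot(att_length >= 3L)
      p0 <- sample(seq(600L, nchar(hseq) - 600L - att_length), 1L)  # 0-based
      att <- substr(hseq, p0 + 1L, p0 + att_length)
      new <- paste0(substr(hseq, 1L, p0 + att_length), pseq,
                    substr(hseq, p0 + 1L, nchar(hseq)))
      start <- p0 + att_length
      truth <- data.frame(prophage_start = start,
                          prophage_end = start + nchar(pseq),
                          att_sequence = att, att_left = p0,
                          att_right = start + nchar(pseq),
                          stringsAsFactors = FALSE)
      list(host_sequence = new, truth = truth)
    } else {
      seqs <- hseq; truths <- list()
      for (i in seq_len(n_copies)) {
        p0 <- sample(seq(600L, nchar(seqs) - 600L), 1L)
        seqs <- paste0(substr(seqs, 1L, p0), pseq,
                       substr(seqs, p0 + 1L, nchar(seqs)))
        truths[[i]] <- data.frame(prophage_start = p0,
                                  prophage_end = p0 + nchar(pseq),
                                  stringsAsFactors = FALSE)
      }
      list(host_sequence = seqs, truth = do.call(rbind, truths))
    }
  })
}

#' Simulate reads from encapsidated phage DNA
#'
#' `headful` packaging emulates a transposable phage: every virion carries
#' the phage flanked by host DNA from an independent random location, so
#' terminus-spanning reads have variable flanks. `cos` packaging produces
#' exact genome ends: terminal reads start at the terminus with no
#' overhang.
#'
#' @param phage phage DNA string or genome row.
#' @param host host DNA string (flank source for headful packaging).
#' @param packaging `"headful"` or `"cos"`.
#' @param n_reads number of terminal-region reads to simulate.
#' @param read_length read length (bp).
#' @param seed optional RNG seed.
#' @return named character vector of reads.
#' @export
simulate_packaged_reads <- function(phage, host = NULL,
                                    packaging = c("headful", "cos"),
                                    n_reads = 50L, read_length = 250L,
                                    seed = NULL) {
  packaging <- match.arg(packaging)
  pseq <- genome_sequence(phage)
  n <- nchar(pseq)
  with_seed(seed, {
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      left <- runif(1) < 0.5
      if (packaging == "headful") {
        if (is.null(host)) stop("headful packaging needs a host flank source",
                                call. = FALSE)
        hseq <- genome_sequence(host)
        o <- sample(40:120, 1L)
        hp <- sample(nchar(hseq) - o, 1L)
        flank <- substr(hseq, hp + 1L, hp + o)
        reads[i] <- if (left) {
          paste0(flank, substr(pseq, 1L, read_length - o))
        } else {
          paste0(substr(pseq, n - (read_length - o) + 1L, n), flank)
        }
      } else {
        reads[i] <- if (left) substr(pseq, 1L, read_length)
                    else substr(pseq, n - read_length + 1L, n)
      }
    }
    setNames(reads, paste0("vread", seq_len(n_reads)))
  })
}

# draw one read (with substitution errors) from a sequence
draw_read <- function(seq, read_length, error_rate) {
  n <- nchar(seq)
  rl <- min(read_length, n)
  p <- if (n == rl) 1L else sample(n - rl + 1L, 1L)
  r <- substr(seq, p, p + rl - 1L)
  if (error_rate > 0) {
    ch <- strsplit(r, "")[[1]]
    i <- which(runif(rl) < error_rate)
    if (length(i)) {
      ch[i] <- vapply(ch[i], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
      r <- paste(ch, collapse = "")
    }
  }
  if (runif(1) < 0.5) r <- revcomp(r)
  r
}

#' Simulate a virome read sample
#'
#' Reads are drawn uniformly along each reference at the stated per-read
#' frequencies; a contamination fraction is drawn from the bacterial
#' contamination source (host genome and control segments); the remainder
#' is unmappable background. Substitution errors only.
#'
#' @param references a [phage_genome_set()] of phage genomes.
#' @param frequencies named per-read sampling probabilities (names must be
#'   reference ids; sum with `contamination_fraction` must be <= 1).
#' @param n_reads total reads.
#' @param read_length read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param contamination_source optional [phage_genome_set()] of bacterial
#'   sequences (for instance the two 50-kb control segments).
#' @param contamination_fraction fraction of reads drawn from the
#'   contamination source.
#' @param sample_id sample identifier.
#' @param seed RNG seed.
#' @return list with `reads` (named character vector), `sample_id`,
#'   `n_total_reads`, and `truth` (per-read source labels).
#' @export
simulate_virome <- function(references, frequencies, n_reads,
                            read_length = 250L, error_rate = 0.005,
                            contamination_source = NULL,
                            contamination_fraction = 0,
                            sample_id = "sample1", seed = NULL) {
  if (any(frequencies < 0)) stop("negative frequency", call. = FALSE)
  stopifnot(contamination_fraction >= 0, contamination_fraction < 1)
  if (sum(frequencies) + contamination_fraction > 1) {
    stop("frequencies plus contamination exceed 1", call. = FALSE)
  }
  with_seed(seed, {
    if (n_reads == 0L) {
      return(list(reads = setNames(character(0), character(0)),
                  sample_id = sample_id, n_total_reads = 0L,
                  truth = character(0), empty = TRUE))
    }
    sources <- c(names(frequencies), "contamination", "background")
    probs <- c(as.numeric(frequencies), contamination_fraction,
               1 - sum(frequencies) - contamination_fraction)
    lab <- sample(sources, n_reads, replace = TRUE, prob = probs)
    refseq <- setNames(references$sequence, references$id)
    contam <- if (!is.null(contamination_source)) {
      contamination_source$sequence
    } else NULL
    reads <- vapply(lab, function(src) {
      if (src == "background") {
        paste(sample(DNA_BASES, read_length, TRUE), collapse = "")
      } else if (src == "contamination") {
        s <- contam[[sample(length(contam), 1L)]]
        draw_read(s, read_length, error_rate)
      } else {
        draw_read(refseq[[src]], read_length, error_rate)
      }
    }, character(1))
    names(reads) <- paste0(sample_id, "_r", seq_len(n_reads))
    list(reads = reads, sample_id = sample_id, n_total_reads = n_reads,
         truth = setNames(lab, names(reads)), empty = FALSE)
  })
}

#' Simulate a healthy/IBD virome cohort (count level)
#'
#' Per-patient random intercepts are drawn once; per-sample phage read
#' frequencies follow a logistic model with a cohort-status fixed effect;
#' presence is planted per group prevalence. Hit counts are binomial draws
#' against the total read count, alongside binomial contamination counts
#' for two 50-kb control regions. Read sequences themselves can be
#' generated separately with [simulate_virome()] using the emitted truth.
#'
#' @param n_patients named vector `c(healthy = ..., IBD = ...)`.
#' @param samples_per_patient integer range sampled per patient.
#' @param baseline_freq phage read frequency at healthy baseline.
#' @param status_log_odds status fixed effect (log-odds, IBD vs healthy).
#' @param patient_sd standard deviation of the patient random intercept.
#' @param prevalence_by_group named per-sample presence probability.
#' @param n_reads total reads per sample.
#' @param contamination_freq per-control-region contamination read
#'   frequency.
#' @param seed RNG seed.
#' @return list with `sample_sheet`, `counts` (per sample: `n_hits`,
#'   `control_hits_1`, `control_hits_2`, `n_total_reads`, `present`), and
#'   `truth` (patient intercepts, per-sample true frequencies).
#' @export
simulate_cohort <- function(n_patients = c(healthy = 21, IBD = 52),
                            samples_per_patient = 2:3,
                            baseline_freq = 2e-4, status_log_odds = 1.0,
                            patient_sd = 0.5,
                            prevalence_by_group = c(healthy = 0.2, IBD = 0.3),
                            n_reads = 2e5, contamination_freq = 2e-5,
                            seed = NULL) {
  stopifnot(patient_sd >= 0, baseline_freq > 0, baseline_freq < 1)
  with_seed(seed, {
    rows <- list(); cnts <- list(); tr <- list()
    sidx <- 0L
    for (grp in names(n_patients)) {
      for (pt in seq_len(n_patients[[grp]])) {
        pid <- sprintf("%s_pt%02d", grp, pt)
        b <- rnorm(1, 0, patient_sd)
        ns <- if (length(samples_per_patient) == 1L) samples_per_patient
              else sample(samples_per_patient, 1L)
        for (sm in seq_len(ns)) {
          sidx <- sidx + 1L
          sid <- sprintf("s%04d", sidx)
          eta <- stats::qlogis(baseline_freq) +
                 (grp == "IBD") * status_log_odds + b
          freq <- stats::plogis(eta)
          present <- runif(1) < prevalence_by_group[[grp]]
          hits <- if (present) rbinom(1, n_reads, freq) else 0L
          rows[[sidx]] <- data.frame(sample_id = sid, subject_id = pid,
                                     status = grp, n_total_reads = n_reads,
                                     stringsAsFactors = FALSE)
          cnts[[sidx]] <- data.frame(
            sample_id = sid, n_hits = hits,
            control_hits_1 = rbinom(1, n_reads, contamination_freq),
            control_hits_2 = rbinom(1, n_reads, contamination_freq),
            n_total_reads = n_reads, present = present,
            stringsAsFactors = FALSE)
          tr[[sidx]] <- data.frame(sample_id = sid, subject_id = pid,
                                   intercept = b, true_freq = freq,
                                   present = present, stringsAsFactors = FALSE)
        }
      }
    }
    list(sample_sheet = do.call(rbind, rows), counts = do.call(rbind, cnts),
         truth = do.call(rbind, tr))
  })
}
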