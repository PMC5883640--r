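# Internal alignment machinery: k-mer hashing, maximal exact matches and
# Karlin-Altschul E-values. Local alignment itself is delegated to
# Biostrings::pairwiseAlignment (Smith-Waterman in C); everything here is
# the seeding/statistics layer around it.

# table of (kmer, pos) for all k-mers of a sequence; pos is 1-based
kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(data.table::data.table(kmer = character(0), pos = integer(0)))
  }
  pos <- seq_len(n - k + 1L)
  data.table::data.table(kmer = substring(seq, pos, pos + k - 1L), pos = pos)
}

# shared k-mer positions between two sequences: data.table(pos_a, pos_b)
kmer_hits <- function(a, b, k, max_occ = Inf) {
  ta <- kmer_table(a, k)
  tb <- kmer_table(b, k)
  if (is.finite(max_occ)) {
    ta <- ta[, if (.N <= max_occ) .SD, by = kmer]
    tb <- tb[, if (.N <= max_occ) .SD, by = kmer]
  }
  m <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(data.table::data.table(pos_a = integer(0), pos_b = integer(0)))
  }
  m[, list(pos_a, pos_b)]
}

# Merge diagonal runs of shared k-mers into maximal exact matches.
# A run of consecutive hits (i, j), (i+1, j+1), ... on one diagonal is a
# single exact match of length run + k - 1; it is maximal because any
# flanking matching base would extend the run by another shared k-mer.
merge_diagonal_runs <- function(hits, k) {
  if (nrow(hits) == 0L) {
    return(data.table::data.table(start_a = integer(0), start_b = integer(0),
                                  len = integer(0)))
  }
  hits <- data.table::copy(hits)
  hits[, d := pos_b - pos_a]
  data.table::setorder(hits, d, pos_a)
  hits[, run_id := cumsum(!(d == data.table::shift(d, fill = -.Machine$integer.max) &
                            pos_a == data.table::shift(pos_a, fill = -2L) + 1L))]
  hits[, list(start_a = min(pos_a), start_b = min(pos_b),
              len = .N + k - 1L), by = run_id][, run_id := NULL][]
}

# Maximal exact matches of length >= k between a and b, both strands.
# Returned coordinates are 1-based starts on the forward strands of a and b.
maximal_exact_matches <- function(a, b, k, strands = c("+", "-"),
                                  max_occ = 64L) {
  out <- list()
  if ("+" %in% strands) {
    runs <- merge_diagonal_runs(kmer_hits(a, b, k, max_occ), k)
    if (nrow(runs)) {
      runs[, `:=`(strand = "+")]
      out[["+"]] <- runs
    }
  }
  if ("-" %in% strands) {
    brc <- revcomp(b)
    runs <- merge_diagonal_runs(kmer_hits(a, brc, k, max_occ), k)
    if (nrow(runs)) {
      nb <- nchar(b)
      runs[, start_b := nb - (start_b + len - 1L) + 1L]
      runs[, `:=`(strand = "-")]
      out[["-"]] <- runs
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(start_a = integer(0), start_b = integer(0),
                                  len = integer(0), strand = character(0)))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, start_a, start_b)
  res[]
}

# --- Karlin-Altschul statistics ------------------------------------------

# lambda for a match/mismatch scoring scheme under uniform base composition
ka_cache <- new.env(parent = emptyenv())

ka_lambda_nt <- function(match = 2, mismatch = -3) {
  key <- paste0("nt", match, "_", mismatch)
  if (!is.null(ka_cache[[key]])) return(ka_cache[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  ka_cache[[key]] <- lam
  lam
}

# E-value of a nucleotide local alignment score (ungapped lambda used as the
# standard practical approximation for moderately gapped alignments)
evalue_nt <- function(score, m, n, match = 2, mismatch = -3, K = 0.41) {
  K * m * n * exp(-ka_lambda_nt(match, mismatch) * score)
}

# BLOSUM62 with affine gaps 11/1: standard gapped parameters
evalue_aa <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

# substitution matrix for nucleotide local alignment (shared by read mapping
# and gap polishing); N scores 0 against everything
nt_submat <- function(match = 2, mismatch = -3) {
  key <- paste0("mat", match, "_", mismatch)
  if (!is.null(ka_cache[[key]])) return(ka_cache[[key]])
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  ka_cache[[key]] <- m
  m
}

blosum62 <- function() {
  if (is.null(ka_cache[["BLOSUM62"]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ka_cache[["BLOSUM62"]] <- e$BLOSUM62
  }
  ka_cache[["BLOSUM62"]]
}

# unique k-mer table of a whole proteome: data.table(kmer, J). K-mers
# occurring in a large fraction of the proteins (compositional bias, not
# homology signal) are dropped from the candidate prefilter.
proteome_kmer_table <- function(prot, k = 4L, max_df_frac = 0.15) {
  t <- data.table::rbindlist(lapply(seq_along(prot), function(i) {
    x <- kmer_table(prot[i], k); x[, J := i]; x
  }))
  if (nrow(t) == 0L) return(data.table::data.table(kmer = character(0),
                                                   J = integer(0)))
  t <- unique(t[, list(kmer, J)])
  max_df <- max(3L, ceiling(max_df_frac * length(prot)))
  t[, if (.N <= max_df) .SD, by = kmer][, list(kmer, J)]
}

# Candidate scoring of all plausibly homologous protein pairs between two
# proteomes. Pairs are pre-screened by shared 4-mers (>= min_shared_kmers),
# then Smith-Waterman scored in one batched elementwise call.
# Returns data.table(qi, sj, score, pid, evalue).
aa_pair_scores <- function(prot_a, prot_b, k = 4L, min_shared_kmers = 2L,
                           tab_a = NULL, tab_b = NULL) {
  if (is.null(tab_a)) tab_a <- proteome_kmer_table(prot_a, k)
  if (is.null(tab_b)) tab_b <- proteome_kmer_table(prot_b, k)
  empty <- data.table::data.table(qi = integer(0), sj = integer(0),
                                  score = numeric(0), pid = numeric(0),
                                  evalue = numeric(0))
  if (nrow(tab_a) == 0L || nrow(tab_b) == 0L) return(empty)
  ta <- data.table::copy(tab_a); data.table::setnames(ta, "J", "qi")
  tb <- data.table::copy(tab_b); data.table::setnames(tb, "J", "sj")
  pairs <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE)[
    , list(nk = .N), by = list(qi, sj)][nk >= min_shared_kmers]
  if (nrow(pairs) == 0L) return(empty)
  data.table::setorder(pairs, qi, sj)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(prot_b[pairs$sj]),
    subject = Biostrings::AAStringSet(prot_a[pairs$qi]),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  sc <- Biostrings::score(aln)
  n_total <- sum(nchar(prot_b))  # subject search space: the whole proteome
  data.table::data.table(
    qi = pairs$qi, sj = pairs$sj, score = sc,
    pid = Biostrings::pid(aln, type = "PID1"),
    evalue = evalue_aa(sc, nchar(prot_a[pairs$qi]), n_total)
  )
}
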