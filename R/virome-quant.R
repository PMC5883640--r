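# Quantification of phages in virome read sets: seed-and-extend read
# alignment, hit filtering, 50-kb length normalization, 500-bp window
# coverage with spurious-pile-up correction, and contamination-controlled
# presence calls.

#' Build a k-mer index over a set of reference sequences
#'
#' @param references a [phage_genome_set()] table or a named character
#'   vector of sequences.
#' @param k seed length.
#' @return an opaque index object for [align_reads()].
#' @export
reference_kmer_index <- function(references, k = 12L) {
  if (is.data.frame(references)) {
    seqs <- setNames(references$sequence, references$id)
  } else {
    seqs <- references
    if (is.null(names(seqs))) names(seqs) <- paste0("ref", seq_along(seqs))
  }
  tabs <- lapply(seqs, function(s) {
    t <- kmer_table(s, k)
    data.table::setkey(t, kmer)
    t
  })
  structure(list(seqs = seqs, tabs = tabs, k = k),
            class = "reference_kmer_index")
}

# Align one read against every reference in the index: banded seed-and-extend
# with a Smith-Waterman polish of the best diagonal band. Returns a named
# list (by reference) of hit lists, NULL where no seed support exists.
align_read <- function(read, index, band = 30L) {
  k <- index$k
  res <- setNames(vector("list", length(index$seqs)), names(index$seqs))
  reads2 <- c(`+` = read, `-` = revcomp(read))
  rk <- lapply(reads2, function(r) kmer_table(r, k))
  for (ref in names(index$seqs)) {
    tab <- index$tabs[[ref]]
    best <- NULL
    for (strand in c("+", "-")) {
      q <- rk[[strand]]
      if (nrow(q) == 0L) next
      m <- tab[q, on = "kmer", nomatch = NULL]
      if (nrow(m) == 0L) next
      # m: pos (reference), i.pos (read); pick the best-supported diagonal band
      diag <- m$pos - m$i.pos
      db <- round(diag / band)
      tb <- table(db)
      center <- as.integer(names(tb)[which.max(tb)])
      sel <- abs(db - center) <= 1L
      cand <- list(strand = strand,
                   ref_lo = min(m$pos[sel]), ref_hi = max(m$pos[sel]),
                   support = sum(sel))
      if (is.null(best) || cand$support > best$support) best <- cand
    }
    if (is.null(best)) next
    rseq <- reads2[[best$strand]]
    w0 <- max(1L, best$ref_lo - nchar(rseq) - band)
    w1 <- min(nchar(index$seqs[[ref]]), best$ref_hi + nchar(rseq) + band)
    window <- substr(index$seqs[[ref]], w0, w1)
    aln <- Biostrings::pairwiseAlignment(
      pattern = rseq, subject = window, type = "local",
      substitutionMatrix = nt_submat(2, -3), gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (sc <= 0) next
    sub <- Biostrings::subject(aln)
    pat <- Biostrings::pattern(aln)
    aln_len <- Biostrings::nchar(aln)
    nmatch <- Biostrings::nmatch(aln)
    ref_start0 <- w0 - 1L + Biostrings::start(sub) - 1L      # 0-based
    ref_end0 <- w0 - 1L + Biostrings::end(sub)               # exclusive
    # mismatch positions on the reference (0-based), excluding gap columns
    ps <- strsplit(as.character(pat), "")[[1]]
    ss <- strsplit(as.character(sub), "")[[1]]
    refpos <- ref_start0 - 1L + cumsum(ss != "-")             # 0-based
    mm_pos <- refpos[ps != ss & ps != "-" & ss != "-"]
    res[[ref]] <- list(
      strand = best$strand, score = sc,
      identity_percent = 100 * nmatch / aln_len,
      alignment_length_bp = aln_len,
      e_value = evalue_nt(sc, nchar(read), nchar(index$seqs[[ref]])),
      ref_start = ref_start0, ref_end = ref_end0,
      read_start = Biostrings::start(pat) - 1L,
      read_end = Biostrings::end(pat),
      mismatch_positions = mm_pos)
  }
  res
}

#' Align virome reads against phage references
#'
#' Seed-and-extend local alignment (shared 12-mers define a diagonal band,
#' polished by Smith-Waterman) of every read against every reference, on
#' both strands. One read may hit several references; per-reference
#' counting matches per-phage read proportions. Only the best local
#' alignment per read/reference pair is reported.
#'
#' @param reads named character vector of read sequences (names become
#'   `read_id`).
#' @param references a [phage_genome_set()] table, named character vector,
#'   or a prebuilt [reference_kmer_index()].
#' @param details if `TRUE`, keep per-hit mismatch reference positions (for
#'   [vr_variability()]).
#' @param e_report hits with E-value above this are not reported at all.
#' @return `data.frame` of hits: `read_id`, `reference_id`,
#'   `identity_percent`, `alignment_length_bp`, `e_value`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand`; with `details`, a
#'   `mismatch_positions` list column.
#' @export
align_reads <- function(reads, references, details = FALSE, e_report = 1e-3) {
  if (!inherits(references, "reference_kmer_index")) {
    references <- reference_kmer_index(references)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rows <- list()
  for (rid in names(reads)) {
    hits <- align_read(reads[[rid]], references)
    for (ref in names(hits)) {
      h <- hits[[ref]]
      if (is.null(h) || h$e_value > e_report) next
      rows[[length(rows) + 1L]] <- list(
        read_id = rid, reference_id = ref,
        identity_percent = h$identity_percent,
        alignment_length_bp = h$alignment_length_bp,
        e_value = h$e_value, ref_start = h$ref_start,
        ref_end = h$ref_end, strand = h$strand,
        mismatch_positions = list(h$mismatch_positions))
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(read_id = character(0), reference_id = character(0),
                      identity_percent = numeric(0),
                      alignment_length_bp = integer(0), e_value = numeric(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    if (details) out$mismatch_positions <- I(list())
    return(out)
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  if (!details) out$mismatch_positions <- NULL
  out
}

#' Filter read hits on E-value and identity
#'
#' Strict inequalities on both thresholds (E below `e_max`, identity above
#' `min_identity` percent).
#'
#' @param hits hit table from [align_reads()].
#' @param e_max E-value cutoff.
#' @param min_identity percent identity cutoff.
#' @return the retained rows.
#' @export
filter_hits <- function(hits, e_max = 1e-9, min_identity = 75) {
  stopifnot(e_max > 0, min_identity > 0)
  hits[hits$e_value < e_max & hits$identity_percent > min_identity, ,
       drop = FALSE]
}

#' Length-normalize a hit count to a 50-kb reference genome
#'
#' Read counts are divided by genome length and rescaled to the average
#' phage genome length (50 kb), making read proportions comparable across
#' phages of different sizes.
#'
#' @param n_hits hit count (any numeric).
#' @param genome_length_bp reference genome length.
#' @param reference_length_bp normalization target length.
#' @return normalized count.
#' @export
normalize_count <- function(n_hits, genome_length_bp,
                            reference_length_bp = 50000) {
  if (any(genome_length_bp <= 0)) stop("genome length must be positive",
                                       call. = FALSE)
  n_hits * reference_length_bp / genome_length_bp
}

#' Cap spurious coverage pile-ups
#'
#' Over the non-zero 500-bp windows, let `m` be the median count and `a`
#' the mean. When the mean exceeds 10 times the median, windows counting
#' more than `10 m` are considered spurious (conserved-region pile-ups from
#' unrelated phages) and replaced by `10 m`; otherwise counts are returned
#' unchanged. Idempotent, never increases a count.
#'
#' @param raw_counts non-negative per-window hit counts.
#' @return corrected counts.
#' @export
spurious_correction <- function(raw_counts) {
  stopifnot(all(raw_counts >= 0))
  nz <- raw_counts[raw_counts > 0]
  if (length(nz) == 0L) return(raw_counts)
  m <- median(nz)
  a <- mean(nz)
  if (a > 10 * m) pmin(raw_counts, 10 * m) else raw_counts
}

#' Per-window coverage profile of a reference
#'
#' Non-overlapping 500-bp windows tiled from position 0 (the last, partial
#' window counts); each retained hit is assigned to the window containing
#' its reference-interval midpoint.
#'
#' @param hits filtered hit table for one reference.
#' @param reference_length reference genome length (bp).
#' @param window_size window size in bp.
#' @return list with `raw_counts`, `corrected_counts`,
#'   `n_nonzero_windows` (windows with at least one raw hit).
#' @export
coverage_profile <- function(hits, reference_length, window_size = 500L) {
  nw <- as.integer(ceiling(reference_length / window_size))
  raw <- integer(nw)
  if (nrow(hits)) {
    mid <- (hits$ref_start + hits$ref_end) %/% 2L
    w <- pmin(mid %/% window_size + 1L, nw)
    t <- table(w)
    raw[as.integer(names(t))] <- as.integer(t)
  }
  list(raw_counts = raw, corrected_counts = spurious_correction(raw),
       n_nonzero_windows = sum(raw > 0L))
}

#' Two-proportion z-test
#'
#' Pooled-variance z statistic for comparing two binomial proportions, with
#' a one- or two-tailed normal p-value.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param tail `"greater"` (p1 > p2), `"less"`, or `"two.sided"`.
#' @return list with `z` and `p`.
#' @export
two_prop_z <- function(x1, n1, x2, n2,
                       tail = c("greater", "two.sided", "less")) {
  tail <- match.arg(tail)
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1", call. = FALSE)
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- switch(tail,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = 2 * pnorm(-abs(z)))
  list(z = z, p = p)
}

#' Contamination-controlled phage presence call
#'
#' A sample is `excluded` for a phage when its retained hits cover fewer
#' than `min_windows` non-overlapping 500-bp windows (spurious
#' conserved-region matches). Otherwise the phage hit proportion is tested
#' against the pooled hit proportion of the two 50-kb bacterial control
#' regions (the maximal theoretical contamination yield) with a one-tailed
#' two-proportion z-test; `positive` iff p < `alpha`.
#'
#' @param phage_counts per-window raw hit counts for this phage in this
#'   sample (see [coverage_profile()]).
#' @param control_hits numeric vector of retained hit counts on the
#'   bacterial control regions (typically length 2).
#' @param n_total_reads total reads in the sample.
#' @param alpha significance threshold.
#' @param min_windows exclusion threshold on covered windows.
#' @param control_mode `"pooled"` sums the control counts (maximal
#'   theoretical contamination); `"max"` uses the larger one.
#' @return one-row `data.frame`: `call`, `p_value`, `phage_proportion`,
#'   `control_proportion`, `n_covered_windows`.
#' @export
call_presence <- function(phage_counts, control_hits, n_total_reads,
                          alpha = 0.05, min_windows = 3L,
                          control_mode = c("pooled", "max")) {
  control_mode <- match.arg(control_mode)
  if (length(control_hits) == 0L || anyNA(control_hits)) {
    stop("control counts are required for presence calling", call. = FALSE)
  }
  corrected <- spurious_correction(phage_counts)
  covered <- sum(phage_counts > 0)
  x1 <- sum(corrected)
  x2 <- switch(control_mode, pooled = sum(control_hits),
               max = max(control_hits))
  p1 <- x1 / n_total_reads
  p2 <- x2 / n_total_reads
  if (covered < min_windows) {
    return(data.frame(call = "excluded", p_value = NA_real_,
                      phage_proportion = p1, control_proportion = p2,
                      n_covered_windows = covered, stringsAsFactors = FALSE))
  }
  zt <- two_prop_z(x1, n_total_reads, x2, n_total_reads, tail = "greater")
  data.frame(call = if (zt$p < alpha) "positive" else "negative",
             p_value = zt$p, phage_proportion = p1, control_proportion = p2,
             n_covered_windows = covered, stringsAsFactors = FALSE)
}

#' Quantify phages in one virome sample
#'
#' End-to-end per-sample pipeline: align reads to phage references and
#' bacterial control regions, filter hits (E < `e_max`, identity >
#' `min_identity`), window the coverage, correct spurious pile-ups,
#' normalize counts to 50 kb, and call presence against the contamination
#' controls.
#'
#' @param reads named character vector of read sequences.
#' @param references phage reference [phage_genome_set()].
#' @param controls bacterial control-region [phage_genome_set()] (two 50-kb
#'   segments in the standard design).
#' @param e_max,min_identity hit filters.
#' @param alpha,min_windows,control_mode presence-call settings.
#' @param window_size coverage window (bp).
#' @return list with `hits` (filtered), `abundance` (per phage:
#'   `reference_id`, `n_hits_raw`, `n_hits_corrected`, `n_hits_normalized`,
#'   `frequency`), `presence` (per phage presence calls), `coverage`
#'   (list of per-phage profiles), `control_hits` (named counts).
#' @export
quantify_sample <- function(reads, references, controls,
                            e_max = 1e-9, min_identity = 75,
                            alpha = 0.05, min_windows = 3L,
                            control_mode = "pooled", window_size = 500L) {
  all_refs <- rbind(references[, c("id", "sequence")],
                    controls[, c("id", "sequence")])
  idx <- reference_kmer_index(setNames(all_refs$sequence, all_refs$id))
  hits <- align_reads(reads, idx)
  hits <- filter_hits(hits, e_max = e_max, min_identity = min_identity)
  n_total <- length(reads)
  control_hits <- vapply(controls$id, function(cid) {
    sum(hits$reference_id == cid)
  }, integer(1))
  coverage <- list()
  ab <- list(); pres <- list()
  for (i in seq_len(nrow(references))) {
    rid <- references$id[i]
    rh <- hits[hits$reference_id == rid, , drop = FALSE]
    prof <- coverage_profile(rh, references$length_bp[i], window_size)
    coverage[[rid]] <- prof
    n_raw <- sum(prof$raw_counts)
    n_cor <- sum(prof$corrected_counts)
    n_norm <- normalize_count(n_cor, references$length_bp[i])
    ab[[rid]] <- data.frame(reference_id = rid, n_hits_raw = n_raw,
                            n_hits_corrected = n_cor,
                            n_hits_normalized = n_norm,
                            frequency = n_norm / n_total,
                            stringsAsFactors = FALSE)
    pc <- call_presence(prof$raw_counts, control_hits, n_total,
                        alpha = alpha, min_windows = min_windows,
                        control_mode = control_mode)
    pc <- cbind(data.frame(reference_id = rid, stringsAsFactors = FALSE), pc)
    pres[[rid]] <- pc
  }
  list(hits = hits, abundance = do.call(rbind, ab),
       presence = do.call(rbind, pres), coverage = coverage,
       control_hits = control_hits)
}
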