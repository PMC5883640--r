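# Sequence-level evidence of prophage activity: attL/attR direct repeats at
# integration sites, variable host flanks typical of transposable-phage
# headful packaging, coverage enrichment of induced prophages, and
# hypervariability of variable-repeat regions in mapped reads.

#' Find attL/attR direct repeats flanking an integrated prophage
#'
#' Searches the two host windows abutting the prophage borders for maximal
#' exact direct repeats with one copy in each flank, the signature of
#' site-specific integration. When the prophage sits at a contig edge only
#' the available flank is searched (and a warning is raised), which can
#' never yield a two-copy repeat.
#'
#' @param host_sequence host genome DNA string.
#' @param prophage_interval 0-based half-open interval of the prophage.
#' @param flank_window size (bp) of each flank window.
#' @param min_len minimal repeat length (>= 3).
#' @return `data.frame` sorted by decreasing length: `repeat_sequence`,
#'   `left_position`, `right_position` (0-based starts), `repeat_length_bp`.
#' @export
find_att_repeats <- function(host_sequence, prophage_interval,
                             flank_window = 500L, min_len = 5L) {
  stopifnot(min_len >= 3L)
  host <- genome_sequence(host_sequence)
  n <- nchar(host)
  iv <- check_interval(prophage_interval, upper = n, what = "prophage_interval")
  l0 <- max(0L, iv[1] - flank_window); l1 <- iv[1]       # [l0, l1)
  r0 <- iv[2]; r1 <- min(n, iv[2] + flank_window)        # [r0, r1)
  empty <- data.frame(repeat_sequence = character(0),
                      left_position = integer(0), right_position = integer(0),
                      repeat_length_bp = integer(0), stringsAsFactors = FALSE)
  if (l1 - l0 < min_len || r1 - r0 < min_len) {
    warning("prophage at contig edge: only one flank available, ",
            "no two-copy repeat can be found")
    return(empty)
  }
  left <- substr(host, l0 + 1L, l1)
  right <- substr(host, r0 + 1L, r1)
  mem <- maximal_exact_matches(left, right, min_len, strands = "+")
  if (nrow(mem) == 0L) return(empty)
  out <- data.frame(
    repeat_sequence = substring(left, mem$start_a, mem$start_a + mem$len - 1L),
    left_position = l0 + mem$start_a - 1L,
    right_position = r0 + mem$start_b - 1L,
    repeat_length_bp = mem$len, stringsAsFactors = FALSE)
  out <- out[order(-out$repeat_length_bp, out$left_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diversity of host flanks on encapsidated-DNA reads
#'
#' Selects reads whose alignment to the prophage covers one of its termini
#' and overhangs into non-phage sequence by at least `flank_min`
#' nucleotides, then clusters the junction-adjacent flank sequences at
#' `cluster_identity`. Headful packaging of a transposable prophage yields
#' many distinct flanks (high diversity); fixed-end (cos) packaging yields
#' none or one.
#'
#' @param reads named character vector of read sequences.
#' @param prophage_sequence the prophage DNA string.
#' @param terminus_window alignment must start within this distance of the
#'   terminus to count as terminal.
#' @param flank_min minimum overhang length (bp).
#' @param cluster_identity identity threshold for flank clustering.
#' @return `data.frame` with one row per terminus (`left`, `right`):
#'   `n_terminal_reads`, `n_distinct_flanks`, `flank_diversity` (`NA` and
#'   flagged `undefined` when no terminal reads exist).
#' @export
detect_variable_flanks <- function(reads, prophage_sequence,
                                   terminus_window = 100L, flank_min = 15L,
                                   cluster_identity = 0.9) {
  ref <- genome_sequence(prophage_sequence)
  n <- nchar(ref)
  idx <- reference_kmer_index(setNames(ref, "prophage"))
  flanks <- list(left = character(0), right = character(0))
  for (rd in reads) {
    hit <- align_read(rd, idx)[["prophage"]]
    if (is.null(hit)) next
    # map the overhanging read sequence adjacent to each covered terminus
    rseq <- if (hit$strand == "+") rd else revcomp(rd)
    # read coordinates below refer to the aligned orientation
    if (hit$ref_start == 0L && hit$read_start >= flank_min) {
      fl <- substr(rseq, hit$read_start - flank_min + 1L, hit$read_start)
      flanks$left <- c(flanks$left, fl)
    }
    if (hit$ref_end == n &&
        nchar(rseq) - hit$read_end >= flank_min) {
      fl <- substr(rseq, hit$read_end + 1L, hit$read_end + flank_min)
      flanks$right <- c(flanks$right, fl)
    }
  }
  one <- function(term) {
    fl <- flanks[[term]]
    nt <- length(fl)
    if (nt == 0L) {
      return(data.frame(terminus = term, n_terminal_reads = 0L,
                        n_distinct_flanks = 0L, flank_diversity = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    k <- cluster_sequences(fl, cluster_identity)
    data.frame(terminus = term, n_terminal_reads = nt,
               n_distinct_flanks = k, flank_diversity = k / nt,
               undefined = FALSE, stringsAsFactors = FALSE)
  }
  rbind(one("left"), one("right"))
}

# single-linkage clustering of short sequences at an identity threshold,
# via Levenshtein distance; returns the number of clusters
cluster_sequences <- function(seqs, identity = 0.9) {
  m <- length(seqs)
  if (m == 1L) return(1L)
  d <- adist(seqs)
  maxlen <- outer(nchar(seqs), nchar(seqs), pmax)
  sim <- 1 - d / maxlen
  g <- igraph::graph_from_adjacency_matrix(sim >= identity, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' Coverage fold enrichment of a prophage within its host
#'
#' Ratio of the mean read depth inside the prophage interval to the mean
#' depth over the rest of the host genome. Induced prophages show strong
#' enrichment over the host background.
#'
#' @param read_depths numeric vector of per-base depth along the host.
#' @param prophage_interval 0-based half-open interval.
#' @param host_length optional (defaults to `length(read_depths)`).
#' @return list with `fold`, `inside_mean`, `outside_mean`, `infinite`
#'   (`TRUE` when the outside depth is zero).
#' @export
prophage_coverage_fold <- function(read_depths, prophage_interval,
                                   host_length = length(read_depths)) {
  iv <- check_interval(prophage_interval, upper = host_length,
                       what = "prophage_interval")
  inside <- read_depths[(iv[1] + 1L):iv[2]]
  outside <- read_depths[-((iv[1] + 1L):iv[2])]
  if (length(outside) == 0L) stop("prophage interval covers the whole host",
                                  call. = FALSE)
  mi <- mean(inside); mo <- mean(outside)
  if (mo == 0) {
    return(list(fold = Inf, inside_mean = mi, outside_mean = 0,
                infinite = TRUE))
  }
  list(fold = mi / mo, inside_mean = mi, outside_mean = mo, infinite = FALSE)
}

#' Read variability in a variable-repeat region
#'
#' Column-wise mismatch frequency of aligned reads, contrasted between the
#' declared VR interval and the genome-wide baseline (excluding the VR).
#' Active diversity-generating retroelements produce read populations far
#' more variable over the VR than elsewhere.
#'
#' @param read_alignments detailed hit table from
#'   [align_reads()] with `details = TRUE` (columns `ref_start`, `ref_end`,
#'   list column `mismatch_positions` of 0-based reference positions).
#' @param genome genome row or DNA string (defines the length).
#' @param vr_interval 0-based half-open VR interval.
#' @param min_depth below this mean VR depth the result is flagged
#'   low-coverage.
#' @return list with `vr_rate`, `baseline_rate`, `ratio` (0 when the VR
#'   rate is 0; `Inf` when only the baseline is 0), `mean_vr_depth`,
#'   `low_coverage`.
#' @export
vr_variability <- function(read_alignments, genome, vr_interval,
                           min_depth = 5) {
  n <- nchar(genome_sequence(genome))
  iv <- check_interval(vr_interval, upper = n, what = "vr_interval")
  depth <- numeric(n)
  mm <- numeric(n)
  for (r in seq_len(nrow(read_alignments))) {
    a0 <- read_alignments$ref_start[r]; a1 <- read_alignments$ref_end[r]
    depth[(a0 + 1L):a1] <- depth[(a0 + 1L):a1] + 1
    mp <- read_alignments$mismatch_positions[[r]]
    if (length(mp)) mm[mp + 1L] <- mm[mp + 1L] + 1
  }
  vr_idx <- (iv[1] + 1L):iv[2]
  base_idx <- setdiff(which(depth > 0), vr_idx)
  vr_cov <- vr_idx[depth[vr_idx] > 0]
  vr_rate <- if (length(vr_cov)) mean(mm[vr_cov] / depth[vr_cov]) else NA_real_
  baseline <- if (length(base_idx)) mean(mm[base_idx] / depth[base_idx]) else NA_real_
  ratio <- if (is.na(vr_rate) || vr_rate == 0) 0
           else if (is.na(baseline) || baseline == 0) Inf
           else vr_rate / baseline
  mean_depth <- mean(depth[vr_idx])
  list(vr_rate = vr_rate, baseline_rate = baseline, ratio = ratio,
       mean_vr_depth = mean_depth, low_coverage = mean_depth < min_depth)
}
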