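# Detection of diversity-generating retroelement (DGR) cassettes: pairs of
# near-identical repeats (template repeat TR, variable repeat VR) whose
# mismatches sit almost exclusively at TR adenines, with the VR at the 3'
# end of a protein-coding gene.

#' Find near-identical repeat pairs within a genome
#'
#' Candidate repeats are discovered by shared k-mer anchoring (default
#' 14-mers: TR/VR identity is high enough that long exact anchors exist)
#' followed by ungapped X-drop extension, then filtered to the requested
#' length and identity window. The two copies must not overlap.
#'
#' @param genome genome row or DNA string.
#' @param min_len,max_len length window for the repeat (bp).
#' @param min_identity minimum percent identity between the two copies.
#' @param k anchor k-mer length.
#' @return `data.frame` with 0-based starts `pos1`, `pos2` (`pos1 < pos2`),
#'   `length`, `identity_percent`, `n_mismatch`, ordered by `pos1`.
#' @export
find_repeat_pairs <- function(genome, min_len = 80L, max_len = 150L,
                              min_identity = 75, k = 14L) {
  stopifnot(min_len <= max_len, min_identity > 0, min_identity <= 100)
  seq <- genome_sequence(genome)
  n <- nchar(seq)
  if (n <= max_len) stop("genome shorter than max_len", call. = FALSE)
  empty <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0), identity_percent = numeric(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE)
  tab <- kmer_table(seq, k)
  dup <- tab[, if (.N >= 2L && .N <= 20L) .SD, by = kmer]
  if (nrow(dup) == 0L) return(empty)
  pairs <- merge(dup, dup, by = "kmer", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))
  pairs <- pairs[pos_b > pos_a]
  if (nrow(pairs) == 0L) return(empty)
  runs <- merge_diagonal_runs(pairs[, list(pos_a, pos_b)], k)
  # extend each anchor run and collect candidate repeat spans
  chars <- strsplit(seq, "")[[1]]
  cand <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    ext <- extend_ungapped(chars, runs$start_a[r], runs$start_b[r],
                           runs$len[r], max_span = max_len + 30L)
    if (is.null(ext)) next
    if (ext[3] > max_len) {
      ext <- polish_span(chars, ext[1], ext[2], ext[3], max_len)
    }
    cand[[r]] <- ext
  }
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- as.data.frame(cand)
  names(cand) <- c("i0", "j0", "len", "mm")
  cand$identity <- 100 * (cand$len - cand$mm) / cand$len
  cand <- cand[cand$len >= min_len & cand$len <= max_len &
               cand$identity >= min_identity &
               cand$j0 > cand$i0 + cand$len - 1L, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # dedupe overlapping candidates (same repeat found from several anchors)
  cand <- cand[order(-cand$len * cand$identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      ov <- pmin(cand$i0[later] + cand$len[later], cand$i0[i] + cand$len[i]) -
            pmax(cand$i0[later], cand$i0[i]) > 0 &
            pmin(cand$j0[later] + cand$len[later], cand$j0[i] + cand$len[i]) -
            pmax(cand$j0[later], cand$j0[i]) > 0
      keep[later][ov] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(pos1 = as.integer(cand$i0 - 1L),
                    pos2 = as.integer(cand$j0 - 1L),
                    length = as.integer(cand$len),
                    identity_percent = cand$identity,
                    n_mismatch = as.integer(cand$mm),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Ungapped X-drop extension of an exact anchor at 1-based (i0, j0), length
# len. Match +1 / mismatch -2; the drop is generous so clustered internal
# mismatches do not truncate the repeat — boundary cleanup is done
# afterwards by polish_span(). Returns c(i0, j0, len, mismatches) for the
# best-scoring span, or NULL.
extend_ungapped <- function(chars, i0, j0, len, x_drop = 12L,
                            max_span = 200L) {
  n <- length(chars)
  # right extension
  best_r <- 0L; sc <- 0; best_sc <- 0
  ir <- i0 + len; jr <- j0 + len; steps <- 0L
  while (ir + steps <= n && jr + steps <= n && steps < max_span &&
         jr + steps <= n) {
    if (ir + steps > j0) break  # do not run into the second copy
    sc <- sc + if (chars[ir + steps] == chars[jr + steps]) 1 else -2
    steps <- steps + 1L
    if (sc > best_sc) { best_sc <- sc; best_r <- steps }
    if (best_sc - sc > x_drop) break
  }
  # left extension
  best_l <- 0L; sc <- 0; best_sc <- 0
  steps <- 0L
  while (i0 - 1L - steps >= 1L && j0 - 1L - steps >= 1L && steps < max_span) {
    if (j0 - 1L - steps <= i0 + len - 1L + best_r) break
    sc <- sc + if (chars[i0 - 1L - steps] == chars[j0 - 1L - steps]) 1 else -2
    steps <- steps + 1L
    if (sc > best_sc) { best_sc <- sc; best_l <- steps }
    if (best_sc - sc > x_drop) break
  }
  i <- i0 - best_l; j <- j0 - best_l
  L <- len + best_l + best_r
  if (j <= i + L - 1L) return(NULL)
  mm <- sum(chars[i:(i + L - 1L)] != chars[j:(j + L - 1L)])
  c(i, j, L, mm)
}

# Boundary cleanup of an extended span. Chance matches beyond the true
# repeat boundary drag in spurious terminal mismatches; requiring each end
# to open with at least 4 consecutive matches removes them (a genuine
# polymorphic site close to an end is trimmed with no harm — it only
# removes one mismatch from the tally). Spans longer than max_len are
# shaved back through their outermost mismatches, which is where a
# boundary overshoot always ends.
polish_span <- function(chars, i, j, L, max_len, clean_end = 4L) {
  repeat {
    mmpos <- which(chars[i:(i + L - 1L)] != chars[j:(j + L - 1L)])
    changed <- FALSE
    if (length(mmpos)) {
      if (mmpos[1] <= clean_end) {
        cut <- mmpos[1]
        i <- i + cut; j <- j + cut; L <- L - cut
        changed <- TRUE
      } else if (L - mmpos[length(mmpos)] <= clean_end - 1L) {
        L <- mmpos[length(mmpos)] - 1L
        changed <- TRUE
      } else if (L > max_len) {
        dl <- mmpos[1]; dr <- L - mmpos[length(mmpos)] + 1L
        if (min(dl, dr) <= 20L) {
          if (dl <= dr) {
            i <- i + dl; j <- j + dl; L <- L - dl
          } else {
            L <- mmpos[length(mmpos)] - 1L
          }
          changed <- TRUE
        }
      }
    }
    if (!changed || L < 20L) break
  }
  mm <- if (L >= 1L) sum(chars[i:(i + L - 1L)] != chars[j:(j + L - 1L)]) else 0L
  c(i, j, L, mm)
}

#' Classify a repeat pair as TR/VR by adenine-polarized mismatches
#'
#' For each orientation hypothesis (copy 1 or copy 2 is the template
#' repeat, read on either strand), computes the fraction of mismatched
#' columns whose putative-TR base is adenine on that strand. The hypothesis
#' maximizing this fraction is accepted if the maximum reaches
#' `min_adenine_frac` (the operational reading of "differing almost
#' exclusively at template adenines"); ties and invariant repeats are
#' rejected.
#'
#' @param pair one row of [find_repeat_pairs()] output (or a list with
#'   `pos1`, `pos2`, `length`).
#' @param genome genome row or DNA string.
#' @param min_adenine_frac acceptance threshold on the adenine fraction.
#' @return list with `accepted` (logical), `reason` (when rejected),
#'   `orientation` (`"copy1_is_tr"` / `"copy2_is_tr"`), `tr_strand`,
#'   `adenine_mismatch_fraction`, `polymorphic_sites`, `identity_percent`.
#' @export
classify_tr_vr <- function(pair, genome, min_adenine_frac = 0.8) {
  seq <- genome_sequence(genome)
  L <- pair$length[1]
  s1 <- substring(seq, pair$pos1[1] + 1L, pair$pos1[1] + L)
  s2 <- substring(seq, pair$pos2[1] + 1L, pair$pos2[1] + L)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  mm <- which(c1 != c2)
  if (length(mm) == 0L) {
    return(list(accepted = FALSE, reason = "invariant repeat"))
  }
  # four hypotheses: either copy is the TR, read on either strand (a TR
  # adenine on the minus strand appears as T on the forward sequence)
  f <- c(`copy1_is_tr.+` = mean(c1[mm] == "A"),
         `copy2_is_tr.+` = mean(c2[mm] == "A"),
         `copy1_is_tr.-` = mean(c1[mm] == "T"),
         `copy2_is_tr.-` = mean(c2[mm] == "T"))
  if (max(f) < min_adenine_frac) {
    return(list(accepted = FALSE, reason = "not adenine-polarized"))
  }
  if (sum(f == max(f)) > 1L) {
    return(list(accepted = FALSE, reason = "ambiguous orientation"))
  }
  best <- names(f)[which.max(f)]
  parts <- strsplit(best, ".", fixed = TRUE)[[1]]
  list(accepted = TRUE, reason = NA_character_,
       orientation = parts[1], tr_strand = parts[2],
       adenine_mismatch_fraction = unname(max(f)),
       polymorphic_sites = length(mm),
       identity_percent = 100 * (L - length(mm)) / L)
}

#' Locate the gene targeted by a variable repeat
#'
#' Returns the ORF whose 3'-terminal third (strand-aware) overlaps the VR
#' interval by at least half of the VR length; `NULL` when no ORF
#' qualifies. Among several candidates the one with the largest overlap
#' wins (then the first by start).
#'
#' @param vr_interval 0-based half-open interval `c(start, end)`.
#' @param orfs ORF table from [predict_orfs()] on the same genome.
#' @return a one-row ORF `data.frame`, or `NULL`.
#' @export
locate_target <- function(vr_interval, orfs) {
  if (nrow(orfs) == 0L) return(NULL)
  check_interval(vr_interval, what = "vr_interval")
  len <- orfs$end - orfs$start
  third <- floor(len / 3)
  t0 <- ifelse(orfs$strand == "+", orfs$end - third, orfs$start)
  t1 <- ifelse(orfs$strand == "+", orfs$end, orfs$start + third)
  ov <- pmin(t1, vr_interval[2]) - pmax(t0, vr_interval[1])
  ok <- ov >= 0.5 * (vr_interval[2] - vr_interval[1])
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(-ov[cand], orfs$start[cand])][1]
  orfs[best, , drop = FALSE]
}

#' Call DGR cassettes in a genome
#'
#' Composition of [find_repeat_pairs()], [classify_tr_vr()] and
#' [locate_target()]: a cassette is reported when a repeat pair in the
#' length/identity window has adenine-polarized mismatches and its variable
#' copy sits at the 3' end of a gene. An additional length gate (default
#' 100-135 bp, the range observed for this element family) is applied to
#' accepted cassettes. A genome "has a DGR" iff at least one cassette is
#' returned.
#'
#' @param genome genome row or DNA string.
#' @param orfs optional precomputed ORF table.
#' @param min_len,max_len,min_identity,k candidate discovery settings, see
#'   [find_repeat_pairs()].
#' @param accept_len length window applied to accepted cassettes.
#' @param min_adenine_frac see [classify_tr_vr()].
#' @return `data.frame`, one row per cassette: `genome_id`, `tr_start`,
#'   `tr_end`, `vr_start`, `vr_end`, `repeat_length_bp`, `identity_percent`,
#'   `polymorphic_sites`, `adenine_mismatch_fraction`, `orientation`,
#'   `tr_strand`, `target_start`, `target_end`, `target_strand`.
#' @export
call_dgrs <- function(genome, orfs = NULL, min_len = 80L, max_len = 150L,
                      min_identity = 75, k = 14L,
                      accept_len = c(100L, 135L), min_adenine_frac = 0.8) {
  gid <- genome_id_of(genome)
  if (is.null(orfs)) orfs <- predict_orfs(genome)
  pairs <- find_repeat_pairs(genome, min_len = min_len, max_len = max_len,
                             min_identity = min_identity, k = k)
  empty <- data.frame(genome_id = character(0), tr_start = integer(0),
                      tr_end = integer(0), vr_start = integer(0),
                      vr_end = integer(0), repeat_length_bp = integer(0),
                      identity_percent = numeric(0),
                      polymorphic_sites = integer(0),
                      adenine_mismatch_fraction = numeric(0),
                      orientation = character(0), tr_strand = character(0),
                      target_start = integer(0),
                      target_end = integer(0), target_strand = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  out <- list()
  chars <- strsplit(genome_sequence(genome), "")[[1]]
  for (r in seq_len(nrow(pairs))) {
    p_raw <- pairs[r, ]
    # the raw maximal span is classified first; if it fails the cassette
    # length gate or the adenine rule (chance boundary mismatches can
    # dilute it), the boundary-polished span gets a second look
    ps <- polish_span(chars, p_raw$pos1 + 1L, p_raw$pos2 + 1L,
                      p_raw$length, accept_len[2])
    p_pol <- p_raw
    p_pol$pos1 <- ps[1] - 1L; p_pol$pos2 <- ps[2] - 1L
    p_pol$length <- ps[3]; p_pol$n_mismatch <- ps[4]
    p_pol$identity_percent <- 100 * (ps[3] - ps[4]) / ps[3]
    variants <- if (identical(p_pol$pos1, p_raw$pos1) &&
                    identical(p_pol$length, p_raw$length)) {
      list(p_raw)
    } else {
      list(p_raw, p_pol)
    }
    for (p in variants) {
      if (p$length < accept_len[1] || p$length > accept_len[2]) next
      cls <- classify_tr_vr(p, genome, min_adenine_frac)
      if (!isTRUE(cls$accepted)) next
      if (cls$orientation == "copy1_is_tr") {
        tr <- c(p$pos1, p$pos1 + p$length)
        vr <- c(p$pos2, p$pos2 + p$length)
      } else {
        tr <- c(p$pos2, p$pos2 + p$length)
        vr <- c(p$pos1, p$pos1 + p$length)
      }
      target <- locate_target(vr, orfs)
      if (is.null(target)) next
      out[[length(out) + 1L]] <- data.frame(
        genome_id = gid, tr_start = tr[1], tr_end = tr[2],
        vr_start = vr[1], vr_end = vr[2],
        repeat_length_bp = p$length, identity_percent = cls$identity_percent,
        polymorphic_sites = cls$polymorphic_sites,
        adenine_mismatch_fraction = cls$adenine_mismatch_fraction,
        orientation = cls$orientation, tr_strand = cls$tr_strand,
        target_start = target$start, target_end = target$end,
        target_strand = target$strand, stringsAsFactors = FALSE)
      break
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' DGR census over a genome set
#'
#' @param genomes a [phage_genome_set()] table.
#' @param ... passed to [call_dgrs()].
#' @return list with `cassettes` (all cassettes found) and `census`
#'   (`genome_id`, `n_cassettes`, `has_dgr`).
#' @export
dgr_census <- function(genomes, ...) {
  cass <- lapply(seq_len(nrow(genomes)), function(i) {
    call_dgrs(genomes[i, ], ...)
  })
  cass <- do.call(rbind, cass)
  n <- vapply(genomes$id, function(g) sum(cass$genome_id == g), integer(1))
  list(cassettes = cass,
       census = data.frame(genome_id = genomes$id, n_cassettes = as.integer(n),
                           has_dgr = n > 0L, stringsAsFactors = FALSE))
}
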