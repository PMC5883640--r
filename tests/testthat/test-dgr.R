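# plant a repeat pair directly into a random background (no ORF machinery)
plant_pair <- function(bg_len = 8000, rep_len = 120, n_mm = 10, seed = 1) {
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), bg_len, TRUE), collapse = "")
  tr <- paste(sample(c("A", "C", "G", "T"), rep_len, TRUE), collapse = "")
  ch <- strsplit(tr, "")[[1]]
  mm <- sort(sample(rep_len, n_mm))
  ch[mm] <- vapply(ch[mm], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  vr <- paste(ch, collapse = "")
  p1 <- 1000L; p2 <- 5000L
  seq <- paste0(substr(bg, 1, p1), tr,
                substr(bg, p1 + 1, p2), vr,
                substr(bg, p2 + 1, bg_len))
  list(seq = seq, pos1 = p1, pos2 = p2 + rep_len, len = rep_len, n_mm = n_mm)
}

test_that("a planted diverged repeat pair is recovered at its coordinates", {
  pl <- plant_pair(rep_len = 120, n_mm = 10, seed = 5)  # ~92% identity
  got <- find_repeat_pairs(pl$seq)
  expect_equal(nrow(got), 1L)
  # the planted interval, give or take chance matches at the boundaries
  expect_lte(abs(got$pos1 - pl$pos1), 3L)
  expect_lte(abs(got$pos2 - pl$pos2), 3L)
  expect_lte(abs(got$length - pl$len), 4L)
  expect_gte(got$n_mismatch, pl$n_mm)
  expect_gte(got$identity_percent, 90)
})

test_that("a perfect tandem duplication is reported with identity 100", {
  set.seed(6)
  unit <- paste(sample(c("A", "C", "G", "T"), 110, TRUE), collapse = "")
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 1500), unit, unit, substr(bg, 1501, 3000))
  got <- find_repeat_pairs(seq)
  expect_equal(nrow(got), 1L)
  expect_equal(got$identity_percent, 100)
  expect_equal(got$length, 110L)
})

test_that("random sequence contains no repeat pairs (quadratic-scan oracle)", {
  # oracle: best windowed identity over every diagonal offset
  oracle_has_pair <- function(seq, min_len, min_identity) {
    ch <- strsplit(seq, "")[[1]]; n <- length(ch)
    for (d in min_len:(n - min_len)) {
      eq <- ch[seq_len(n - d)] == ch[(d + 1):n]
      cs <- cumsum(eq)
      w <- min_len
      if (length(eq) < w) next
      wins <- cs[w:length(cs)] - c(0, cs[seq_len(length(cs) - w)])
      if (any(wins / w >= min_identity / 100)) return(TRUE)
    }
    FALSE
  }
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_false(oracle_has_pair(seq, 80L, 75))
  expect_equal(nrow(find_repeat_pairs(seq)), 0L)
  # and the oracle does see a planted pair that the detector reports
  pl <- plant_pair(bg_len = 5000, seed = 8)
  expect_true(oracle_has_pair(pl$seq, 80L, 75))
  expect_gt(nrow(find_repeat_pairs(pl$seq)), 0L)
})

test_that("TR/VR classification keys on adenine-polarized mismatches", {
  tr <- "GGCATACAGT"; vr <- "GGCCTCCGGT"
  genome <- paste0(tr, strrep("C", 40), vr)
  pair <- list(pos1 = 0L, pos2 = 50L, length = 10L)
  cls <- classify_tr_vr(pair, genome)
  expect_true(cls$accepted)
  expect_equal(cls$orientation, "copy1_is_tr")
  expect_equal(cls$adenine_mismatch_fraction, 1.0)
  expect_equal(cls$polymorphic_sites, 3L)

  # identical copies: invariant repeat
  g2 <- paste0(tr, strrep("C", 40), tr)
  cls2 <- classify_tr_vr(pair, g2)
  expect_false(cls2$accepted)
  expect_match(cls2$reason, "invariant")

  # mismatches on non-adenine bases in both orientations: rejected
  g3 <- paste0("GGCGTGCGGT", strrep("C", 40), "GGCCTCCGGT")
  cls3 <- classify_tr_vr(pair, g3)
  expect_false(cls3$accepted)
})

test_that("target location demands VR overlap with a gene 3'-terminal third", {
  orfs <- data.frame(genome_id = "g", start = c(1000L, 5000L),
                     end = c(2200L, 6200L), strand = c("+", "-"),
                     protein = c("M", "M"))
  # VR inside the last third of the forward ORF
  hit <- locate_target(c(2000L, 2100L), orfs)
  expect_equal(hit$start, 1000L)
  # intergenic VR: nothing
  expect_null(locate_target(c(3000L, 3100L), orfs))
  # VR at the 5' end of the forward ORF: nothing
  expect_null(locate_target(c(1010L, 1110L), orfs))
  # minus-strand gene: its 3' end is at the genome-left side
  hit2 <- locate_target(c(5050L, 5150L), orfs)
  expect_equal(hit2$strand, "-")
  expect_null(locate_target(c(6050L, 6150L), orfs))
})

test_that("planted cassettes are called with matching coordinates and are
           mirrored under reverse complement", {
  g <- small_genome(12000, seed = 91)
  pl <- plant_dgr(g, tr_length = 120L, n_adenine_sites = 10L, seed = 92)
  cas <- call_dgrs(pl$genome)
  expect_equal(nrow(cas), 1L)
  expect_lte(abs(cas$tr_start - pl$cassette$tr_start), 6L)
  expect_lte(abs(cas$tr_end - pl$cassette$tr_end), 6L)
  expect_lte(abs(cas$vr_start - pl$cassette$vr_start), 6L)
  expect_lte(abs(cas$vr_end - pl$cassette$vr_end), 6L)
  expect_equal(cas$target_start, pl$cassette$target_start)
  expect_gte(cas$adenine_mismatch_fraction, 0.8)

  n <- nchar(pl$genome$sequence)
  rc <- call_dgrs(revcomp(pl$genome$sequence))
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$tr_start, n - cas$tr_end)
  expect_equal(rc$vr_start, n - cas$vr_end)
  expect_equal(rc$repeat_length_bp, cas$repeat_length_bp)
  expect_equal(rc$tr_strand, "-")
})

test_that("planted invariant repeats (no adenine sites) are not called", {
  g <- small_genome(12000, seed = 95)
  pl <- plant_dgr(g, tr_length = 120L, n_adenine_sites = 0L, seed = 96)
  # the repeat pair is found but rejected as invariant
  pairs <- find_repeat_pairs(pl$genome)
  expect_gte(nrow(pairs), 1L)
  expect_equal(nrow(call_dgrs(pl$genome)), 0L)
})

test_that("cassette recovery is sensitive and specific over simulations", {
  hits <- 0L; n_sim <- 25L
  set.seed(99)
  for (i in seq_len(n_sim)) {
    g <- small_genome(10000, seed = 200 + i)
    pl <- plant_dgr(g, tr_length = sample(105:130, 1), seed = 300 + i)
    cas <- call_dgrs(pl$genome)
    # boundary jitter of a few bases (chance matches beyond the planted
    # repeat) is expected of any maximal-span detector
    if (nrow(cas) >= 1L && abs(cas$tr_start[1] - pl$cassette$tr_start) <= 10L &&
        abs(cas$vr_start[1] - pl$cassette$vr_start) <= 10L) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_sim, 0.95)
  # cassette-free genomes of matched composition: no calls
  false_calls <- sum(vapply(1:10, function(i) {
    nrow(call_dgrs(small_genome(10000, seed = 400 + i)))
  }, integer(1)))
  expect_equal(false_calls, 0L)
})
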