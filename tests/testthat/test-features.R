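random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("integration-site direct repeats are recovered after planting", {
  host <- random_dna(8000, seed = 1)
  phage <- random_dna(3000, seed = 2)
  ip <- integrate_prophage(host, phage, att_length = 12L,
                           mode = "site_specific", seed = 3)
  tr <- ip$truth
  att <- find_att_repeats(ip$host_sequence,
                          c(tr$prophage_start, tr$prophage_end))
  expect_gte(nrow(att), 1L)
  # the planted repeat is the longest (spurious 12-mers are essentially
  # impossible in 500-bp windows)
  expect_equal(att$repeat_sequence[1], tr$att_sequence)
  expect_equal(att$left_position[1], tr$att_left)
  expect_equal(att$right_position[1], tr$att_right)
  expect_equal(att$repeat_length_bp[1], 12L)
})

test_that("a 5-bp direct repeat is found at min_len = 5", {
  host <- random_dna(6000, seed = 11)
  phage <- random_dna(2500, seed = 12)
  ip <- integrate_prophage(host, phage, att_length = 5L,
                           mode = "site_specific", seed = 13)
  tr <- ip$truth
  att <- find_att_repeats(ip$host_sequence,
                          c(tr$prophage_start, tr$prophage_end), min_len = 5L)
  planted <- att[att$left_position == tr$att_left &
                 att$right_position == tr$att_right, ]
  expect_gte(nrow(planted), 1L)
  expect_equal(substr(planted$repeat_sequence[1], 1, 5), tr$att_sequence)
})

test_that("flank windows without common words yield no repeats", {
  host <- paste0(strrep("A", 200), strrep("G", 300), strrep("C", 200))
  att <- find_att_repeats(host, c(200L, 500L), flank_window = 200L)
  expect_equal(nrow(att), 0L)
})

test_that("contig-edge prophages trigger a warning and an empty result", {
  host <- random_dna(2000, seed = 21)
  expect_warning(att <- find_att_repeats(host, c(0L, 1500L)), "flank")
  expect_equal(nrow(att), 0L)
})

test_that("att search is invariant under translating the host", {
  host <- random_dna(5000, seed = 31)
  phage <- random_dna(2000, seed = 32)
  ip <- integrate_prophage(host, phage, att_length = 10L,
                           mode = "site_specific", seed = 33)
  iv <- c(ip$truth$prophage_start, ip$truth$prophage_end)
  a1 <- find_att_repeats(ip$host_sequence, iv)
  pad <- random_dna(137, seed = 34)
  a2 <- find_att_repeats(paste0(pad, ip$host_sequence), iv + 137L)
  expect_equal(a2$left_position, a1$left_position + 137L)
  expect_equal(a2$right_position, a1$right_position + 137L)
  expect_equal(a2$repeat_sequence, a1$repeat_sequence)
})

test_that("headful packaging shows variable flanks, cos packaging does not", {
  phage <- small_genome(6000, seed = 41)$sequence
  host <- random_dna(30000, seed = 42)
  headful <- simulate_packaged_reads(phage, host, "headful", n_reads = 40,
                                     seed = 43)
  fp <- detect_variable_flanks(headful, phage)
  expect_gte(sum(fp$n_terminal_reads), 10L)
  expect_true(all(fp$flank_diversity[fp$n_terminal_reads > 0] >= 0.9))

  cos <- simulate_packaged_reads(phage, packaging = "cos", n_reads = 20,
                                 seed = 44)
  fc <- detect_variable_flanks(cos, phage)
  expect_true(all(fc$n_distinct_flanks <= 1L))

  # read order must not matter
  fp2 <- detect_variable_flanks(rev(headful), phage)
  expect_equal(fp2$flank_diversity, fp$flank_diversity)
})

test_that("eight reads with eight distinct planted flanks give diversity 1", {
  phage <- small_genome(4000, seed = 51)$sequence
  reads <- vapply(1:8, function(i) {
    paste0(random_dna(60, seed = 60 + i), substr(phage, 1, 190))
  }, character(1))
  names(reads) <- paste0("r", 1:8)
  fp <- detect_variable_flanks(reads, phage)
  left <- fp[fp$terminus == "left", ]
  expect_equal(left$n_terminal_reads, 8L)
  expect_equal(left$flank_diversity, 1.0)
})

test_that("coverage fold enrichment behaves over the depth vector", {
  depth <- rep(5, 10000)
  expect_equal(prophage_coverage_fold(depth, c(2000L, 5000L))$fold, 1.0)

  set.seed(61)
  depth <- rpois(20000, 5)
  depth[4001:8000] <- rpois(4000, 80)
  cf <- prophage_coverage_fold(depth, c(4000L, 8000L))
  expect_equal(cf$fold, 16, tolerance = 1 / 16)
  # scale invariance
  cf2 <- prophage_coverage_fold(depth * 3.7, c(4000L, 8000L))
  expect_equal(cf2$fold, cf$fold)

  z <- c(rep(0, 100), rep(4, 50), rep(0, 100))
  czf <- prophage_coverage_fold(z, c(100L, 150L))
  expect_true(czf$infinite)
  expect_equal(czf$fold, Inf)
  expect_error(prophage_coverage_fold(depth, c(3000L, 3000L)), "interval")
})

test_that("VR hypervariability is detected against the genome baseline", {
  g <- small_genome(5000, seed = 71)
  seq <- g$sequence
  vr <- c(2000L, 2120L)
  mutate_reads <- function(n, vr_sub, base_sub, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      p <- sample(nchar(seq) - 250L, 1)
      r <- strsplit(substr(seq, p, p + 249L), "")[[1]]
      pos <- p - 1L + seq_along(r) - 1L          # 0-based genome positions
      in_vr <- pos >= vr[1] & pos < vr[2]
      hit <- (in_vr & r == "A" & runif(250) < vr_sub) |
             (runif(250) < base_sub)
      r[hit] <- vapply(r[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(r, collapse = "")
    }, character(1))
  }
  reads <- setNames(mutate_reads(250, 0.5, 0.005, 72), paste0("r", 1:250))
  hits <- align_reads(reads, setNames(seq, "g1"), details = TRUE)
  vv <- vr_variability(hits, seq, vr)
  expect_gte(vv$ratio, 10)
  expect_false(vv$low_coverage)

  clean <- setNames(mutate_reads(40, 0, 0, 73), paste0("c", 1:40))
  hc <- align_reads(clean, setNames(seq, "g1"), details = TRUE)
  vvc <- vr_variability(hc, seq, vr)
  expect_equal(vvc$vr_rate, 0)
  expect_equal(vvc$ratio, 0)

  # variability planted elsewhere must not inflate the declared VR
  far <- setNames(mutate_reads(80, 0, 0.002, 74), paste0("f", 1:80))
  # inject heavy mutations in a different window by relabeling the VR
  hf <- align_reads(setNames(mutate_reads(80, 0.5, 0.002, 75),
                             paste0("h", 1:80)), setNames(seq, "g1"),
                    details = TRUE)
  vvf <- vr_variability(hf, seq, c(4000L, 4120L))
  expect_lte(vvf$ratio, 1.5)
})
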