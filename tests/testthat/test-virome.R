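test_that("verbatim reads align perfectly; foreign reads do not align", {
  ref <- small_genome(20000, seed = 1)
  reads <- c(r1 = substr(ref$sequence, 5001, 5250),
             r2 = revcomp(substr(ref$sequence, 9001, 9250)))
  hits <- align_reads(reads, setNames(ref$sequence, "ref"))
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$identity_percent == 100))
  expect_true(all(hits$e_value < 1e-9))
  h1 <- hits[hits$read_id == "r1", ]
  expect_equal(h1$ref_start, 5000L)
  expect_equal(h1$ref_end, 5250L)
  expect_equal(hits$strand[hits$read_id == "r2"], "-")

  set.seed(2)
  foreign <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  expect_equal(nrow(align_reads(c(f = foreign),
                                setNames(ref$sequence, "ref"))), 0L)
})

test_that("divergent reads report identities matching the mutation truth", {
  ref <- small_genome(20000, seed = 11)
  set.seed(12)
  ids <- numeric(0); truth <- numeric(0)
  reads <- character(0)
  for (i in 1:25) {
    p <- sample(nchar(ref$sequence) - 250L, 1)
    clean <- substr(ref$sequence, p, p + 249L)
    mut <- mutate_genome_nt(clean, 0.20)
    truth <- c(truth, 100 * mean(strsplit(clean, "")[[1]] ==
                                 strsplit(mut, "")[[1]]))
    reads <- c(reads, mut)
  }
  names(reads) <- paste0("r", 1:25)
  hits <- align_reads(reads, setNames(ref$sequence, "ref"))
  expect_gte(nrow(hits), 20L)
  # measured identities track the per-read planted identity (local
  # alignment trims noisy ends, so allow a small upward bias)
  m <- match(hits$read_id, names(reads))
  expect_lt(mean(abs(hits$identity_percent - truth[m])), 4)
  expect_equal(mean(hits$identity_percent), 80, tolerance = 0.05)
})

test_that("hit filtering applies strict inequalities", {
  hits <- data.frame(read_id = paste0("r", 1:4), reference_id = "x",
                     identity_percent = c(75, 76, 90, 74.9),
                     alignment_length_bp = 250L,
                     e_value = c(1e-12, 1e-12, 1e-9, 1e-30),
                     ref_start = 0L, ref_end = 250L, strand = "+")
  kept <- filter_hits(hits)
  expect_equal(kept$read_id, "r2")  # 75.0 removed (strict >), 1e-9 removed
  # brute-force predicate parity on a random table
  set.seed(21)
  tab <- data.frame(read_id = paste0("r", 1:200), reference_id = "x",
                    identity_percent = runif(200, 60, 100),
                    alignment_length_bp = 250L,
                    e_value = 10^runif(200, -30, -3),
                    ref_start = 0L, ref_end = 250L, strand = "+")
  expect_equal(filter_hits(tab),
               tab[tab$e_value < 1e-9 & tab$identity_percent > 75, ])
})

test_that("normalization rescales counts to a 50-kb genome", {
  expect_equal(normalize_count(100, 25000), 200)
  expect_equal(normalize_count(100, 50000), 100)
  expect_equal(normalize_count(0, 31000), 0)
  expect_error(normalize_count(10, 0), "positive")
  # linearity
  expect_equal(normalize_count(7 * 13, 31000),
               7 * normalize_count(13, 31000))
})

test_that("spurious window correction follows the 10x-median rule exactly", {
  expect_equal(spurious_correction(c(1, 1, 1, 1, 100)), c(1, 1, 1, 1, 10))
  expect_equal(spurious_correction(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(spurious_correction(c(0, 0, 2, 2, 3)), c(0, 0, 2, 2, 3))
  expect_equal(spurious_correction(numeric(0)), numeric(0))
  expect_equal(spurious_correction(c(0, 0, 0)), c(0, 0, 0))
  # idempotent, never increasing
  set.seed(31)
  for (i in 1:20) {
    x <- rpois(50, sample(c(1, 5, 20), 1))
    x[sample(50, 2)] <- x[sample(50, 2)] + sample(0:500, 2)
    y <- spurious_correction(x)
    expect_true(all(y <= x))
    expect_equal(spurious_correction(y), y)
  }
})

test_that("coverage windows tile from zero and use hit midpoints", {
  hits <- data.frame(ref_start = c(0L, 499L, 990L, 1400L),
                     ref_end = c(250L, 749L, 1240L, 1650L))
  prof <- coverage_profile(hits, reference_length = 1700L)
  # midpoints 125, 624, 1115, 1525 -> windows 1, 2, 3, 4 (last partial)
  expect_equal(length(prof$raw_counts), 4L)
  expect_equal(prof$raw_counts, c(1L, 1L, 1L, 1L))
  expect_equal(prof$n_nonzero_windows, 4L)
})

test_that("the two-proportion z-test matches its sampling distribution", {
  r0 <- two_prop_z(30, 300, 20, 200, tail = "greater")
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 0.5)

  r <- two_prop_z(50, 1000, 10, 1000, tail = "greater")
  expect_lt(r$p, 1e-4)
  # Monte-Carlo permutation oracle: permute the 60 successes over the
  # pooled 2000 trials
  set.seed(41)
  perm <- replicate(20000, {
    x1s <- sum(sample(2000, 60) <= 1000)
    x1s
  })
  p_perm <- mean(perm >= 50)
  expect_lt(p_perm, 1e-3)

  # moderate case: normal approximation close to the permutation law
  r2 <- two_prop_z(30, 1000, 18, 1000, tail = "greater")
  perm2 <- replicate(20000, sum(sample(2000, 48) <= 1000))
  expect_equal(r2$p, mean(perm2 >= 30), tolerance = 0.25)

  # swapping groups negates z and keeps the two-sided p
  a <- two_prop_z(40, 500, 20, 400, tail = "two.sided")
  b <- two_prop_z(20, 400, 40, 500, tail = "two.sided")
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(two_prop_z(0, 0, 1, 10), "sample sizes")
})

test_that("presence calls follow the exclusion and contamination rules", {
  # only 2 covered windows: excluded no matter how many hits
  counts <- integer(100); counts[c(3, 50)] <- c(200, 300)
  pc <- call_presence(counts, control_hits = c(1, 1), n_total_reads = 1e6)
  expect_equal(pc$call, "excluded")

  # 50 phage hits vs pooled controls 2 in a million reads: positive
  counts <- integer(100); counts[sample(100, 25)] <- 2L
  pc2 <- call_presence(counts, control_hits = c(1, 1), n_total_reads = 1e6)
  expect_equal(pc2$call, "positive")
  expect_lt(pc2$p_value, 0.05)
  # exact conditional binomial oracle: given 52 hits split between phage
  # and (pooled) control streams of equal exposure, both laws call this
  # overwhelmingly significant, and they order cases identically
  p_binom <- pbinom(49, 52, 0.5, lower.tail = FALSE)
  expect_lt(p_binom, 1e-4)
  expect_lt(pc2$p_value, 1e-4)
  weaker <- call_presence({x <- integer(100); x[sample(100, 4)] <- 1L; x},
                          control_hits = c(1, 1), n_total_reads = 1e6)
  p_binom_weak <- pbinom(3, 6, 0.5, lower.tail = FALSE)
  expect_lt(pc2$p_value, weaker$p_value)
  expect_lt(p_binom, p_binom_weak)

  # equal proportions: negative
  counts3 <- integer(100); counts3[1:10] <- 1L
  pc3 <- call_presence(counts3, control_hits = c(5, 5),
                       n_total_reads = 1e6)
  expect_equal(pc3$call, "negative")
  expect_error(call_presence(counts3, control_hits = numeric(0),
                             n_total_reads = 1e6), "control")
})

test_that("presence calling controls type I error and detects spike-ins", {
  set.seed(51)
  n_reads <- 1e6; p_contam <- 2e-5
  spread <- function(n_hits, n_windows = 100L) {
    w <- integer(n_windows)
    if (n_hits > 0) {
      t <- table(sample(n_windows, n_hits, TRUE))
      w[as.integer(names(t))] <- as.integer(t)
    }
    w
  }
  # phage truly at the per-region contamination level
  fp <- sum(replicate(300, {
    ph <- spread(rbinom(1, n_reads, p_contam))
    call_presence(ph, rbinom(2, n_reads, p_contam), n_reads)$call
  }) == "positive")
  expect_lte(fp / 300, 0.07)

  # 10x the contamination level with >= 30 expected hits
  tp <- sum(replicate(200, {
    ph <- spread(rbinom(1, n_reads, 10 * p_contam))
    call_presence(ph, rbinom(2, n_reads, p_contam), n_reads)$call
  }) == "positive")
  expect_gte(tp / 200, 0.95)
})

test_that("normalized frequencies are comparable across genome lengths", {
  # equal molar abundance of a 25-kb and a 50-kb phage: read counts are
  # proportional to length, normalized counts agree within binomial noise
  set.seed(61)
  n_reads <- 1e6
  molar <- 2e-4
  for (i in 1:5) {
    hits_a <- rbinom(1, n_reads, molar * 25000 / 50000)
    hits_b <- rbinom(1, n_reads, molar)
    fa <- normalize_count(hits_a, 25000) / n_reads
    fb <- normalize_count(hits_b, 50000) / n_reads
    expect_equal(fa, fb, tolerance = 0.15)
  }
})

test_that("per-sample quantification recovers planted frequencies end to end", {
  phA <- random_phage_genome(20000, "phA", seed = 71)$genome
  ctl1 <- random_phage_genome(15000, "ctl1", seed = 72)$genome
  ctl2 <- random_phage_genome(15000, "ctl2", seed = 73)$genome
  refs <- phA
  ctls <- rbind(ctl1, ctl2)
  class(ctls) <- c("phage_genome_set", "data.frame")
  sv <- simulate_virome(refs, c(phA = 0.10), n_reads = 900,
                        error_rate = 0.005,
                        contamination_source = ctls,
                        contamination_fraction = 0.01, seed = 74)
  q <- quantify_sample(sv$reads, refs, ctls)
  truth_n <- sum(sv$truth == "phA")
  expect_equal(q$abundance$n_hits_raw, truth_n, tolerance = 0.05)
  expect_equal(q$presence$call, "positive")
  expect_equal(sum(q$control_hits), sum(sv$truth == "contamination"),
               tolerance = 0.35)
})
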