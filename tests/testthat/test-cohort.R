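make_calls <- function(n_pos, n_total, phage = "ph") {
  data.frame(sample_id = sprintf("s%03d", seq_len(n_total)),
             reference_id = phage,
             call = c(rep("positive", n_pos),
                      rep("negative", n_total - n_pos)))
}

test_that("the 3 percent prevalence gate counts all samples", {
  g1 <- prevalence_gate(make_calls(6, 171))
  expect_true(g1$retained)          # 3.5%
  g2 <- prevalence_gate(make_calls(5, 171))
  expect_false(g2$retained)         # 2.9%
  g3 <- prevalence_gate(make_calls(0, 171))
  expect_false(g3$retained)
  # excluded samples stay in the denominator
  calls <- make_calls(6, 171)
  calls$call[100:120] <- "excluded"
  expect_equal(prevalence_gate(calls)$n_samples, 171L)
})

test_that("prevalence comparison is a symmetric two-tailed z-test", {
  calls <- make_calls(40, 200)
  st <- setNames(rep(c("healthy", "IBD"), each = 100), calls$sample_id)
  # 20 positives in each group by construction
  calls$call <- "negative"
  calls$call[c(1:20, 101:120)] <- "positive"
  r <- compare_prevalence(calls, st)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)

  calls$call <- "negative"
  calls$call[c(1:5, 101:140)] <- "positive"
  r2 <- compare_prevalence(calls, st)
  expect_equal(r2$direction, "IBD")
  expect_lt(r2$p_value, 0.05)
  # swapping the group labels preserves p and flips direction
  st_sw <- setNames(ifelse(st == "IBD", "healthy", "IBD"), names(st))
  r3 <- compare_prevalence(calls, st_sw)
  expect_equal(r3$p_value, r2$p_value)
  expect_equal(r3$direction, "healthy")
})

test_that("prevalence test has power at 0.4 vs 0.1 and holds its level", {
  set.seed(81)
  reject <- replicate(200, {
    x_i <- rbinom(1, 60, 0.4); x_h <- rbinom(1, 60, 0.1)
    two_prop_z(x_i, 60, x_h, 60, tail = "two.sided")$p < 0.05
  })
  expect_gte(mean(reject), 0.9)
  null_rej <- replicate(400, {
    x_i <- rbinom(1, 60, 0.2); x_h <- rbinom(1, 60, 0.2)
    two_prop_z(x_i, 60, x_h, 60, tail = "two.sided")$p < 0.05
  })
  expect_lte(mean(null_rej), 0.09)
})

test_that("flat abundance gives a null effect and small cohorts are flagged", {
  ab <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   n_hits = rep(50L, 20), n_total_reads = rep(1e5, 20))
  st <- setNames(rep(c("healthy", "IBD"), 10), ab$sample_id)
  su <- setNames(sprintf("p%02d", 1:20), ab$sample_id)
  r <- compare_abundance(ab, st, su)
  expect_true(r$testable)
  expect_equal(r$effect, 0, tolerance = 1e-6)
  expect_gt(r$p_value, 0.9)

  r2 <- compare_abundance(ab[1:2, ], st, su)
  expect_false(r2$testable)
  one_status <- setNames(rep("IBD", 20), ab$sample_id)
  r3 <- compare_abundance(ab, one_status, su)
  expect_false(r3$testable)
})

test_that("with one sample per patient the model equals plain logistic", {
  set.seed(91)
  co <- simulate_cohort(n_patients = c(healthy = 30, IBD = 30),
                        samples_per_patient = 1, patient_sd = 0,
                        baseline_freq = 5e-4, status_log_odds = 0.8,
                        prevalence_by_group = c(healthy = 1, IBD = 1),
                        seed = 92)
  d <- merge(co$counts, co$sample_sheet)
  ab <- data.frame(sample_id = d$sample_id, n_hits = d$n_hits,
                   n_total_reads = d$n_total_reads)
  st <- setNames(d$status, d$sample_id)
  su <- setNames(d$subject_id, d$sample_id)
  r <- compare_abundance(ab, st, su)
  expect_equal(r$model, "glm")
  ref <- stats::glm(cbind(n_hits, n_total_reads - n_hits) ~
                      factor(status, levels = c("healthy", "IBD")),
                    data = d, family = binomial())
  expect_equal(r$effect, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(r$se, unname(summary(ref)$coefficients[2, 2]),
               tolerance = 1e-4)
})

test_that("the mixed model recovers a planted status effect", {
  set.seed(101)
  est <- replicate(25, {
    co <- simulate_cohort(n_patients = c(healthy = 40, IBD = 40),
                          samples_per_patient = 2:3, baseline_freq = 5e-4,
                          status_log_odds = 1.0, patient_sd = 0.5,
                          prevalence_by_group = c(healthy = 1, IBD = 1),
                          seed = sample.int(1e6, 1))
    d <- merge(co$counts, co$sample_sheet)
    r <- compare_abundance(
      data.frame(sample_id = d$sample_id, n_hits = d$n_hits,
                 n_total_reads = d$n_total_reads),
      setNames(d$status, d$sample_id), setNames(d$subject_id, d$sample_id))
    r$effect
  })
  expect_equal(mean(est), 1.0, tolerance = 0.1)
})

test_that("the full cohort workflow gates, tests and excludes phages", {
  set.seed(111)
  n <- 150
  sheet <- data.frame(sample_id = sprintf("s%03d", 1:n),
                      subject_id = sprintf("p%03d", rep(1:75, each = 2)),
                      status = rep(c("healthy", "IBD"), each = n / 2),
                      n_total_reads = 1e5)
  status <- setNames(sheet$status, sheet$sample_id)
  # phage "up": more prevalent and more abundant in IBD; "rare": gated out
  mk <- function(phage, pos_idx, hits) {
    data.frame(sample_id = sheet$sample_id, reference_id = phage,
               call = ifelse(seq_len(n) %in% pos_idx, "positive", "negative"))
  }
  pos_up <- c(sample(1:75, 8), sample(76:150, 40))
  calls <- rbind(mk("up", pos_up), mk("rare", c(3, 80)),
                 mk("mushu_like", sample(1:150, 30)))
  set.seed(112)
  ab <- do.call(rbind, lapply(c("up", "rare", "mushu_like"), function(ph) {
    lam <- ifelse(status == "IBD" & ph == "up", 3e-4, 1e-4)
    data.frame(sample_id = sheet$sample_id, reference_id = ph,
               n_hits = rbinom(n, 1e5, lam), n_total_reads = 1e5)
  }))
  res <- run_cohort_analysis(calls, ab, sheet, exclude = "mushu_like")
  expect_false("mushu_like" %in% res$reference_id)
  up <- res[res$reference_id == "up", ]
  expect_true(up$retained)
  expect_equal(up$direction, "IBD")
  expect_lt(up$p_value, 0.05)
  expect_gt(up$abundance_effect, 0)
  expect_lt(up$abundance_p, 0.05)
  rare <- res[res$reference_id == "rare", ]
  expect_false(rare$retained)
  expect_equal(rare$excluded_reason, "below prevalence gate")
})
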