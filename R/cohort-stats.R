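# Healthy-vs-IBD cohort comparison of phage prevalence (two-proportion
# z-tests on presence calls) and abundance (binomial mixed-effect logistic
# regression with a per-patient random intercept).

#' Prevalence gate
#'
#' A phage is retained for cohort analysis only when its phage-positive
#' samples exceed `min_prevalence` of all samples; excluded samples stay in
#' the denominator.
#'
#' @param presence_calls `data.frame` with `sample_id`, `reference_id`,
#'   `call` (`positive` / `negative` / `excluded`).
#' @param min_prevalence prevalence threshold (strict).
#' @return `data.frame` per phage: `reference_id`, `n_positive`,
#'   `n_samples`, `prevalence`, `retained`.
#' @export
prevalence_gate <- function(presence_calls, min_prevalence = 0.03) {
  sp <- split(presence_calls, presence_calls$reference_id)
  out <- lapply(sp, function(d) {
    npos <- sum(d$call == "positive")
    n <- nrow(d)
    data.frame(reference_id = d$reference_id[1], n_positive = npos,
               n_samples = n, prevalence = npos / n,
               retained = npos / n > min_prevalence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare phage prevalence between cohorts
#'
#' Per phage, a two-tailed two-proportion z-test of the positive-sample
#' fraction in IBD versus healthy samples.
#'
#' @param presence_calls as in [prevalence_gate()].
#' @param statuses named vector mapping `sample_id` to `"healthy"` /
#'   `"IBD"`.
#' @return `data.frame` per phage: counts per group, `direction`
#'   (`"IBD"` / `"healthy"` / `"none"`, where prevalence is higher), `z`,
#'   `p_value`.
#' @export
compare_prevalence <- function(presence_calls, statuses) {
  st <- statuses[presence_calls$sample_id]
  if (anyNA(st)) stop("missing status for some samples", call. = FALSE)
  if (length(unique(st)) < 2L) {
    stop("both cohorts must contain at least one sample", call. = FALSE)
  }
  sp <- split(seq_len(nrow(presence_calls)), presence_calls$reference_id)
  out <- lapply(sp, function(ii) {
    d <- presence_calls[ii, ]; s <- st[ii]
    n_h <- sum(s == "healthy"); n_i <- sum(s == "IBD")
    if (n_h == 0L || n_i == 0L) {
      stop("a cohort has zero samples", call. = FALSE)
    }
    x_h <- sum(d$call == "positive" & s == "healthy")
    x_i <- sum(d$call == "positive" & s == "IBD")
    zt <- two_prop_z(x_i, n_i, x_h, n_h, tail = "two.sided")
    data.frame(reference_id = d$reference_id[1],
               n_positive_healthy = x_h, n_healthy = n_h,
               n_positive_ibd = x_i, n_ibd = n_i,
               direction = if (zt$z > 0) "IBD" else if (zt$z < 0) "healthy"
                           else "none",
               z = zt$z, p_value = zt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare phage abundance between cohorts (mixed-effect logistic model)
#'
#' On phage-positive samples only, fits a binomial regression of (hits out
#' of total reads) on cohort status with a per-patient random intercept
#' (Laplace-approximated likelihood via `lme4::glmer`). When every patient
#' contributes a single sample the model reduces to ordinary logistic
#' regression, which is then fitted directly. The reported effect is the
#' status log-odds (IBD versus healthy) with its Wald p-value.
#'
#' @param abundances `data.frame` with `sample_id`, `n_hits`,
#'   `n_total_reads` for the phage-positive samples of one phage.
#' @param statuses named vector mapping `sample_id` to status.
#' @param subjects named vector mapping `sample_id` to patient id.
#' @return list with `effect` (log-odds), `se`, `p_value`, `model`
#'   (`"glmm"` or `"glm"`), `testable` (FALSE with a `reason` when fewer
#'   than 3 samples or a single status level).
#' @export
compare_abundance <- function(abundances, statuses, subjects) {
  d <- data.frame(
    hits = abundances$n_hits,
    total = abundances$n_total_reads,
    status = factor(statuses[abundances$sample_id],
                    levels = c("healthy", "IBD")),
    subject = as.character(subjects[abundances$sample_id]),
    stringsAsFactors = FALSE
  )
  if (nrow(d) < 3L) {
    return(list(effect = NA_real_, se = NA_real_, p_value = NA_real_,
                model = NA_character_, testable = FALSE,
                reason = "fewer than 3 phage-positive samples"))
  }
  if (length(unique(d$status[!is.na(d$status)])) < 2L) {
    return(list(effect = NA_real_, se = NA_real_, p_value = NA_real_,
                model = NA_character_, testable = FALSE,
                reason = "single status level among positive samples"))
  }
  repeated <- any(duplicated(d$subject))
  if (repeated) {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(cbind(hits, total - hits) ~ status + (1 | subject),
                  data = d, family = stats::binomial())))
    co <- summary(fit)$coefficients
    model <- "glmm"
  } else {
    fit <- stats::glm(cbind(hits, total - hits) ~ status, data = d,
                      family = stats::binomial())
    co <- summary(fit)$coefficients
    model <- "glm"
  }
  row <- grep("^statusIBD$", rownames(co))
  list(effect = unname(co[row, 1]), se = unname(co[row, 2]),
       p_value = unname(co[row, 4]), model = model, testable = TRUE,
       reason = NA_character_)
}

#' Full cohort analysis across phages
#'
#' Applies the prevalence gate, the two-tailed prevalence comparison and
#' the abundance mixed model to every phage, reproducing the
#' presence/prevalence/abundance workflow for a healthy-vs-IBD virome
#' cohort. Phages on the exclusion list (for instance broad-host-range
#' phages whose host link is unclear) are dropped up front.
#'
#' @param presence_calls per sample x phage presence table (`sample_id`,
#'   `reference_id`, `call`).
#' @param abundances per sample x phage hit counts (`sample_id`,
#'   `reference_id`, `n_hits`, `n_total_reads`).
#' @param sample_sheet `data.frame` with `sample_id`, `subject_id`,
#'   `status`.
#' @param exclude phage ids to drop before analysis.
#' @param min_prevalence prevalence gate threshold.
#' @param p_adjust multiple-testing correction (`"none"` by default,
#'   matching per-phage reporting; `"BH"` available).
#' @return `data.frame`, one row per analyzed phage, combining gate,
#'   prevalence test and abundance model columns.
#' @export
run_cohort_analysis <- function(presence_calls, abundances, sample_sheet,
                                exclude = character(0),
                                min_prevalence = 0.03,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  presence_calls <- presence_calls[!presence_calls$reference_id %in% exclude, ]
  abundances <- abundances[!abundances$reference_id %in% exclude, ]
  statuses <- setNames(sample_sheet$status, sample_sheet$sample_id)
  subjects <- setNames(sample_sheet$subject_id, sample_sheet$sample_id)
  gate <- prevalence_gate(presence_calls, min_prevalence)
  prev <- compare_prevalence(presence_calls, statuses)
  out <- list()
  for (ph in gate$reference_id) {
    g <- gate[gate$reference_id == ph, ]
    row <- merge(g, prev[prev$reference_id == ph, ], by = "reference_id")
    if (!g$retained) {
      row$excluded_reason <- "below prevalence gate"
      row$abundance_effect <- NA_real_
      row$abundance_p <- NA_real_
      out[[ph]] <- row
      next
    }
    pos <- presence_calls$sample_id[presence_calls$reference_id == ph &
                                    presence_calls$call == "positive"]
    ab <- abundances[abundances$reference_id == ph &
                     abundances$sample_id %in% pos, ]
    cmp <- compare_abundance(ab, statuses, subjects)
    row$excluded_reason <- if (cmp$testable) NA_character_ else cmp$reason
    row$abundance_effect <- cmp$effect
    row$abundance_p <- cmp$p_value
    out[[ph]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (p_adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, "BH")
    res$abundance_p <- stats::p.adjust(res$abundance_p, "BH")
  }
  res
}
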