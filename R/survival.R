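# Survival analysis: Kaplan-Meier group comparison, univariate Cox fits,
# and maximally selected log-rank cutpoints with permutation significance.

validate_survival <- function(surv) {
  assert_that(all(c("time", "event") %in% colnames(surv)),
              "survival table needs time and event columns")
  assert_that(all(surv$time > 0), "times must be strictly positive")
  assert_that(all(surv$event %in% c(0, 1)), "event must be 0/1")
  invisible(surv)
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' @param surv Data.frame with `time` (days, > 0) and `event` (0/1).
#' @param groups Group label per row (>= 2 groups; groups with zero events
#'   are included with a warning).
#' @return List with `fit` (the [survival::survfit()] object), `chisq`,
#'   `df`, `p` (log-rank), and `medians` (per-group median survival,
#'   NA = not reached).
#' @export
survival_compare <- function(surv, groups) {
  validate_survival(surv)
  assert_that(length(groups) == nrow(surv), "groups must match rows")
  g <- factor(groups)
  assert_that(nlevels(g) >= 2, "need >= 2 groups")
  ev <- tapply(surv$event, g, sum)
  if (any(ev == 0)) warning("group(s) with zero events: ",
                            paste(names(ev)[ev == 0], collapse = ", "))
  df <- data.frame(time = surv$time, event = surv$event, group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd_$chisq
  dfree <- nlevels(g) - 1
  p <- stats::pchisq(chisq, dfree, lower.tail = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list(levels(g), names(tab)))
  medians <- tab[, "median"]
  names(medians) <- sub("^group=", "", rownames(tab))
  list(fit = fit, chisq = chisq, df = dfree, p = p, medians = medians)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood Newton fit via [survival::coxph()] with Breslow tie
#' handling; constant covariates are rejected (no variation, no information).
#'
#' @param surv Data.frame with `time` and `event`.
#' @param covariate Numeric (or 2-level) covariate per row.
#' @param conf_level Wald CI level (default 0.95).
#' @return List with `hr`, `ci` (length 2), `p` (Wald), `beta`, `se` and
#'   the fitted model.
#' @export
cox_univariate <- function(surv, covariate, conf_level = 0.95) {
  validate_survival(surv)
  x <- if (is.numeric(covariate)) covariate else as.numeric(factor(covariate))
  if (length(unique(x)) < 2) {
    stop("covariate dropped due to a lack of variation", call. = FALSE)
  }
  df <- data.frame(time = surv$time, event = surv$event, x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(c(beta - z * se, beta + z * se)),
       p = unname(summary(fit)$coefficients[, "Pr(>|z|)"]),
       beta = beta, se = se, fit = fit)
}

# Two-group log-rank chi-square; own implementation so the maxstat scan and
# its permutation null stay fast. Cross-checked against survival::survdiff
# in the test suite.
logrank_chisq <- function(time, event, group) {
  o <- order(time)
  time <- time[o]; event <- event[o]; g1 <- (group[o] == 1)
  n <- length(time)
  ut <- unique(time[event == 1])
  U <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(event == 1 & time == t)
    d1_t <- sum(event == 1 & time == t & g1)
    U <- U + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  if (V <= 0) return(0)
  U^2 / V
}

#' Maximally selected log-rank cutpoint for a continuous score
#'
#' Scans every candidate threshold (midpoints between consecutive distinct
#' score values) that keeps both groups at least `min_group_frac` of the
#' cohort, and returns the threshold maximizing the two-group log-rank
#' chi-square, the full scan trace, and a permutation p value (the naive
#' best-split p is anti-conservative because of the maximal selection).
#'
#' @param surv Data.frame with `time` and `event`.
#' @param score Numeric score per row (>= 2 distinct values).
#' @param min_group_frac Minimum group fraction (default 0.1).
#' @param n_perm Score permutations for the p value (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List with `cutpoint`, `chisq`, `p_perm`, `p_naive` (unadjusted
#'   chi-square p at the best split), `groups` (low/high factor) and
#'   `trace` (threshold, chisq, n_high).
#' @export
maxstat_cutpoint <- function(surv, score, min_group_frac = 0.1,
                             n_perm = 1000, seed = 1) {
  validate_survival(surv)
  assert_that(length(score) == nrow(surv), "score must match rows")
  assert_that(length(unique(score)) >= 2, "score needs >= 2 distinct values")
  n <- nrow(surv)
  min_n <- max(1L, ceiling(min_group_frac * n))
  scan <- function(sc) {
    u <- sort(unique(sc))
    thr <- (u[-1] + u[-length(u)]) / 2
    keep <- vapply(thr, function(t) {
      hi <- sum(sc > t)
      hi >= min_n && (n - hi) >= min_n
    }, TRUE)
    thr <- thr[keep]
    if (length(thr) == 0) return(NULL)
    chis <- vapply(thr, function(t)
      logrank_chisq(surv$time, surv$event, as.integer(sc > t)), 0)
    list(thr = thr, chis = chis)
  }
  obs <- scan(score)
  if (is.null(obs)) {
    stop("no threshold satisfies the minimum group-size bound", call. = FALSE)
  }
  best <- which.max(obs$chis)
  cut <- obs$thr[best]
  stat <- obs$chis[best]
  set.seed(derive_seed(seed, 41L))
  perm_max <- vapply(seq_len(n_perm), function(b) {
    s <- scan(sample(score))
    if (is.null(s)) 0 else max(s$chis)
  }, 0)
  p_perm <- (1 + sum(perm_max >= stat)) / (n_perm + 1)
  list(cutpoint = cut, chisq = stat,
       p_perm = p_perm,
       p_naive = stats::pchisq(stat, 1, lower.tail = FALSE),
       groups = factor(ifelse(score > cut, "high", "low"),
                       levels = c("low", "high")),
       trace = data.frame(threshold = obs$thr, chisq = obs$chis,
                          n_high = vapply(obs$thr, function(t) sum(score > t), 0L)))
}
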