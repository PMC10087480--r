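.check_studies <- function(estimate, variance) {
  stopifnot(
    "estimate must be a finite numeric vector" =
      is.numeric(estimate) && all(is.finite(estimate)),
    "variance must be a finite numeric vector of positive values" =
      is.numeric(variance) && all(is.finite(variance)) && all(variance > 0),
    "estimate and variance must have the same length" =
      length(estimate) == length(variance)
  )
  if (length(estimate) < 2L) {
    stop("at least 2 studies are required to estimate ",
         "between-trial heterogeneity")
  }
}

#' DerSimonian-Laird estimator of between-trial heterogeneity
#'
#' Moment estimator of the between-trial variance \eqn{\tau^2} from
#' per-study effect estimates and known within-study variances. With
#' fixed-effect weights \eqn{v_k = 1/s_k^2} and the inverse-variance pooled
#' estimate \eqn{\hat\Delta_{FE}}, Cochran's
#' \eqn{Q = \sum_k v_k (\hat\Delta_k - \hat\Delta_{FE})^2} and
#' \deqn{\hat\tau^2_{DL} = \max\left(0,\;
#'   \frac{Q - (K-1)}{\sum_k v_k - \sum_k v_k^2 / \sum_k v_k}\right).}
#' Truncation at zero means identical estimates always give
#' \eqn{\hat\tau^2 = 0}.
#'
#' @param estimate Numeric vector of per-study effect estimates
#'   \eqn{\hat\Delta_k} (length \eqn{K \ge 2}).
#' @param variance Numeric vector of known within-study variances
#'   \eqn{s_k^2 > 0}.
#' @return The estimate \eqn{\hat\tau^2 \ge 0}.
#' @examples
#' tau2_dl(c(0, 2), c(1, 1))    # 1
#' tau2_dl(c(0, 1), c(10, 10))  # 0: truncated
#' @references DerSimonian, R. and Laird, N. (1986). Meta-analysis in
#'   clinical trials. Controlled Clinical Trials 7, 177-188.
#' @export
tau2_dl <- function(estimate, variance) {
  .check_studies(estimate, variance)
  v <- 1 / variance
  mu_fe <- sum(v * estimate) / sum(v)
  q <- sum(v * (estimate - mu_fe)^2)
  denom <- sum(v) - sum(v^2) / sum(v)
  max(0, (q - (length(estimate) - 1)) / denom)
}

# Shared fixed-point iteration for the (RE)ML tau^2 estimators with known
# within-study variances. REML adds the 1/sum(w) correction for estimating
# the pooled mean. Converges monotonically in practice for K = 2; truncated
# at zero each step.
.tau2_likelihood <- function(estimate, variance, reml,
                             tol = 1e-8, max_iter = 200L) {
  .check_studies(estimate, variance)
  tau2 <- max(tau2_dl(estimate, variance), 0)
  for (i in seq_len(max_iter)) {
    w <- 1 / (variance + tau2)
    mu <- sum(w * estimate) / sum(w)
    resid2 <- (estimate - mu)^2
    adj <- if (reml) 1 / sum(w) else 0
    new <- sum(w^2 * (resid2 + adj - variance)) / sum(w^2)
    new <- max(0, new)
    if (abs(new - tau2) < tol) return(new)
    tau2 <- new
  }
  warning("tau^2 iteration did not converge within ", max_iter,
          " iterations; returning last value")
  tau2
}

#' Maximum-likelihood estimator of between-trial heterogeneity
#'
#' Iterative ML estimate of \eqn{\tau^2} under the normal random-effects
#' model with known within-study variances, truncated at zero
#' (fixed-point iteration, tolerance 1e-8, at most 200 iterations).
#'
#' @inheritParams tau2_dl
#' @return The estimate \eqn{\hat\tau^2 \ge 0}.
#' @export
tau2_ml <- function(estimate, variance) {
  .tau2_likelihood(estimate, variance, reml = FALSE)
}

#' Restricted-maximum-likelihood estimator of between-trial heterogeneity
#'
#' Iterative REML estimate of \eqn{\tau^2} (accounts for estimation of the
#' pooled mean), truncated at zero (fixed-point iteration, tolerance 1e-8,
#' at most 200 iterations).
#'
#' @inheritParams tau2_dl
#' @return The estimate \eqn{\hat\tau^2 \ge 0}.
#' @export
tau2_reml <- function(estimate, variance) {
  .tau2_likelihood(estimate, variance, reml = TRUE)
}

#' Random-effects meta-analytic decision rule for two trials
#'
#' Fits the inverse-variance random-effects model with weights
#' \eqn{w_k = 1/(s_k^2 + \tau^2)}, pooled estimate
#' \eqn{\hat\Delta = \sum_k w_k \hat\Delta_k / \sum_k w_k}, and test
#' statistic \eqn{Z_{RE} = \hat\Delta \sqrt{\sum_k w_k}}. To match the
#' two-trial paradigm's type I error at the common null boundary, the rule
#' rejects \eqn{H_0: \Delta \le 0} when
#' \eqn{Z_{RE} > \Phi^{-1}(1 - (\alpha/2)^2)}. Uncertainty in an estimated
#' \eqn{\tau^2} is ignored in the test, as is standard (and consequential
#' with only two trials).
#'
#' With \eqn{\tau^2 = 0} this is the fixed-effect analysis; when the
#' within-study variances come from the trial design
#' (\eqn{s_k^2 = 2\sigma^2/n_k}) the weights are proportional to the sample
#' sizes and \eqn{Z_{RE}} equals the one-trial pooled statistic exactly.
#'
#' @inheritParams tau2_dl
#' @param tau2 Between-trial variance to plug in; `NULL` (default) estimates
#'   it with `method`.
#' @param level_a Per-trial one-sided level (\eqn{\alpha/2}); the rule
#'   tests at `level_a^2`.
#' @param method Heterogeneity estimator used when `tau2` is `NULL`:
#'   `"DL"` (default), `"REML"` or `"ML"`.
#' @return An object of class `"re_fit"`: list with `tau2`, `weights`,
#'   `pooled`, `z_re`, `crit`, `reject`, `level_a`, `method`.
#' @examples
#' re_fit(c(0.3, 0.5), c(0.02, 0.02))
#' re_fit(c(0.3, 0.5), c(0.02, 0.02), tau2 = 0)
#' @export
re_fit <- function(estimate, variance, tau2 = NULL, level_a = 0.025,
                   method = c("DL", "REML", "ML")) {
  method <- match.arg(method)
  .check_studies(estimate, variance)
  .check_level(level_a)
  if (is.null(tau2)) {
    tau2 <- switch(method,
                   DL = tau2_dl(estimate, variance),
                   REML = tau2_reml(estimate, variance),
                   ML = tau2_ml(estimate, variance))
  } else {
    stopifnot(
      "tau2 must be a single non-negative number" =
        is.numeric(tau2) && length(tau2) == 1L && is.finite(tau2) &&
        tau2 >= 0
    )
    method <- "fixed"
  }
  w <- 1 / (variance + tau2)
  pooled <- sum(w * estimate) / sum(w)
  z_re <- pooled * sqrt(sum(w))
  crit <- stats::qnorm(1 - level_a^2)
  structure(
    list(tau2 = tau2, weights = w, pooled = pooled, z_re = z_re,
         crit = crit, reject = z_re > crit, level_a = level_a,
         method = method),
    class = "re_fit"
  )
}

#' @export
print.re_fit <- function(x, ...) {
  cat("Random-effects meta-analytic rule (K =", length(x$weights), "trials)\n")
  cat(sprintf("  tau^2 = %.6g (%s), pooled effect = %.6g\n",
              x$tau2, x$method, x$pooled))
  cat(sprintf("  Z_RE = %.4f vs critical value %.4f at one-sided level %g: %s\n",
              x$z_re, x$crit, x$level_a^2,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Heterogeneity scenario for the random-effects simulations
#'
#' The generative side of the random-effects model: per-trial true effects
#' are drawn as \eqn{\Delta_k \sim N(\Delta, \tau^2)} around a common
#' effect. `tau2 = 0` recovers identical populations.
#'
#' @param common_effect Common true effect \eqn{\Delta}.
#' @param tau2 Between-trial variance \eqn{\tau^2 \ge 0}.
#' @return An object of class `"heterogeneity_scenario"`.
#' @examples
#' heterogeneity_scenario(0, 0.25)
#' @export
heterogeneity_scenario <- function(common_effect, tau2) {
  stopifnot(
    "common_effect must be a single finite number" =
      is.numeric(common_effect) && length(common_effect) == 1L &&
      is.finite(common_effect),
    "tau2 must be a single non-negative number" =
      is.numeric(tau2) && length(tau2) == 1L && is.finite(tau2) && tau2 >= 0
  )
  structure(list(common_effect = as.numeric(common_effect),
                 tau2 = as.numeric(tau2)),
            class = "heterogeneity_scenario")
}

# Vectorized DL over replicate columns for K = 2 with constant variances.
.tau2_dl_vec <- function(y1, y2, s2_1, s2_2) {
  v1 <- 1 / s2_1
  v2 <- 1 / s2_2
  vsum <- v1 + v2
  mu <- (v1 * y1 + v2 * y2) / vsum
  q <- v1 * (y1 - mu)^2 + v2 * (y2 - mu)^2
  denom <- vsum - (v1^2 + v2^2) / vsum
  pmax(0, (q - 1) / denom)
}

#' Simulated operating characteristics of the random-effects rule
#'
#' Monte Carlo rejection rate of the random-effects decision rule under
#' between-trial heterogeneity. Each replicate draws per-trial true effects
#' \eqn{\Delta_k \sim N(\Delta, \tau^2)} and summary estimates
#' \eqn{\hat\Delta_k \sim N(\Delta_k, s_k^2)} with
#' \eqn{s_k^2 = 2\sigma^2/n_k} from the trial design (the summary estimate
#' is sufficient under known \eqn{\sigma^2}, so patient-level simulation
#' would be distributionally identical), then applies the rule with
#' \eqn{\tau^2} estimated by DerSimonian-Laird (`estimator = "dl"`) or
#' plugged in at its true value (`estimator = "known"`).
#'
#' A fixed `seed` draws the between-trial innovations before the
#' within-trial ones, so runs at different `tau2` with the same seed share
#' common random numbers — the device used to compare error rates across
#' heterogeneity levels.
#'
#' @inheritParams avg_effect
#' @param scenario A [heterogeneity_scenario()].
#' @param estimator `"dl"` (estimate \eqn{\tau^2} per replicate) or
#'   `"known"` (use `scenario$tau2`).
#' @param n_reps Number of replicates, at least 1.
#' @param seed Integer RNG seed.
#' @return An object of class `"re_oc_sim"`: list with `reject_rate`, its
#'   binomial `se`, and the run metadata.
#' @examples
#' simulate_re_oc(trial_config(500, 0.5), heterogeneity_scenario(0, 0.25),
#'                estimator = "dl", n_reps = 1e4, seed = 7)
#' @export
simulate_re_oc <- function(config, scenario, estimator = c("dl", "known"),
                           n_reps = 1e5, seed) {
  estimator <- match.arg(estimator)
  stopifnot(
    inherits(config, "trial_config"),
    inherits(scenario, "heterogeneity_scenario"),
    "n_reps must be a single integer >= 1" =
      is.numeric(n_reps) && length(n_reps) == 1L && is.finite(n_reps) &&
      n_reps >= 1,
    "seed must be a single finite number" =
      is.numeric(seed) && length(seed) == 1L && is.finite(seed)
  )
  n_reps <- as.integer(n_reps)
  s2_1 <- 2 * config$sigma2 / config$n1
  s2_2 <- 2 * config$sigma2 / config$n2
  tau <- sqrt(scenario$tau2)
  set.seed(seed)
  eb1 <- stats::rnorm(n_reps)
  eb2 <- stats::rnorm(n_reps)
  ew1 <- stats::rnorm(n_reps)
  ew2 <- stats::rnorm(n_reps)
  d1 <- scenario$common_effect + tau * eb1
  d2 <- scenario$common_effect + tau * eb2
  y1 <- d1 + sqrt(s2_1) * ew1
  y2 <- d2 + sqrt(s2_2) * ew2
  tau2_used <- if (estimator == "dl") {
    .tau2_dl_vec(y1, y2, s2_1, s2_2)
  } else {
    scenario$tau2
  }
  w1 <- 1 / (s2_1 + tau2_used)
  w2 <- 1 / (s2_2 + tau2_used)
  z_re <- (w1 * y1 + w2 * y2) / sqrt(w1 + w2)
  crit <- stats::qnorm(1 - config$level_a^2)
  rate <- mean(z_re > crit)
  structure(
    list(reject_rate = rate,
         se = sqrt(rate * (1 - rate) / n_reps),
         n_reps = n_reps, estimator = estimator, seed = seed,
         scenario = scenario, config = config),
    class = "re_oc_sim"
  )
}

#' @export
print.re_oc_sim <- function(x, ...) {
  cat(sprintf(
    "Random-effects rule simulation (%s tau^2, %d replicates)\n",
    if (x$estimator == "dl") "DerSimonian-Laird" else "known", x$n_reps))
  cat(sprintf("  Delta = %g, tau^2 = %g, f = %g, N = %g\n",
              x$scenario$common_effect, x$scenario$tau2,
              x$config$fraction_f, x$config$total_n))
  cat(sprintf("  rejection rate = %.6f (SE %.2g)\n", x$reject_rate, x$se))
  invisible(x)
}

#' Read per-study summaries from CSV
#'
#' Reads a CSV with columns `estimate` and `variance` (one row per study)
#' for use with [re_fit()] and the heterogeneity estimators.
#'
#' @param path Path of the CSV file.
#' @return A data.frame with columns `estimate` and `variance`.
#' @export
read_study_summaries <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("estimate", "variance") %in% names(df))) {
    stop("study summary CSV must have columns 'estimate' and 'variance'")
  }
  .check_studies(df$estimate, df$variance)
  df[c("estimate", "variance")]
}
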