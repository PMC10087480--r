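#' Critical values of the two decision rules
#'
#' The two-trial paradigm declares success when both per-trial statistics
#' exceed \eqn{c_{two} = \Phi^{-1}(1 - \alpha/2)}; the one-trial (pooled)
#' paradigm requires the single combined statistic to exceed the more
#' stringent \eqn{c_{one} = \Phi^{-1}(1 - (\alpha/2)^2)}, chosen so that the
#' two rules have the same type I error when both treatment differences are
#' zero. Here `level_a` plays the role of \eqn{\alpha/2}.
#'
#' @param level_a Per-trial one-sided significance level, in (0, 0.5).
#' @return An object of class `"rejection_thresholds"`: list with `c_two`,
#'   `c_one` and `level_a`; always `c_one > c_two > 0`.
#' @examples
#' rejection_thresholds(0.025)
#' @export
rejection_thresholds <- function(level_a = 0.025) {
  stopifnot(
    "level_a must be a single number in (0, 0.5)" =
      is.numeric(level_a) && length(level_a) == 1L && is.finite(level_a) &&
      level_a > 0 && level_a < 0.5
  )
  structure(
    list(
      c_two = stats::qnorm(1 - level_a),
      c_one = stats::qnorm(1 - level_a^2),
      level_a = level_a
    ),
    class = "rejection_thresholds"
  )
}

#' @export
print.rejection_thresholds <- function(x, ...) {
  cat(sprintf(
    "Rejection thresholds at per-trial one-sided level %g:\n", x$level_a))
  cat(sprintf("  two-trial: Z_k > %.6f (each trial)\n", x$c_two))
  cat(sprintf("  one-trial: Z   > %.6f (pooled)\n", x$c_one))
  invisible(x)
}

# Accept a noncentrality_triple, a plain list, or (for p_one) a numeric
# vector; returns list(d1, d2, d) with NULLs where absent.
.nc_fields <- function(nc) {
  if (inherits(nc, "noncentrality_triple") || is.list(nc)) {
    list(d1 = nc$d1, d2 = nc$d2, d = nc$d)
  } else if (is.numeric(nc)) {
    list(d1 = NULL, d2 = NULL, d = nc)
  } else {
    stop("nc must be a noncentrality triple, a list, or a numeric vector")
  }
}

.check_level <- function(level_a) {
  stopifnot(
    "level_a must be a single number in (0, 0.5)" =
      is.numeric(level_a) && length(level_a) == 1L && is.finite(level_a) &&
      level_a > 0 && level_a < 0.5
  )
}

#' Rejection probability of the two-trial rule
#'
#' Closed-form probability that both independent trials are individually
#' significant:
#' \deqn{p_{two} = [1 - \Phi(\Phi^{-1}(1-\alpha/2) - \delta_1)]
#'                 [1 - \Phi(\Phi^{-1}(1-\alpha/2) - \delta_2)].}
#' This is the type I error when the scenario lies in the union null
#' (\eqn{\Delta_1 \le 0} or \eqn{\Delta_2 \le 0}) and the power otherwise.
#'
#' @param nc A [noncentrality()] triple, or a list with numeric (possibly
#'   vector) components `d1` and `d2`.
#' @param level_a Per-trial one-sided level (\eqn{\alpha/2}).
#' @return Rejection probability (vectorized over `d1`, `d2`).
#' @examples
#' p_two_trial(list(d1 = 0, d2 = 0))          # 0.000625 at the origin
#' p_two_trial(list(d1 = 10, d2 = 0))         # ~ 0.025, the boundary supremum
#' @seealso [p_one_trial()], [boundary_sup()]
#' @export
p_two_trial <- function(nc, level_a = 0.025) {
  .check_level(level_a)
  v <- .nc_fields(nc)
  if (is.null(v$d1) || is.null(v$d2)) {
    stop("nc must supply per-trial noncentralities d1 and d2")
  }
  c_two <- stats::qnorm(1 - level_a)
  stats::pnorm(c_two - v$d1, lower.tail = FALSE) *
    stats::pnorm(c_two - v$d2, lower.tail = FALSE)
}

#' Rejection probability of the one-trial rule
#'
#' Closed-form probability that the pooled statistic
#' \eqn{Z = \sqrt{f} Z_1 + \sqrt{1-f} Z_2} exceeds the single-trial critical
#' value:
#' \deqn{p_{one} = 1 - \Phi(\Phi^{-1}(1 - (\alpha/2)^2) - \delta).}
#'
#' @param nc A [noncentrality()] triple, a list with numeric component `d`,
#'   or a numeric vector of combined noncentralities \eqn{\delta}.
#' @inheritParams p_two_trial
#' @return Rejection probability (vectorized over `d`).
#' @examples
#' p_one_trial(0)        # 0.000625 at the origin
#' p_one_trial(2.4004)   # ~ 0.20
#' @export
p_one_trial <- function(nc, level_a = 0.025) {
  .check_level(level_a)
  v <- .nc_fields(nc)
  if (is.null(v$d)) stop("nc must supply the combined noncentrality d")
  stats::pnorm(stats::qnorm(1 - level_a^2) - v$d, lower.tail = FALSE)
}

#' Membership in the two-trial rejection region
#'
#' The two-trial region is the upper-right quadrant
#' \eqn{\Omega_{two} = \{(Z_1, Z_2): Z_1 > c_{two},\ Z_2 > c_{two}\}}.
#' The inequality is strict: a statistic exactly at the critical value does
#' not reject.
#'
#' @param z1,z2 Realized per-trial z statistics (vectorized).
#' @param thr A [rejection_thresholds()] object.
#' @return Logical vector.
#' @examples
#' thr <- rejection_thresholds(0.025)
#' in_two_region(2.5, 2.5, thr)   # TRUE
#' in_two_region(3.5, 1.0, thr)   # FALSE: one trial fails
#' @export
in_two_region <- function(z1, z2, thr) {
  stopifnot(inherits(thr, "rejection_thresholds"))
  z1 > thr$c_two & z2 > thr$c_two
}

#' Membership in the one-trial rejection region
#'
#' The one-trial region is the half-plane above an oblique boundary whose
#' slope depends on the trial fraction:
#' \eqn{\Omega_{one} = \{(Z_1, Z_2): \sqrt{f} Z_1 + \sqrt{1-f} Z_2 > c_{one}\}}.
#' A large statistic in the bigger trial can carry a negative one in the
#' smaller trial across the boundary.
#'
#' @inheritParams in_two_region
#' @param fraction_f Fraction of patients in trial 1, in (0, 1).
#' @return Logical vector.
#' @examples
#' thr <- rejection_thresholds(0.025)
#' in_one_region(2.4, 2.4, 0.5, thr)    # TRUE
#' in_one_region(4.0, -0.5, 0.9, thr)   # TRUE: the large trial dominates
#' @export
in_one_region <- function(z1, z2, fraction_f, thr) {
  stopifnot(
    inherits(thr, "rejection_thresholds"),
    "fraction_f must be a single number strictly between 0 and 1" =
      is.numeric(fraction_f) && length(fraction_f) == 1L &&
      is.finite(fraction_f) && fraction_f > 0 && fraction_f < 1
  )
  sqrt(fraction_f) * z1 + sqrt(1 - fraction_f) * z2 > thr$c_one
}

#' Operating-characteristic grid over effect scenarios
#'
#' Evaluates the closed-form rejection probabilities of both rules over the
#' Cartesian product of `delta1_values` and `delta2_values`, together with
#' each scenario's classification under the union null and the
#' average-effect null. One row per \eqn{(\Delta_1, \Delta_2)} pair.
#'
#' @inheritParams avg_effect
#' @param delta1_values,delta2_values Non-empty numeric vectors of true
#'   treatment differences.
#' @return A `data.frame` with columns `delta1`, `delta2`, `f`, `N`,
#'   `p_two`, `p_one`, `union_null_label`, `average_null_label`.
#' @examples
#' oc_grid(trial_config(500, 0.5), 0, 0)
#' @export
oc_grid <- function(config, delta1_values, delta2_values) {
  stopifnot(
    inherits(config, "trial_config"),
    "delta1_values must be a non-empty finite numeric vector" =
      is.numeric(delta1_values) && length(delta1_values) > 0L &&
      all(is.finite(delta1_values)),
    "delta2_values must be a non-empty finite numeric vector" =
      is.numeric(delta2_values) && length(delta2_values) > 0L &&
      all(is.finite(delta2_values))
  )
  g <- expand.grid(delta1 = delta1_values, delta2 = delta2_values,
                   KEEP.OUT.ATTRS = FALSE)
  f <- config$fraction_f
  scale <- sqrt(config$total_n / (4 * config$sigma2))
  d1 <- g$delta1 * sqrt(f) * scale
  d2 <- g$delta2 * sqrt(1 - f) * scale
  avg <- f * g$delta1 + (1 - f) * g$delta2
  d <- avg * scale
  lab <- function(x) {
    ifelse(x > 0, "alternative", ifelse(x < 0, "null", "boundary"))
  }
  data.frame(
    delta1 = g$delta1,
    delta2 = g$delta2,
    f = f,
    N = config$total_n,
    p_two = p_two_trial(list(d1 = d1, d2 = d2), config$level_a),
    p_one = p_one_trial(list(d = d), config$level_a),
    union_null_label = lab(pmin(g$delta1, g$delta2)),
    average_null_label = lab(avg),
    stringsAsFactors = FALSE
  )
}

#' Supremum of a rule's rejection probability over a null region
#'
#' Over the union null (\eqn{\Delta_1 \le 0} or \eqn{\Delta_2 \le 0}) the
#' worst case for either rule sits along the boundary where one treatment
#' difference is exactly zero and the other grows without bound. In that
#' limit the two-trial rule's type I error tends to its per-trial level
#' \eqn{\alpha/2} (the zero-effect trial rejects with probability
#' \eqn{\alpha/2}, the other with probability tending to 1), while the
#' one-trial rule's pooled statistic is dragged across its threshold by the
#' large effect and the error tends to 1. The suprema are returned as these
#' analytic limits.
#'
#' Under its own average-effect null, the one-trial rule's supremum is
#' \eqn{(\alpha/2)^2}, attained at the boundary point; it is returned for
#' completeness. The two-trial rule is not calibrated against that frame and
#' requesting it is an error.
#'
#' @param rule `"two_trial"` or `"one_trial"`.
#' @inheritParams avg_effect
#' @param frame `"union_null"` or `"average_null"`.
#' @return The supremum, a single number.
#' @examples
#' cfg <- trial_config(500, 0.5)
#' boundary_sup("two_trial", cfg, "union_null")   # alpha/2 = 0.025
#' boundary_sup("one_trial", cfg, "union_null")   # 1
#' @export
boundary_sup <- function(rule = c("two_trial", "one_trial"), config,
                         frame = c("union_null", "average_null")) {
  rule <- match.arg(rule)
  frame <- match.arg(frame)
  stopifnot(inherits(config, "trial_config"))
  a <- config$level_a
  if (frame == "average_null") {
    if (rule == "two_trial") {
      stop("the two-trial rule is not calibrated against the ",
           "average-effect null; its supremum there is not a standard ",
           "operating characteristic (use frame = \"union_null\")")
    }
    return(a^2)
  }
  switch(rule, two_trial = a, one_trial = 1)
}

#' Rejection probability of the known-heterogeneity random-effects rule
#'
#' Closed-form probability that the random-effects statistic
#' \eqn{Z_{RE} = \hat\Delta \sqrt{\sum_k w_k}} with known between-trial
#' variance \eqn{\tau^2} (weights \eqn{w_k = 1/(s_k^2 + \tau^2)},
#' \eqn{s_k^2 = 2\sigma^2/n_k}) exceeds the single-trial critical value,
#' when per-trial true effects are drawn around \eqn{(\Delta_1, \Delta_2)}
#' with between-trial variance \eqn{\tau^2}. Under that generative model
#' \eqn{Z_{RE}} is standard normal around
#' \eqn{\sum_k w_k \Delta_k / \sqrt{\sum_k w_k}}, so
#' \deqn{p_{RE} = 1 - \Phi\left(\Phi^{-1}(1-(\alpha/2)^2) -
#'   \frac{\sum_k w_k \Delta_k}{\sqrt{\sum_k w_k}}\right).}
#' At \eqn{\tau^2 = 0} this reduces exactly to the one-trial probability
#' [p_one_trial()].
#'
#' @inheritParams avg_effect
#' @param tau2 Known between-trial variance \eqn{\tau^2 \ge 0}.
#' @param level_a Per-trial one-sided level (\eqn{\alpha/2}); the rule
#'   itself tests at `level_a^2`.
#' @return Rejection probability, a single number.
#' @examples
#' cfg <- trial_config(500, 0.5)
#' p_re_known(cfg, effect_scenario(-0.2, 0), tau2 = 0.01)
#' @export
p_re_known <- function(config, effects, tau2, level_a = config$level_a) {
  stopifnot(
    inherits(config, "trial_config"),
    inherits(effects, "effect_scenario"),
    "tau2 must be a single non-negative number" =
      is.numeric(tau2) && length(tau2) == 1L && is.finite(tau2) && tau2 >= 0
  )
  .check_level(level_a)
  s2 <- 2 * config$sigma2 / c(config$n1, config$n2)
  w <- 1 / (s2 + tau2)
  m <- sum(w * c(effects$delta1, effects$delta2)) / sqrt(sum(w))
  stats::pnorm(stats::qnorm(1 - level_a^2) - m, lower.tail = FALSE)
}
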