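#' Pivotal trial design parameters
#'
#' Bundles the design of a pair of pivotal phase III trials run in parallel:
#' `total_n` patients are split between the trials with a fraction
#' `fraction_f` in trial 1, and patients are randomized 1:1 between control
#' and experimental arms within each trial, giving per-arm sizes
#' \eqn{n_1 = fN/2} and \eqn{n_2 = (1-f)N/2}. The outcome is normal with
#' known variance `sigma2` (so with `sigma2 = 1` treatment differences are
#' Cohen's d values), and each individual trial is tested one-sided at level
#' `level_a` (the conventional \eqn{\alpha/2 = 0.025}).
#'
#' @param total_n Total number of patients \eqn{N} across both trials
#'   (at least 4).
#' @param fraction_f Fraction \eqn{f \in (0,1)} of `total_n` enrolled in
#'   trial 1.
#' @param sigma2 Known outcome variance \eqn{\sigma^2 > 0}.
#' @param level_a Per-trial one-sided significance level, in (0, 0.5).
#'
#' @return An object of class `"trial_config"`: a list with fields
#'   `total_n`, `fraction_f`, `sigma2`, `level_a` and the (unrounded)
#'   per-arm sizes `n1`, `n2`.
#' @examples
#' trial_config(total_n = 500, fraction_f = 0.5)
#' @export
trial_config <- function(total_n, fraction_f, sigma2 = 1, level_a = 0.025) {
  stopifnot(
    "total_n must be a single finite number" =
      is.numeric(total_n) && length(total_n) == 1L && is.finite(total_n),
    "total_n must be at least 4" = total_n >= 4,
    "fraction_f must be a single number strictly between 0 and 1" =
      is.numeric(fraction_f) && length(fraction_f) == 1L &&
      is.finite(fraction_f) && fraction_f > 0 && fraction_f < 1,
    "sigma2 must be a single positive number" =
      is.numeric(sigma2) && length(sigma2) == 1L && is.finite(sigma2) &&
      sigma2 > 0,
    "level_a must be a single number in (0, 0.5)" =
      is.numeric(level_a) && length(level_a) == 1L && is.finite(level_a) &&
      level_a > 0 && level_a < 0.5
  )
  structure(
    list(
      total_n = as.numeric(total_n),
      fraction_f = fraction_f,
      sigma2 = sigma2,
      level_a = level_a,
      n1 = fraction_f * total_n / 2,
      n2 = (1 - fraction_f) * total_n / 2
    ),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Two pivotal trials, 1:1 randomization\n")
  cat(sprintf("  N = %g patients, f = %g (per-arm n1 = %g, n2 = %g)\n",
              x$total_n, x$fraction_f, x$n1, x$n2))
  cat(sprintf("  known variance sigma^2 = %g, per-trial one-sided level = %g\n",
              x$sigma2, x$level_a))
  invisible(x)
}

#' True treatment effects in the two trial populations
#'
#' The effect scenario is the pair of true treatment differences
#' \eqn{\Delta_1 = \mu_{11} - \mu_{01}} and \eqn{\Delta_2 = \mu_{12} - \mu_{02}}
#' between experimental and control means in trial populations 1 and 2.
#' Identical populations correspond to `delta1 == delta2`.
#'
#' @param delta1,delta2 Finite true treatment differences (outcome units;
#'   Cohen's d when `sigma2 = 1`).
#' @return An object of class `"effect_scenario"`.
#' @examples
#' effect_scenario(0.3, 0.3)
#' @export
effect_scenario <- function(delta1, delta2) {
  stopifnot(
    "delta1 must be a single finite number" =
      is.numeric(delta1) && length(delta1) == 1L && is.finite(delta1),
    "delta2 must be a single finite number" =
      is.numeric(delta2) && length(delta2) == 1L && is.finite(delta2)
  )
  structure(list(delta1 = as.numeric(delta1), delta2 = as.numeric(delta2)),
            class = "effect_scenario")
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat(sprintf("Effect scenario: Delta1 = %g, Delta2 = %g\n",
              x$delta1, x$delta2))
  invisible(x)
}

#' Average treatment effect across the two trials
#'
#' The single parameter targeted by the one-trial (pooled) paradigm:
#' \eqn{\tilde\Delta = f\Delta_1 + (1-f)\Delta_2}. When the two populations
#' are identical (\eqn{\Delta_1 = \Delta_2}) it does not depend on `f`.
#'
#' @param config A [trial_config()].
#' @param effects An [effect_scenario()].
#' @return The average effect, a single number.
#' @examples
#' avg_effect(trial_config(400, 0.1), effect_scenario(0.6, 0.2))
#' @export
avg_effect <- function(config, effects) {
  stopifnot(inherits(config, "trial_config"),
            inherits(effects, "effect_scenario"))
  config$fraction_f * effects$delta1 +
    (1 - config$fraction_f) * effects$delta2
}

#' Noncentrality parameters of the trial test statistics
#'
#' Maps an effect scenario to the means \eqn{(\delta_1, \delta_2, \delta)}
#' of the per-trial z statistics \eqn{Z_1, Z_2} and the pooled statistic
#' \eqn{Z = \sqrt{f} Z_1 + \sqrt{1-f} Z_2}:
#' \deqn{\delta_1 = \Delta_1 \sqrt{fN/(4\sigma^2)},\quad
#'       \delta_2 = \Delta_2 \sqrt{(1-f)N/(4\sigma^2)},\quad
#'       \delta   = \tilde\Delta \sqrt{N/(4\sigma^2)},}
#' which satisfy the exact identity
#' \eqn{\delta = \sqrt{f}\,\delta_1 + \sqrt{1-f}\,\delta_2}.
#'
#' @inheritParams avg_effect
#' @return An object of class `"noncentrality_triple"`: list with fields
#'   `d1`, `d2`, `d`.
#' @examples
#' noncentrality(trial_config(400, 0.1), effect_scenario(0.6, 0.2))
#' @export
noncentrality <- function(config, effects) {
  stopifnot(inherits(config, "trial_config"),
            inherits(effects, "effect_scenario"))
  f <- config$fraction_f
  scale <- sqrt(config$total_n / (4 * config$sigma2))
  structure(
    list(
      d1 = effects$delta1 * sqrt(f) * scale,
      d2 = effects$delta2 * sqrt(1 - f) * scale,
      d  = avg_effect(config, effects) * scale
    ),
    class = "noncentrality_triple"
  )
}

#' @export
print.noncentrality_triple <- function(x, ...) {
  cat(sprintf("Noncentrality: delta1 = %.6g, delta2 = %.6g, delta = %.6g\n",
              x$d1, x$d2, x$d))
  invisible(x)
}

#' Classify an effect scenario against a null-hypothesis frame
#'
#' The two paradigms control type I error against different null
#' hypotheses. The two-trial rule tests the union null
#' \eqn{H_0 = H_0^1 \cup H_0^2} (at least one of \eqn{\Delta_1, \Delta_2}
#' is \eqn{\le 0}); the one-trial rule tests the average-effect null
#' \eqn{\tilde\Delta \le 0}. A scenario exactly on the boundary of the null
#' region (the relevant quantity equal to zero) is labelled `"boundary"`
#' and belongs to the null for one-sided error-rate accounting.
#'
#' The `"common_null"` frame (sign of the common effect \eqn{\Delta} in the
#' random-effects parameterization) is not accepted here: it applies to the
#' \eqn{(\Delta, \tau^2)} parameterization used by [simulate_re_oc()].
#'
#' @inheritParams avg_effect
#' @param frame Null frame, `"union_null"` or `"average_null"`.
#' @return One of `"null"`, `"alternative"`, `"boundary"`.
#' @examples
#' cfg <- trial_config(500, 0.5)
#' classify_scenario(cfg, effect_scenario(-0.5, 0.3), "union_null")
#' classify_scenario(cfg, effect_scenario(-0.1, 0.5), "average_null")
#' @export
classify_scenario <- function(config, effects,
                              frame = c("union_null", "average_null",
                                        "common_null")) {
  frame <- match.arg(frame)
  if (frame == "common_null") {
    stop("the common_null frame applies to the (Delta, tau^2) ",
         "parameterization of the random-effects rule; ",
         "use union_null or average_null here")
  }
  stopifnot(inherits(config, "trial_config"),
            inherits(effects, "effect_scenario"))
  x <- switch(frame,
    union_null = min(effects$delta1, effects$delta2),
    average_null = avg_effect(config, effects)
  )
  if (x > 0) "alternative" else if (x < 0) "null" else "boundary"
}
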