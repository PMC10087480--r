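# Rounded per-arm sizes and the effective fraction they imply. The design
# treats f*N as exact; simulation needs integer arms, so the combination
# weight uses f_eff = n1/(n1+n2) to keep the pooled-statistic identity exact.
.arm_sizes <- function(config) {
  n1 <- round(config$fraction_f * config$total_n / 2)
  n2 <- round((1 - config$fraction_f) * config$total_n / 2)
  if (n1 < 1 || n2 < 1) {
    stop("infeasible design: per-arm sizes round to n1 = ", n1,
         ", n2 = ", n2, "; each arm needs at least 1 patient")
  }
  list(n1 = n1, n2 = n2, f_eff = n1 / (n1 + n2))
}

#' Generate synthetic patient-level data for a pair of trials
#'
#' Draws independent normal outcomes for every patient in both trials under
#' the known-variance model: control arms have mean 0 and treatment arms
#' have means `delta1` (trial 1) and `delta2` (trial 2), all with variance
#' `sigma2`. Only the treatment differences enter any downstream formula,
#' so control means are fixed at 0 (a location shift changes nothing).
#' Per-arm sizes are `round(f*N/2)` and `round((1-f)*N/2)`.
#'
#' @inheritParams avg_effect
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   exactly.
#' @return An object of class `"trial_dataset"`: list with `data` (a
#'   data.frame with columns `trial`, `arm`, `patient`, `outcome`), the
#'   generating `config` and `effects`, `seed`, and the rounded arm sizes
#'   `n1`, `n2`.
#' @examples
#' d <- generate_trial_data(trial_config(100, 0.5),
#'                          effect_scenario(0.5, 0.2), seed = 1)
#' head(d$data)
#' @export
generate_trial_data <- function(config, effects, seed) {
  stopifnot(
    inherits(config, "trial_config"),
    inherits(effects, "effect_scenario"),
    "seed must be a single finite number" =
      is.numeric(seed) && length(seed) == 1L && is.finite(seed)
  )
  sz <- .arm_sizes(config)
  sd <- sqrt(config$sigma2)
  set.seed(seed)
  df <- data.frame(
    trial = rep(c(1L, 1L, 2L, 2L), times = c(sz$n1, sz$n1, sz$n2, sz$n2)),
    arm = rep(c("control", "treatment", "control", "treatment"),
              times = c(sz$n1, sz$n1, sz$n2, sz$n2)),
    patient = c(seq_len(sz$n1), seq_len(sz$n1),
                seq_len(sz$n2), seq_len(sz$n2)),
    outcome = c(stats::rnorm(sz$n1, 0, sd),
                stats::rnorm(sz$n1, effects$delta1, sd),
                stats::rnorm(sz$n2, 0, sd),
                stats::rnorm(sz$n2, effects$delta2, sd)),
    stringsAsFactors = FALSE
  )
  structure(
    list(data = df, config = config, effects = effects, seed = seed,
         n1 = sz$n1, n2 = sz$n2),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial dataset: %d + %d patients per arm (trials 1, 2), seed %g\n",
    x$n1, x$n2, x$seed))
  cat(sprintf("  true effects Delta1 = %g, Delta2 = %g, sigma^2 = %g\n",
              x$effects$delta1, x$effects$delta2, x$config$sigma2))
  invisible(x)
}

#' Test statistics from a trial dataset
#'
#' Computes the per-trial z statistics with known variance,
#' \eqn{Z_k = (\bar X_{1k} - \bar X_{0k}) / \sqrt{2\sigma^2/n_k}}, and the
#' pooled statistic \eqn{Z} from the combined arm sums,
#' \eqn{Z = (\bar X_1 - \bar X_0)/\sqrt{2\sigma^2/(n_1+n_2)}}, which equals
#' the inverse normal combination
#' \eqn{\sqrt{f} Z_1 + \sqrt{1-f} Z_2} (with the effective `f` implied by
#' the rounded arm sizes). Both routes are computed and verified to agree.
#'
#' @param data A [generate_trial_data()] dataset.
#' @return An object of class `"z_triple"`: list with `z1`, `z2`, `z` and
#'   the effective fraction `f_eff`.
#' @examples
#' d <- generate_trial_data(trial_config(100, 0.5),
#'                          effect_scenario(0.5, 0.2), seed = 1)
#' z_statistics(d)
#' @export
z_statistics <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  df <- data$data
  s2 <- data$config$sigma2
  sums <- tapply(df$outcome, list(df$trial, df$arm), sum)
  n1 <- data$n1
  n2 <- data$n2
  z1 <- (sums["1", "treatment"] - sums["1", "control"]) / n1 /
    sqrt(2 * s2 / n1)
  z2 <- (sums["2", "treatment"] - sums["2", "control"]) / n2 /
    sqrt(2 * s2 / n2)
  n <- n1 + n2
  z_pooled <- (sums["1", "treatment"] + sums["2", "treatment"] -
                 sums["1", "control"] - sums["2", "control"]) / n /
    sqrt(2 * s2 / n)
  f_eff <- n1 / n
  z_comb <- sqrt(f_eff) * z1 + sqrt(1 - f_eff) * z2
  stopifnot(
    "pooled statistic disagrees with the weighted combination" =
      abs(z_pooled - z_comb) < 1e-8
  )
  structure(list(z1 = unname(z1), z2 = unname(z2), z = unname(z_pooled),
                 f_eff = f_eff),
            class = "z_triple")
}

#' @export
print.z_triple <- function(x, ...) {
  cat(sprintf("z1 = %.4f, z2 = %.4f, pooled z = %.4f (f_eff = %g)\n",
              x$z1, x$z2, x$z, x$f_eff))
  invisible(x)
}

#' Monte Carlo operating characteristics of both decision rules
#'
#' Estimates the rejection probabilities of the two-trial and one-trial
#' rules at a given effect scenario by repeated simulation. The default
#' `"summary"` mode draws the per-trial z statistics from their exact
#' sampling distribution (the arm means are sufficient for the treatment
#' differences under known variance, so this is distributionally identical
#' to the patient-level model and much faster); `mode = "patient"` runs the
#' full patient-level generator and [z_statistics()] for every replicate and
#' serves as a cross-check of that equivalence.
#'
#' @inheritParams avg_effect
#' @param n_reps Number of Monte Carlo replicates, at least 1.
#' @param seed Integer RNG seed.
#' @param mode `"summary"` (exact sufficient-statistic draws, default) or
#'   `"patient"` (full patient-level simulation per replicate).
#' @return An object of class `"mc_oc"`: list with rejection frequencies
#'   `p_two`, `p_one`, their binomial standard errors `se_two`, `se_one`,
#'   and the run metadata.
#' @examples
#' mc <- monte_carlo_oc(trial_config(500, 0.5), effect_scenario(0, 0),
#'                      n_reps = 1e4, seed = 42)
#' mc
#' @export
monte_carlo_oc <- function(config, effects, n_reps = 1e5, seed,
                           mode = c("summary", "patient")) {
  mode <- match.arg(mode)
  stopifnot(
    inherits(config, "trial_config"),
    inherits(effects, "effect_scenario"),
    "n_reps must be a single integer >= 1" =
      is.numeric(n_reps) && length(n_reps) == 1L && is.finite(n_reps) &&
      n_reps >= 1,
    "seed must be a single finite number" =
      is.numeric(seed) && length(seed) == 1L && is.finite(seed)
  )
  n_reps <- as.integer(n_reps)
  sz <- .arm_sizes(config)
  thr <- rejection_thresholds(config$level_a)
  if (mode == "summary") {
    # Z_k ~ N(delta_k, 1) with delta_k implied by the rounded arm sizes;
    # the pooled Z uses the effective fraction so the identity is exact.
    d1 <- effects$delta1 * sqrt(sz$n1 / (2 * config$sigma2))
    d2 <- effects$delta2 * sqrt(sz$n2 / (2 * config$sigma2))
    set.seed(seed)
    z1 <- stats::rnorm(n_reps, d1, 1)
    z2 <- stats::rnorm(n_reps, d2, 1)
    z <- sqrt(sz$f_eff) * z1 + sqrt(1 - sz$f_eff) * z2
  } else {
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
    z1 <- z2 <- z <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      zt <- z_statistics(generate_trial_data(config, effects, rep_seeds[i]))
      z1[i] <- zt$z1
      z2[i] <- zt$z2
      z[i] <- zt$z
    }
  }
  rej_two <- z1 > thr$c_two & z2 > thr$c_two
  rej_one <- z > thr$c_one
  p_two <- mean(rej_two)
  p_one <- mean(rej_one)
  structure(
    list(
      p_two = p_two, p_one = p_one,
      se_two = sqrt(p_two * (1 - p_two) / n_reps),
      se_one = sqrt(p_one * (1 - p_one) / n_reps),
      n_reps = n_reps, seed = seed, mode = mode,
      config = config, effects = effects
    ),
    class = "mc_oc"
  )
}

#' @export
print.mc_oc <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo operating characteristics (%s mode, %d replicates)\n",
    x$mode, x$n_reps))
  cat(sprintf("  two-trial rejection: %.6f (SE %.2g)\n", x$p_two, x$se_two))
  cat(sprintf("  one-trial rejection: %.6f (SE %.2g)\n", x$p_one, x$se_one))
  invisible(x)
}

#' Tidy export of a simulated trial dataset
#'
#' @param data A [generate_trial_data()] dataset.
#' @param path Path of the CSV file to write (columns `trial`, `arm`,
#'   `patient`, `outcome`).
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(data$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
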