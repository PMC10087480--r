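# Per-trial effect estimates and their known variances from a simulated
# patient-level dataset, for feeding the meta-analytic rule.
study_summaries_from <- function(dataset) {
  df <- dataset$data
  diff_k <- function(k) {
    mean(df$outcome[df$trial == k & df$arm == "treatment"]) -
      mean(df$outcome[df$trial == k & df$arm == "control"])
  }
  list(
    estimate = c(diff_k(1), diff_k(2)),
    variance = 2 * dataset$config$sigma2 / c(dataset$n1, dataset$n2)
  )
}
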