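#' Liability-threshold AUC prediction from PRS summaries
#'
#' Under the liability-threshold reading of the polygenic score (a latent
#' normal liability with disease above a prevalence cutoff), the expected
#' classifier AUC is
#' `Phi((E[PRS_case] - E[PRS_control]) / sqrt(Var[PRS_case] + Var[PRS_control]))`,
#' with `Phi` the standard normal CDF. The case/control mean difference
#' (`delta_prs`) is the plug-in estimate of the numerator; the observed
#' case and control score variances give the denominator.
#'
#' @param summary a `"prs_summary"` (see [prs_scores()]), or any list with
#'   `mean_case`, `mean_control`, `var_case`, `var_control`.
#' @return an object of class `"auc_prediction"`: list with `model`
#'   (`"liability"`), `value` in (0, 1), and `inputs_used`.
#' @examples
#' auc_liability(list(mean_case = 1, mean_control = 0,
#'                    var_case = 0.5, var_control = 0.5))$value # Phi(1)
#' @export
auc_liability <- function(summary) {
  need <- c("mean_case", "mean_control", "var_case", "var_control")
  if (!all(need %in% names(summary))) {
    stop("`summary` must carry ", paste(need, collapse = ", "))
  }
  tot_var <- summary$var_case + summary$var_control
  if (!is.finite(tot_var) || tot_var <= 0) {
    stop("total PRS variance must be positive")
  }
  z <- (summary$mean_case - summary$mean_control) / sqrt(tot_var)
  structure(
    list(model = "liability", value = stats::pnorm(z),
         inputs_used = summary[need]),
    class = "auc_prediction"
  )
}

#' Log-risk AUC prediction from the PRS coefficient of determination
#'
#' Under the log-risk reading of the polygenic score (the score is the log
#' disease risk of the genotype; rare disease, equal case/control score
#' variances), the expected AUC is
#' `Phi(sqrt(R2 * (1 - K)^2 / (2 P (1 - P))))`,
#' where `R2` is the coefficient of determination of PRS on the binary
#' phenotype, `K` the population prevalence and `P` the sample prevalence.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @param K population disease prevalence (default 0.01, the simulated
#'   baseline wild-type risk).
#' @param P sample prevalence (default 0.5, balanced case/control design).
#' @return an `"auc_prediction"` with `model = "log_risk"`.
#' @examples
#' auc_log_risk(0.5)$value # Phi(0.99)
#' @export
auc_log_risk <- function(r2, K = 0.01, P = 0.5) {
  stopifnot(length(r2) == 1L, length(K) == 1L, length(P) == 1L)
  if (!is.finite(r2) || r2 < 0 || r2 > 1) stop("`r2` must lie in [0, 1]")
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) stop("`K` and `P` must lie in (0, 1)")
  z <- sqrt(r2 * (1 - K)^2 / (2 * P * (1 - P)))
  # with r2 <= 1 the argument is capped at (1-K)/sqrt(2P(1-P))
  stopifnot(z <= (1 - K) / sqrt(2 * P * (1 - P)) + 1e-12)
  structure(
    list(model = "log_risk", value = stats::pnorm(z),
         inputs_used = list(r2 = r2, K = K, P = P)),
    class = "auc_prediction"
  )
}

#' @export
print.auc_prediction <- function(x, ...) {
  cat(sprintf("<auc_prediction> %s model: AUC = %.4f\n", x$model, x$value))
  invisible(x)
}

#' Contrast empirical AUC with the two analytic predictions
#'
#' Takes a replicate table (as produced by [run_grid()], or any data frame
#' carrying `delta_prs`, `auc`, `auc_liability` and `auc_log_risk` per
#' replicate) and returns the tidy comparison supporting AUC-versus-PRS
#' plots: one row per replicate with both analytic predictions and their
#' residuals against the empirical AUC. The analytic formulas were derived
#' for additive risk; rows for other inheritance modes are retained and
#' labeled so the contrast can be drawn per mode.
#'
#' @param records data frame with columns `delta_hat`, `delta_prs`, `auc`,
#'   `auc_liability`, `auc_log_risk` (and optionally `architecture`,
#'   `replicate`, `classifier`).
#' @return a tibble with the input identifiers plus `resid_liability =
#'   auc_liability - auc` and `resid_log_risk = auc_log_risk - auc`.
#' @export
compare_analytic_empirical <- function(records) {
  need <- c("delta_hat", "delta_prs", "auc", "auc_liability", "auc_log_risk")
  if (!all(need %in% names(records))) {
    stop("`records` must carry ", paste(need, collapse = ", "))
  }
  keep <- intersect(
    c("architecture", "delta_hat", "replicate", "classifier", "delta_prs",
      "auc", "auc_liability", "auc_log_risk"),
    names(records)
  )
  out <- tibble::as_tibble(records[, keep, drop = FALSE])
  out$resid_liability <- out$auc_liability - out$auc
  out$resid_log_risk <- out$auc_log_risk - out$auc
  out
}
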