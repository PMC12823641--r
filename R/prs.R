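#' Estimate per-site allelic odds-ratio PRS weights
#'
#' For every site, the risk allele frequency among cases (`f_cs`) and
#' controls (`f_ct`) is estimated as risk-allele count / (2 x group size),
#' and the allelic odds ratio is
#' `OR = f_cs (1 - f_ct) / (f_ct (1 - f_cs))`; the PRS weight is `ln(OR)`.
#' When any cell of the site's 2x2 allele-count table is zero the
#' Haldane-Anscombe continuity correction (add 0.5 to all four cells) is
#' applied, keeping the weight finite; corrected sites are flagged.
#'
#' @param train a `"cohort"` containing both cases and controls.
#' @return an object of class `"or_weights"`: a data.frame with one row per
#'   site and columns `site_id`, `f_cs`, `f_ct`, `or`, `ln_or`, `corrected`.
#' @examples
#' arch <- sample_architecture(c(additive = 20, null = 5), 0.005, seed = 1)
#' co <- simulate_cohort(arch, 200, 200, seed = 2)
#' head(estimate_or_weights(co))
#' @export
estimate_or_weights <- function(train) {
  stopifnot(inherits(train, "cohort"))
  case <- train$phenotype == 1L
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L) stop("training cohort must contain both cases and controls")

  risk_cs <- colSums(train$genotypes[case, , drop = FALSE])
  risk_ct <- colSums(train$genotypes[!case, , drop = FALSE])
  a <- as.numeric(risk_cs); b <- 2 * n1 - a   # case risk / non-risk alleles
  c_ <- as.numeric(risk_ct); d <- 2 * n0 - c_ # control risk / non-risk alleles
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[corrected] <- a[corrected] + 0.5; b[corrected] <- b[corrected] + 0.5
  c_[corrected] <- c_[corrected] + 0.5; d[corrected] <- d[corrected] + 0.5

  or <- (a * d) / (b * c_)
  out <- data.frame(
    site_id = train$site_ids,
    f_cs = a / (a + b), f_ct = c_ / (c_ + d),
    or = or, ln_or = log(or), corrected = corrected,
    stringsAsFactors = FALSE
  )
  class(out) <- c("or_weights", "data.frame")
  out
}

#' Polygenic risk scores and their case/control summary
#'
#' Scores every individual as `PRS = (1 / 2n) * sum_i ln(OR_i) X_i`, with
#' `n` the number of sites used, `X_i` the individual's risk-allele count at
#' site i, and `ln(OR_i)` the training-estimated weight. Summaries include
#' the case/control means and variances, their difference
#' `delta_prs = mean_case - mean_control`, the coefficient of determination
#' of the scores on the 0/1 phenotype (squared Pearson correlation, equal to
#' the R^2 of the simple linear regression of PRS on phenotype), and
#' Kolmogorov-Smirnov normality p-values for the case and control score
#' distributions.
#'
#' Weights are conventionally estimated on the training cohort and scores
#' computed out-of-sample on the test cohort.
#'
#' @param weights an `"or_weights"` object (site order must match `cohort`).
#' @param cohort a `"cohort"` to score.
#' @return an object of class `"prs_summary"`: list with `scores`,
#'   `mean_case`, `mean_control`, `delta_prs`, `var_case`, `var_control`,
#'   `r2`, `ks_p_case`, `ks_p_control`, `n_sites`.
#' @examples
#' arch <- sample_architecture(c(additive = 20, null = 5), 0.005, seed = 1)
#' tt <- make_train_test(arch, 200, 200, master_seed = 3)
#' w <- estimate_or_weights(tt$train)
#' prs_scores(w, tt$test)$delta_prs
#' @export
prs_scores <- function(weights, cohort) {
  stopifnot(inherits(weights, "or_weights"), inherits(cohort, "cohort"))
  if (!identical(weights$site_id, cohort$site_ids)) {
    stop("site mismatch between weights and cohort")
  }
  n <- nrow(weights)
  scores <- drop(cohort$genotypes %*% weights$ln_or) / (2 * n)
  case <- cohort$phenotype == 1L
  mean_case <- mean(scores[case]); mean_control <- mean(scores[!case])
  r2 <- if (stats::sd(scores) == 0) {
    0 # constant scores carry no phenotype information
  } else {
    stats::cor(scores, cohort$phenotype)^2
  }
  structure(
    list(scores = scores,
         mean_case = mean_case, mean_control = mean_control,
         delta_prs = mean_case - mean_control,
         var_case = stats::var(scores[case]),
         var_control = stats::var(scores[!case]),
         r2 = r2,
         ks_p_case = ks_normal_p(scores[case]),
         ks_p_control = ks_normal_p(scores[!case]),
         n_sites = n),
    class = "prs_summary"
  )
}

# One-sample KS test of normality with plug-in mean/sd (the convention used
# for the "PRS is approximately normal" check); ties in discrete-ish scores
# only warn, so warnings are suppressed.
ks_normal_p <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' @export
print.prs_summary <- function(x, ...) {
  cat("<prs_summary> ", length(x$scores), " scored individuals, ",
      x$n_sites, " sites\n", sep = "")
  cat(sprintf("  delta_prs = %.4g (case %.4g, control %.4g)\n",
              x$delta_prs, x$mean_case, x$mean_control))
  cat(sprintf("  var_case = %.3g, var_control = %.3g, r2 = %.3g\n",
              x$var_case, x$var_control, x$r2))
  invisible(x)
}

#' Tabulate PRS summaries over a delta-hat grid
#'
#' Collects per-replicate PRS summaries into a tidy table for studying how
#' the case/control PRS separation scales with the penetrance perturbation.
#'
#' @param summaries list of `"prs_summary"` objects.
#' @param delta_hat numeric vector (recycled if length 1) tagging each
#'   summary with its grid value.
#' @param replicate optional replicate index per summary.
#' @return a tibble with columns `delta_hat`, `replicate`, `delta_prs`,
#'   `var_case`, `var_control`, `r2`.
#' @export
delta_prs_curve <- function(summaries, delta_hat, replicate = seq_along(summaries)) {
  if (length(summaries) == 0L) stop("`summaries` must be non-empty")
  stopifnot(all(vapply(summaries, inherits, TRUE, "prs_summary")))
  delta_hat <- rep_len(delta_hat, length(summaries))
  tibble::tibble(
    delta_hat = delta_hat,
    replicate = replicate,
    delta_prs = vapply(summaries, `[[`, 0, "delta_prs"),
    var_case = vapply(summaries, `[[`, 0, "var_case"),
    var_control = vapply(summaries, `[[`, 0, "var_control"),
    r2 = vapply(summaries, `[[`, 0, "r2")
  )
}

#' Write PRS weights / scores as TSV
#'
#' @param weights an `"or_weights"` object.
#' @param summary a `"prs_summary"`.
#' @param cohort the `"cohort"` that was scored (for iid and phenotype).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_or_weights <- function(weights, path) {
  stopifnot(inherits(weights, "or_weights"))
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_or_weights
#' @export
write_prs_scores <- function(summary, cohort, path) {
  stopifnot(inherits(summary, "prs_summary"), inherits(cohort, "cohort"))
  df <- data.frame(
    iid = sprintf("ind_%05d", seq_along(cohort$phenotype)),
    phenotype = cohort$phenotype,
    prs = summary$scores,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
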