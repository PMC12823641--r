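# Fixture builders used across the suite. All fixtures are constructed in
# code; exact-parameter architectures bypass sampling so analytic oracles
# apply.

# Architecture with exactly the given per-site parameters.
make_arch <- function(p, mode, delta, f11 = 0.01, delta_hat = NA_real_) {
  L <- length(p)
  mode <- rep_len(mode, L)
  delta <- rep_len(delta, L)
  f12 <- ifelse(mode %in% c("dominant", "additive"), f11 + delta, f11)
  f22 <- ifelse(mode == "additive", f11 + 2 * delta,
                ifelse(mode == "null", f11, f11 + delta))
  structure(
    list(
      sites = data.frame(site_id = sprintf("site_%04d", seq_len(L)),
                         p = p, mode = mode, delta = delta,
                         f11 = f11, f12 = f12, f22 = f22,
                         stringsAsFactors = FALSE),
      f11_baseline = f11,
      delta_hat = if (is.na(delta_hat)) max(delta) else delta_hat,
      beta_a = 1.9195, beta_b = 5.6067,
      counts = table(mode), seed = NULL),
    class = "architecture")
}

# Cohort from an explicit genotype matrix and phenotype vector.
make_cohort <- function(G, y) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (is.null(colnames(G))) colnames(G) <- sprintf("site_%04d", seq_len(ncol(G)))
  structure(list(genotypes = G, phenotype = as.integer(y),
                 site_ids = colnames(G)),
            class = "cohort")
}

# PRS weights with given odds ratios.
make_weights <- function(or, site_ids = sprintf("site_%04d", seq_along(or))) {
  out <- data.frame(site_id = site_ids, f_cs = NA_real_, f_ct = NA_real_,
                    or = or, ln_or = log(or), corrected = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("or_weights", "data.frame")
  out
}

# Naive loop evaluation of the PRS definition, kept deliberately independent
# of the matrix implementation.
prs_loop_oracle <- function(G, ln_or) {
  n_sites <- length(ln_or)
  sapply(seq_len(nrow(G)), function(j) {
    acc <- 0
    for (i in seq_len(n_sites)) acc <- acc + ln_or[i] * G[j, i]
    acc / (2 * n_sites)
  })
}

# Default study-condition sizes used by the full-scale checks.
default_n <- 2000L
default_counts <- function(mode) architecture_counts(mode, 500L, 50L)
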