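#' Penetrance triple for a mode of inheritance
#'
#' Builds the genotype penetrances `(f11, f12, f22)` — the probabilities of
#' disease given 0, 1 or 2 copies of the risk allele — from a wild-type
#' baseline `f11` and an absolute penetrance increment `delta`:
#'
#' * recessive: `(f11, f11, f11 + delta)`
#' * dominant:  `(f11, f11 + delta, f11 + delta)`
#' * additive:  `(f11, f11 + delta, f11 + 2 delta)` (heterozygote exactly
#'   intermediate)
#' * null:      `(f11, f11, f11)` (requires `delta = 0`)
#'
#' Equivalently, with genotypic relative risk `gamma = 1 + delta / f11`,
#' these are the classical relations `f22 = gamma f12` (recessive),
#' `f22 = f12 = gamma f11` (dominant) and `f12 = gamma f11,
#' f22 = (2 gamma - 1) f11` (additive).
#'
#' @param mode one of `"additive"`, `"recessive"`, `"dominant"`, `"null"`.
#' @param f11 baseline penetrance of the wild-type homozygote, in (0, 1).
#' @param delta non-negative absolute penetrance increment. Combinations
#'   with `f11 + 2 * delta > 1` are rejected (the additive homozygote
#'   penetrance would leave `[0, 1]`); the model fails loudly rather than
#'   clipping.
#' @return named numeric vector `c(f11=, f12=, f22=)` of class
#'   `"penetrance_triple"`, non-decreasing in risk-allele count.
#' @examples
#' penetrance_from_mode("dominant", 0.01, 0.015)
#' penetrance_from_mode("additive", 0.01, 0.005)
#' @export
penetrance_from_mode <- function(mode = c("additive", "recessive", "dominant", "null"),
                                 f11, delta) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(f11), length(f11) == 1L, is.numeric(delta), length(delta) == 1L)
  if (f11 <= 0 || f11 >= 1) stop("`f11` must lie strictly in (0, 1)")
  if (delta < 0) stop("`delta` must be non-negative")
  if (f11 + 2 * delta > 1) {
    stop("invalid penetrance model: f11 + 2*delta = ", f11 + 2 * delta, " exceeds 1")
  }
  if (mode == "null" && delta != 0) stop("null sites must have delta = 0")
  triple <- switch(mode,
    recessive = c(f11, f11, f11 + delta),
    dominant  = c(f11, f11 + delta, f11 + delta),
    additive  = c(f11, f11 + delta, f11 + 2 * delta),
    null      = c(f11, f11, f11)
  )
  structure(stats::setNames(triple, c("f11", "f12", "f22")),
            class = "penetrance_triple")
}

#' Hardy-Weinberg genotype probabilities
#'
#' Probabilities of carrying 0, 1 or 2 copies of an allele with population
#' frequency `p`, under Hardy-Weinberg equilibrium.
#'
#' @param p allele frequency, strictly in (0, 1).
#' @return named numeric vector `c(g0=, g1=, g2=)` summing to 1.
#' @examples
#' hwe_genotype_probs(0.2)
#' @export
hwe_genotype_probs <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly in (0, 1)")
  stats::setNames(c((1 - p)^2, 2 * p * (1 - p), p^2), c("g0", "g1", "g2"))
}

#' Per-site disease prevalence
#'
#' The marginal disease probability contributed by one site,
#' `sum_g f(g) * P(g)` with `P(g)` the Hardy-Weinberg genotype
#' probabilities.
#'
#' @param p risk allele frequency in (0, 1).
#' @param pen penetrance triple (see [penetrance_from_mode()]), or any
#'   length-3 numeric of probabilities ordered by risk-allele count.
#' @return prevalence, a probability between `min(pen)` and `max(pen)`.
#' @examples
#' site_prevalence(0.5, c(0.01, 0.01, 0.02))
#' @export
site_prevalence <- function(p, pen) {
  pen <- as_penetrance(pen)
  sum(pen * hwe_genotype_probs(p))
}

#' Genotype distribution conditional on disease status
#'
#' Bayes inversion of the penetrance model at one site: the distribution of
#' the risk-allele count g given case status is
#' `P(g | case) = f(g) P(g) / K` and given control status
#' `P(g | control) = (1 - f(g)) P(g) / (1 - K)`, with `P(g)` the
#' Hardy-Weinberg marginal and `K` the site prevalence. Mixing the two
#' conditionals with weights `(K, 1 - K)` recovers the marginal exactly.
#'
#' @inheritParams site_prevalence
#' @param status `"case"` or `"control"`.
#' @return named probability vector over g in {0, 1, 2}.
#' @examples
#' genotype_given_status(0.5, c(0.01, 0.01, 0.02), "case")
#' @export
genotype_given_status <- function(p, pen, status = c("case", "control")) {
  status <- match.arg(status)
  pen <- as_penetrance(pen)
  hwe <- hwe_genotype_probs(p)
  prev <- sum(pen * hwe)
  if (prev <= 0 || prev >= 1) {
    stop("degenerate site prevalence ", prev, "; conditional distribution undefined")
  }
  if (status == "case") pen * hwe / prev else (1 - pen) * hwe / (1 - prev)
}

as_penetrance <- function(pen) {
  pen <- unclass(as.numeric(pen))
  if (length(pen) != 3L || anyNA(pen) || any(pen < 0) || any(pen > 1)) {
    stop("`pen` must be three probabilities (f11, f12, f22)")
  }
  pen
}
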