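#' Site-count compositions for the standard architectures
#'
#' Named presets for the simulated panel composition: 500 risk sites of one
#' inheritance mode plus 50 null sites (GWAS false-positive stand-ins), and
#' the two mixed architectures (400 additive + 100 dominant or recessive
#' + 50 null).
#'
#' @param name preset name.
#' @param n_risk,n_null number of risk and null sites for the pure presets.
#' @return named integer vector mapping mode to site count, suitable for
#'   [sample_architecture()].
#' @examples
#' architecture_counts("mixed_dominant")
#' @export
architecture_counts <- function(name = c("additive", "recessive", "dominant",
                                         "mixed_dominant", "mixed_recessive",
                                         "null"),
                                n_risk = 500L, n_null = 50L) {
  name <- match.arg(name)
  switch(name,
    additive  = c(additive  = n_risk, null = n_null),
    recessive = c(recessive = n_risk, null = n_null),
    dominant  = c(dominant  = n_risk, null = n_null),
    mixed_dominant  = c(additive = 400L, dominant  = 100L, null = n_null),
    mixed_recessive = c(additive = 400L, recessive = 100L, null = n_null),
    null = c(null = n_risk + n_null)
  )
}

#' Sample a genetic architecture
#'
#' Draws the per-site parameters of a simulated disease architecture. Each
#' site receives an independent risk allele frequency `p ~ Beta(beta_a,
#' beta_b)` (defaults fitted to the site frequency spectrum of genome-wide
#' significant GWAS SNPs: mean 0.255, variance 0.0223). Each risk site
#' additionally receives an independent penetrance increment
#' `delta ~ Uniform[0, 2 * delta_hat]`, so `E[delta] = delta_hat`; null
#' sites have `delta = 0`. Sites are ordered risk-first (in the order the
#' modes appear in `counts`), nulls last.
#'
#' @param counts named integer vector mapping inheritance mode to number of
#'   sites, e.g. `c(additive = 500, null = 50)`; see [architecture_counts()].
#' @param delta_hat expected penetrance perturbation, `>= 0`. Values with
#'   `f11 + 4 * delta_hat > 1` are rejected (the maximal additive homozygote
#'   penetrance would exceed 1).
#' @param f11 baseline wild-type penetrance (default 0.01).
#' @param beta_a,beta_b Beta shape parameters of the allele frequency
#'   distribution.
#' @param seed optional integer seed for the draw (the global RNG stream is
#'   left untouched when supplied).
#' @return an object of class `"architecture"`: a list with `sites` (a
#'   data.frame of site_id, p, mode, delta, f11, f12, f22), the scalar
#'   parameters, and `counts`.
#' @examples
#' arch <- sample_architecture(architecture_counts("dominant"),
#'                             delta_hat = 0.002, seed = 1)
#' head(arch$sites)
#' @export
sample_architecture <- function(counts, delta_hat,
                                f11 = 0.01,
                                beta_a = 1.9195, beta_b = 5.6067,
                                seed = NULL) {
  modes <- names(counts)
  if (is.null(modes) || !all(modes %in% c("additive", "recessive", "dominant", "null"))) {
    stop("`counts` must be a named vector with names among ",
         "additive/recessive/dominant/null")
  }
  counts <- as.integer(counts)
  names(counts) <- modes
  if (any(counts < 0)) stop("site counts must be non-negative")
  if (delta_hat < 0) stop("`delta_hat` must be non-negative")
  if (f11 + 4 * delta_hat > 1) {
    stop("invalid grid point: f11 + 4*delta_hat = ", f11 + 4 * delta_hat,
         " exceeds 1 (penetrance would leave [0, 1])")
  }
  if (beta_a <= 0 || beta_b <= 0) stop("Beta shape parameters must be positive")

  # risk modes keep their configured block order; nulls go last
  modes <- c(setdiff(modes, "null"), intersect(modes, "null"))
  counts <- counts[modes]
  L <- sum(counts)
  site_mode <- rep(modes, counts)

  with_seed_or_current(seed, {
    p <- stats::rbeta(L, beta_a, beta_b)
    delta <- ifelse(site_mode == "null", 0, stats::runif(L, 0, 2 * delta_hat))
  })

  f12 <- ifelse(site_mode %in% c("dominant", "additive"), f11 + delta, f11)
  f22 <- ifelse(site_mode == "additive", f11 + 2 * delta,
                ifelse(site_mode == "null", f11, f11 + delta))
  sites <- data.frame(
    site_id = sprintf("site_%04d", seq_len(L)),
    p = p, mode = site_mode, delta = delta,
    f11 = f11, f12 = f12, f22 = f22,
    stringsAsFactors = FALSE
  )
  structure(
    list(sites = sites, f11_baseline = f11, delta_hat = delta_hat,
         beta_a = beta_a, beta_b = beta_b, counts = counts, seed = seed),
    class = "architecture"
  )
}

#' @export
print.architecture <- function(x, ...) {
  comp <- paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = " + ")
  cat("<architecture> ", comp, "\n", sep = "")
  cat("  delta_hat = ", format(x$delta_hat),
      ", f11 = ", format(x$f11_baseline),
      ", p ~ Beta(", format(x$beta_a), ", ", format(x$beta_b), ")\n", sep = "")
  invisible(x)
}

#' Write / read an architecture as JSON
#'
#' Serializes the full per-site table (site_id, p, mode, delta, f11, f12,
#' f22) together with the top-level parameters, so a simulated architecture
#' can be archived and re-loaded exactly.
#'
#' @param arch an `"architecture"` object.
#' @param path file path.
#' @return `write_architecture` returns `path` invisibly;
#'   `read_architecture` returns the restored `"architecture"`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "architecture"))
  doc <- list(
    f11_baseline = arch$f11_baseline, delta_hat = arch$delta_hat,
    beta_a = arch$beta_a, beta_b = arch$beta_b,
    seed = arch$seed, counts = as.list(arch$counts),
    sites = arch$sites
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- unlist(doc$counts)
  structure(
    list(sites = as.data.frame(doc$sites), f11_baseline = doc$f11_baseline,
         delta_hat = doc$delta_hat, beta_a = doc$beta_a, beta_b = doc$beta_b,
         counts = stats::setNames(as.integer(counts), names(counts)),
         seed = doc$seed),
    class = "architecture"
  )
}
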