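#' Simulate a balanced case/control cohort
#'
#' Disease status is assigned first (`n_case` cases, `n_control` controls);
#' the genotype at every site is then drawn independently from the
#' site's genotype distribution conditional on that status (see
#' [genotype_given_status()]). Because sampling is conditional on status
#' with balanced groups, no genome-wide prevalence is simulated; each site
#' uses its own marginal prevalence. Sites are in the architecture's order.
#'
#' Sampling is vectorized: one uniform draw per genotype, inverted through
#' the per-site conditional CDF.
#'
#' @param arch an `"architecture"` from [sample_architecture()].
#' @param n_case,n_control cohort group sizes (default 2000 each).
#' @param seed optional integer seed (global RNG untouched when supplied).
#' @return an object of class `"cohort"`: list with `genotypes` (an
#'   `n x L` integer matrix of risk-allele counts 0/1/2, columns named by
#'   site), `phenotype` (0 = control, 1 = case; cases first) and `site_ids`.
#' @examples
#' arch <- sample_architecture(c(additive = 20, null = 5), 0.005, seed = 1)
#' co <- simulate_cohort(arch, n_case = 100, n_control = 100, seed = 2)
#' table(co$phenotype)
#' @export
simulate_cohort <- function(arch, n_case = 2000L, n_control = 2000L, seed = NULL) {
  stopifnot(inherits(arch, "architecture"))
  if (n_case < 1L || n_control < 1L) stop("group sizes must be positive")
  s <- arch$sites
  L <- nrow(s)
  hwe <- cbind((1 - s$p)^2, 2 * s$p * (1 - s$p), s$p^2)
  pen <- cbind(s$f11, s$f12, s$f22)
  prev <- rowSums(pen * hwe)
  if (any(prev <= 0 | prev >= 1)) {
    stop("degenerate site prevalence; cannot condition on disease status")
  }
  p_case <- pen * hwe / prev
  p_ctrl <- (1 - pen) * hwe / (1 - prev)

  draw <- function(n, probs) {
    # probs: L x 3 conditional genotype probabilities
    c1 <- matrix(probs[, 1], n, L, byrow = TRUE)
    c2 <- matrix(probs[, 1] + probs[, 2], n, L, byrow = TRUE)
    U <- matrix(stats::runif(n * L), n, L)
    matrix(as.integer((U > c1) + (U > c2)), n, L)
  }
  G <- with_seed_or_current(seed,
    rbind(draw(n_case, p_case), draw(n_control, p_ctrl)))
  colnames(G) <- s$site_id
  structure(
    list(genotypes = G,
         phenotype = rep(c(1L, 0L), c(n_case, n_control)),
         site_ids = s$site_id),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$phenotype), " individuals (",
      sum(x$phenotype == 1L), " case / ", sum(x$phenotype == 0L),
      " control) x ", length(x$site_ids), " sites\n", sep = "")
  invisible(x)
}

#' Simulate paired training and test cohorts
#'
#' Two independent balanced cohorts drawn from the same architecture, using
#' decorrelated substreams (`"train"`, `"test"`) of one master seed.
#'
#' @inheritParams simulate_cohort
#' @param master_seed integer seed from which the two cohort streams are
#'   derived with [derive_seed()].
#' @return list with elements `train` and `test`, each a `"cohort"`.
#' @examples
#' arch <- sample_architecture(c(additive = 20, null = 5), 0.005, seed = 1)
#' tt <- make_train_test(arch, n_case = 50, n_control = 50, master_seed = 9)
#' @export
make_train_test <- function(arch, n_case = 2000L, n_control = 2000L, master_seed = 1L) {
  list(
    train = simulate_cohort(arch, n_case, n_control,
                            seed = derive_seed(master_seed, "train")),
    test  = simulate_cohort(arch, n_case, n_control,
                            seed = derive_seed(master_seed, "test"))
  )
}

#' Cohort TSV input/output
#'
#' The canonical genotype dialect is a TSV with header
#' `iid<TAB>phenotype<TAB><site ids...>`, one row per individual, phenotype
#' coded 0 (control) / 1 (case) and genotype cells the risk-allele count
#' 0/1/2. `write_cohort_raw()` additionally writes a PLINK `.raw`-style
#' additive table (`FID IID PAT MAT SEX PHENOTYPE` then per-site counts,
#' phenotype coded 1 = control / 2 = case) for interoperability; the TSV
#' dialect is canonical and round-trips through `read_cohort_tsv()`.
#'
#' @param cohort a `"cohort"`.
#' @param path output file path.
#' @return the writers return `path` invisibly; `read_cohort_tsv()` returns
#'   a `"cohort"`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(
    iid = sprintf("ind_%05d", seq_along(cohort$phenotype)),
    phenotype = cohort$phenotype,
    cohort$genotypes,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("iid", "phenotype") == names(df)[1:2])) {
    stop("not a cohort TSV: first columns must be iid, phenotype")
  }
  G <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(G) <- "integer"
  if (!all(G %in% 0:2)) stop("genotype cells must be 0, 1 or 2")
  structure(
    list(genotypes = G, phenotype = as.integer(df$phenotype),
         site_ids = colnames(G)),
    class = "cohort"
  )
}

#' @rdname write_cohort_tsv
#' @export
write_cohort_raw <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  iid <- sprintf("ind_%05d", seq_along(cohort$phenotype))
  df <- data.frame(
    FID = iid, IID = iid, PAT = 0L, MAT = 0L, SEX = 0L,
    PHENOTYPE = cohort$phenotype + 1L,
    cohort$genotypes,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
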