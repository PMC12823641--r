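#' Classifier specification
#'
#' A lightweight container naming one of the four benchmarked families and
#' its hyperparameters. Defaults:
#'
#' * `LR` — logistic regression with a minimal ridge penalty
#'   (`lambda = 1e-4`, via glmnet) for robustness to quasi-separation at
#'   strong signal;
#' * `NB` — Gaussian naive Bayes on the 0/1/2 genotype encoding (e1071 fit);
#' * `RF` — probability random forest, 500 trees, `floor(sqrt(L))` candidate
#'   features per split (ranger backend);
#' * `NN` — single-hidden-layer feed-forward network (nnet), 4 logistic
#'   units, weight decay 1e-3, 100 BFGS iterations, sized so that fitting
#'   4000 genomes x 550 sites stays tractable.
#'
#' @param family one of `"LR"`, `"NB"`, `"RF"`, `"NN"`.
#' @param ... family-specific hyperparameter overrides (`lambda` for LR;
#'   `num_trees`, `mtry` for RF; `size`, `decay`, `maxit` for NN).
#' @return an object of class `"classifier_spec"`.
#' @examples
#' classifier_spec("RF", num_trees = 200)
#' @export
classifier_spec <- function(family = c("LR", "NB", "RF", "NN"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    LR = list(lambda = 1e-4),
    NB = list(),
    RF = list(num_trees = 500L, mtry = NULL),
    NN = list(size = 4L, decay = 1e-3, maxit = 100L)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", family, ": ",
         paste(unknown, collapse = ", "))
  }
  structure(list(family = family, params = utils::modifyList(defaults, override)),
            class = "classifier_spec")
}

#' LASSO feature selection with a retention floor
#'
#' Fits an L1-penalized logistic model of phenotype on genotypes over a grid
#' of penalties and returns the selected site subset. A candidate penalty
#' qualifies only if it retains at least `min_fraction` of the sites
#' (default 10%); among qualifying penalties the one minimizing 5-fold
#' cross-validated binomial deviance is chosen. If no grid point qualifies,
#' selection is reported as failed (`failed = TRUE`) and callers run without
#' feature selection.
#'
#' @param train a `"cohort"`.
#' @param lambda_grid candidate penalties (default 0 to 0.05 in steps of
#'   0.01).
#' @param min_fraction minimal fraction of sites a qualifying mask must
#'   retain.
#' @param nfolds folds for the cross-validated deviance used to pick among
#'   qualifying penalties.
#' @param thresh coordinate-descent convergence threshold passed to glmnet.
#'   Selection only needs the support set and the fold-level deviance
#'   ordering, both stable well above glmnet's default `1e-7`; the looser
#'   default avoids very slow unpenalized (`lambda = 0`) fits.
#' @param seed optional seed (controls fold assignment).
#' @return an object of class `"feature_mask"`: list with `retained`
#'   (ordered site ids), `lambda_used`, `fraction_retained`, `failed`.
#' @examples
#' arch <- sample_architecture(c(additive = 30, null = 5), 0.005, seed = 1)
#' co <- simulate_cohort(arch, 150, 150, seed = 2)
#' mask <- lasso_select(co, seed = 3)
#' mask$fraction_retained
#' @export
lasso_select <- function(train, lambda_grid = seq(0, 0.05, by = 0.01),
                         min_fraction = 0.10, nfolds = 5L, thresh = 1e-5,
                         seed = NULL) {
  stopifnot(inherits(train, "cohort"))
  if (length(lambda_grid) == 0L) stop("`lambda_grid` must be non-empty")
  if (any(lambda_grid < 0)) stop("penalties must be non-negative")
  y <- train$phenotype
  if (length(unique(y)) < 2L) stop("degenerate training labels")
  x <- train$genotypes
  storage.mode(x) <- "double"
  L <- ncol(x)
  lambda <- sort(unique(lambda_grid), decreasing = TRUE)

  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = lambda,
                        thresh = thresh)
  nonzero <- vapply(seq_along(fit$lambda),
                    function(k) sum(abs(fit$beta[, k]) > 0), 0L)
  qualifies <- nonzero > 0L & (nonzero / L) >= min_fraction
  if (!any(qualifies)) {
    return(structure(list(retained = character(), lambda_used = NA_real_,
                          fraction_retained = 0, failed = TRUE),
                     class = "feature_mask"))
  }

  if (sum(qualifies) == 1L || length(lambda) < 2L) {
    best <- which(qualifies)[1L]
  } else {
    foldid <- with_seed_or_current(seed, sample(rep_len(seq_len(nfolds), length(y))))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lambda, foldid = foldid,
                            type.measure = "deviance", thresh = thresh)
    cvm <- cv$cvm[match(fit$lambda, cv$lambda)]
    best <- which(qualifies)[which.min(cvm[qualifies])]
  }
  retained <- rownames(fit$beta)[abs(fit$beta[, best]) > 0]
  structure(
    list(retained = retained,
         lambda_used = fit$lambda[best],
         fraction_retained = length(retained) / L,
         failed = FALSE),
    class = "feature_mask"
  )
}

#' Fit a classifier on a training cohort and score a test cohort
#'
#' Trains the requested family on the (optionally feature-masked) training
#' genotypes and returns one real-valued score per test individual; larger
#' scores are more case-like. Stochastic families (RF, NN) are deterministic
#' given `seed`. Non-convergence is flagged (attribute `converged`), never
#' silently dropped.
#'
#' @param spec a `"classifier_spec"` (or a family name, which is promoted
#'   with default hyperparameters).
#' @param train,test `"cohort"` objects sharing the same site order.
#' @param mask optional `"feature_mask"` restricting the sites used.
#' @param seed optional integer seed for stochastic families.
#' @return numeric vector of test scores with attributes `converged`
#'   (logical) and `family`.
#' @examples
#' arch <- sample_architecture(c(dominant = 20, null = 5), 0.01, seed = 1)
#' tt <- make_train_test(arch, 150, 150, master_seed = 4)
#' sc <- fit_predict("LR", tt$train, tt$test)
#' auc_empirical(sc, tt$test$phenotype)$auc
#' @export
fit_predict <- function(spec, train, test, mask = NULL, seed = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "cohort"), inherits(test, "cohort"))
  if (!identical(train$site_ids, test$site_ids)) {
    stop("train and test cohorts must share site order")
  }
  cols <- train$site_ids
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "feature_mask"))
    if (mask$failed) stop("cannot apply a failed feature mask")
    if (!all(mask$retained %in% cols)) stop("mask sites absent from cohort")
    cols <- mask$retained
  }
  xtr <- train$genotypes[, cols, drop = FALSE]
  xte <- test$genotypes[, cols, drop = FALSE]
  storage.mode(xtr) <- "double"; storage.mode(xte) <- "double"
  y <- train$phenotype
  if (length(unique(y)) < 2L) stop("degenerate training labels")
  p <- spec$params
  converged <- TRUE

  scores <- switch(spec$family,
    LR = {
      # short warm-start path down to the target ridge penalty; glmnet needs
      # at least two columns, so a single-site model gets a zero dummy
      if (ncol(xtr) == 1L) {
        xtr <- cbind(xtr, `.dummy` = 0)
        xte <- cbind(xte, `.dummy` = 0)
      }
      path <- sort(unique(c(1, 0.1, 0.01, p$lambda)), decreasing = TRUE)
      fit <- glmnet::glmnet(xtr, y, family = "binomial", alpha = 0, lambda = path)
      drop(stats::predict(fit, xte, s = p$lambda))
    },
    NB = {
      fit <- e1071::naiveBayes(x = xtr, y = factor(y, levels = 0:1))
      nb_log_odds(fit, xte)
    },
    RF = {
      mtry <- if (is.null(p$mtry)) floor(sqrt(ncol(xtr))) else p$mtry
      fit <- ranger::ranger(x = xtr, y = factor(y, levels = 0:1),
                            num.trees = p$num_trees, mtry = mtry,
                            probability = TRUE, num.threads = 1L,
                            seed = if (is.null(seed)) 1L else seed)
      stats::predict(fit, xte, num.threads = 1L)$predictions[, "1"]
    },
    NN = {
      fit <- with_seed_or_current(seed,
        nnet::nnet(x = xtr, y = y, size = p$size, decay = p$decay,
                   maxit = p$maxit, entropy = TRUE, trace = FALSE,
                   MaxNWts = (ncol(xtr) + 2L) * p$size + 1L))
      converged <- isTRUE(fit$convergence == 0)
      drop(stats::predict(fit, xte))
    }
  )
  structure(as.numeric(scores), converged = converged, family = spec$family)
}

# Vectorized Gaussian naive Bayes log-odds from an e1071 fit. Equivalent to
# predict(fit, type = "raw") (checked to ~1e-13) but O(n p) in compiled
# arithmetic instead of an R-level loop over rows. Class-conditional sds of
# zero (constant feature within a class) are floored to keep scores finite.
nb_log_odds <- function(fit, x) {
  mu <- vapply(fit$tables, function(t) t[, 1], numeric(2))  # 2 x p
  sd_ <- vapply(fit$tables, function(t) t[, 2], numeric(2))
  sd_ <- pmax(sd_, 1e-6)
  loglik <- function(cls) {
    -0.5 * colSums((t(x) - mu[cls, ])^2 / sd_[cls, ]^2) - sum(log(sd_[cls, ]))
  }
  prior <- fit$apriori / sum(fit$apriori)
  loglik(2L) - loglik(1L) + log(prior[2L] / prior[1L])
}

#' Empirical ROC curve and AUC
#'
#' Computes the area under the ROC curve by the rank-sum (Mann-Whitney)
#' identity with mid-ranks for ties — the probability that a random case
#' outscores a random control, counting ties as 1/2 — together with the
#' tie-grouped ROC curve itself (thresholds swept over distinct score
#' values; endpoints (0,0) and (1,1)). The trapezoidal area under the curve
#' equals the rank-sum AUC.
#'
#' @param scores numeric scores, larger = more case-like.
#' @param labels binary labels (1 = case, 0 = control); both classes must be
#'   present.
#' @return an object of class `"roc_result"`: list with `auc`, `curve`
#'   (data.frame of `fpr`, `tpr`), `n_case`, `n_control`.
#' @examples
#' auc_empirical(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc
#' @export
auc_empirical <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  r <- rank(scores) # mid-ranks for ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tpr <- c(0, cumsum(y)[keep] / n1)
  fpr <- c(0, cumsum(1 - y)[keep] / n0)
  structure(
    list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
         n_case = n1, n_control = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d case / %d control)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' Write per-individual classifier predictions as TSV
#'
#' One row per test individual: `iid`, `label`, `score`, `classifier`,
#' `fs_flag` (whether the scores came from a feature-selected fit).
#'
#' @param scores numeric score vector from [fit_predict()].
#' @param cohort the scored `"cohort"` (for ids and labels).
#' @param path output file path.
#' @param feature_selection logical flag recorded per row.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(scores, cohort, path, feature_selection = FALSE) {
  stopifnot(inherits(cohort, "cohort"),
            length(scores) == length(cohort$phenotype))
  fam <- attr(scores, "family")
  df <- data.frame(
    iid = sprintf("ind_%05d", seq_along(cohort$phenotype)),
    label = cohort$phenotype,
    score = as.numeric(scores),
    classifier = if (is.null(fam)) NA_character_ else fam,
    fs_flag = feature_selection,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve data.frame with `fpr`, `tpr` columns ordered from (0,0) to
#'   (1,1), as produced by [auc_empirical()].
#' @return the trapezoidal area, equal to the rank-sum AUC.
#' @export
roc_trapezoid <- function(curve) {
  n <- nrow(curve)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-n]) / 2)
}
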