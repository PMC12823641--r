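#' Grid configuration for the full simulation experiment
#'
#' Bundles and validates everything [run_grid()] needs: the delta-hat grid
#' (default 16 values, 0 to 0.0075 in steps of 0.0005), the architectures
#' (any of the [architecture_counts()] presets), the replicate count, the
#' classifier families, the feature-selection arms, cohort sizes, and the
#' master seed from which every random stream is derived.
#'
#' @param delta_hat_values non-negative, sorted grid of expected penetrance
#'   perturbations.
#' @param architectures character vector of preset names (see
#'   [architecture_counts()]).
#' @param replicates Monte Carlo replicates per grid cell (default 100; use
#'   ~10 for desk-scale runs).
#' @param classifiers families to benchmark, subset of LR/NB/RF/NN.
#' @param feature_selection `"off"`, `"on"`, or `"both"` (runs both arms).
#' @param n_case,n_control per-cohort group sizes (train and test each get
#'   `n_case + n_control` genomes).
#' @param n_risk,n_null panel composition for the pure presets.
#' @param f11 baseline wild-type penetrance.
#' @param beta_a,beta_b Beta shape parameters of the allele frequency model.
#' @param fresh_architecture if `TRUE` (default) a new architecture (new
#'   allele frequencies and per-site deltas) is drawn for every replicate;
#'   if `FALSE` one architecture per (architecture, delta-hat) cell is
#'   shared by all its replicates.
#' @param master_seed integer; the run is a pure function of the config and
#'   this seed.
#' @return validated list of class `"grid_config"`.
#' @examples
#' cfg <- grid_config(delta_hat_values = c(0, 0.002), replicates = 2,
#'                    classifiers = "LR", n_case = 100, n_control = 100,
#'                    n_risk = 20, n_null = 5)
#' @export
grid_config <- function(delta_hat_values = seq(0, 0.0075, by = 5e-4),
                        architectures = "additive",
                        replicates = 100L,
                        classifiers = c("LR", "NB", "RF", "NN"),
                        feature_selection = c("off", "on", "both"),
                        n_case = 2000L, n_control = 2000L,
                        n_risk = 500L, n_null = 50L,
                        f11 = 0.01,
                        beta_a = 1.9195, beta_b = 5.6067,
                        fresh_architecture = TRUE,
                        master_seed = 1L) {
  feature_selection <- match.arg(feature_selection)
  classifiers <- match.arg(classifiers, c("LR", "NB", "RF", "NN"),
                           several.ok = TRUE)
  if (any(delta_hat_values < 0)) stop("delta-hat values must be non-negative")
  if (is.unsorted(delta_hat_values)) stop("delta-hat values must be sorted")
  if (replicates < 1L) stop("`replicates` must be at least 1")
  valid_arch <- c("additive", "recessive", "dominant",
                  "mixed_dominant", "mixed_recessive", "null")
  if (!all(architectures %in% valid_arch)) {
    stop("unknown architecture preset(s): ",
         paste(setdiff(architectures, valid_arch), collapse = ", "))
  }
  structure(
    list(delta_hat_values = delta_hat_values, architectures = architectures,
         replicates = as.integer(replicates), classifiers = classifiers,
         feature_selection = feature_selection,
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_risk = as.integer(n_risk), n_null = as.integer(n_null),
         f11 = f11, beta_a = beta_a, beta_b = beta_b,
         fresh_architecture = isTRUE(fresh_architecture),
         master_seed = as.integer(master_seed)),
    class = "grid_config"
  )
}

#' Read / write a grid configuration (YAML or JSON)
#'
#' @param config a `"grid_config"`.
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `read_grid_config()` returns a validated `"grid_config"`;
#'   `write_grid_config()` returns `path` invisibly.
#' @export
write_grid_config <- function(config, path) {
  stopifnot(inherits(config, "grid_config"))
  doc <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(path) {
  doc <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(grid_config, doc)
}

#' Benchmark one simulated replicate
#'
#' Runs the full per-replicate pipeline on a given architecture: simulate
#' independent balanced train/test cohorts, estimate allelic ln(OR) weights
#' on the training cohort, score the test cohort (PRS summaries, liability
#' and log-risk AUC predictions), optionally LASSO-select features, then
#' fit each requested classifier (with and/or without the mask) and measure
#' its test-set AUC.
#'
#' @param arch an `"architecture"`.
#' @param classifiers character vector of families, or list of
#'   [classifier_spec()] objects.
#' @param feature_selection `"off"`, `"on"`, or `"both"`.
#' @param n_case,n_control cohort group sizes.
#' @param seed integer master seed for this replicate; cohorts, fold
#'   assignment and stochastic classifiers all use named substreams of it.
#' @return a tibble with one row per classifier x feature-selection arm:
#'   identifiers, test AUC, the replicate's PRS summary statistics
#'   (`delta_prs`, `var_case`, `var_control`, `r2`), the two analytic AUC
#'   predictions, convergence status and the mask bookkeeping.
#' @examples
#' arch <- sample_architecture(c(dominant = 20, null = 5), 0.01, seed = 1)
#' benchmark_replicate(arch, "LR", n_case = 100, n_control = 100, seed = 7)
#' @export
benchmark_replicate <- function(arch, classifiers = "LR",
                                feature_selection = c("off", "on", "both"),
                                n_case = 2000L, n_control = 2000L,
                                seed = 1L) {
  feature_selection <- match.arg(feature_selection)
  if (is.character(classifiers)) {
    classifiers <- lapply(classifiers, classifier_spec)
  }
  stopifnot(all(vapply(classifiers, inherits, TRUE, "classifier_spec")))

  tt <- make_train_test(arch, n_case, n_control, master_seed = seed)
  w <- estimate_or_weights(tt$train)
  ps <- prs_scores(w, tt$test)
  pred_liab <- auc_liability(ps)$value
  pred_logr <- auc_log_risk(ps$r2)$value

  arms <- switch(feature_selection, off = FALSE, on = TRUE, both = c(FALSE, TRUE))
  mask <- NULL
  fs_failed <- FALSE
  if (any(arms)) {
    mask <- lasso_select(tt$train, seed = derive_seed(seed, "lasso"))
    if (mask$failed) {
      fs_failed <- TRUE
      mask <- NULL # arm runs without selection, flagged
    }
  }

  rows <- list()
  for (spec in classifiers) {
    for (fs in arms) {
      sc <- fit_predict(spec, tt$train, tt$test,
                        mask = if (fs) mask else NULL,
                        seed = derive_seed(seed, spec$family, fs))
      roc <- auc_empirical(sc, tt$test$phenotype)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        delta_hat = arch$delta_hat,
        classifier = spec$family,
        feature_selection = fs,
        fs_failed = fs && fs_failed,
        lambda_used = if (fs && !is.null(mask)) mask$lambda_used else NA_real_,
        fraction_retained = if (fs && !is.null(mask)) mask$fraction_retained else NA_real_,
        auc = roc$auc,
        delta_prs = ps$delta_prs,
        var_case = ps$var_case, var_control = ps$var_control,
        r2 = ps$r2,
        auc_liability = pred_liab, auc_log_risk = pred_logr,
        converged = attr(sc, "converged"),
        seed = seed
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full simulation grid
#'
#' Loops over architectures x delta-hat values x replicates, running
#' [benchmark_replicate()] in every cell. Every random stream is a named
#' substream of `config$master_seed`, so the output is a pure function of
#' the configuration; any single replicate can be reproduced in isolation.
#' Per-replicate classifier failures are recorded in the `converged` column
#' and the run continues.
#'
#' @param config a `"grid_config"`.
#' @param progress if `TRUE`, writes one line per grid cell to stderr.
#' @return a tibble of replicate records with columns `architecture`,
#'   `delta_hat`, `replicate`, `classifier`, `feature_selection`,
#'   `fs_failed`, `lambda_used`, `fraction_retained`, `auc`, `delta_prs`,
#'   `var_case`, `var_control`, `r2`, `auc_liability`, `auc_log_risk`,
#'   `converged`, `seed`.
#' @examples
#' cfg <- grid_config(delta_hat_values = c(0, 0.005), replicates = 2,
#'                    classifiers = "LR", n_case = 60, n_control = 60,
#'                    n_risk = 15, n_null = 5, master_seed = 42)
#' head(run_grid(cfg))
#' @export
run_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  out <- list()
  for (arch_name in config$architectures) {
    counts <- architecture_counts(arch_name, config$n_risk, config$n_null)
    for (dh in config$delta_hat_values) {
      if (progress) {
        message(sprintf("grid cell: %s, delta_hat = %g", arch_name, dh))
      }
      cell_arch <- NULL
      if (!config$fresh_architecture) {
        cell_arch <- sample_architecture(
          counts, dh, config$f11, config$beta_a, config$beta_b,
          seed = derive_seed(config$master_seed, arch_name, dh, "arch"))
      }
      for (rep_i in seq_len(config$replicates)) {
        rep_seed <- derive_seed(config$master_seed, arch_name, dh, rep_i)
        arch <- if (config$fresh_architecture) {
          sample_architecture(counts, dh, config$f11, config$beta_a,
                              config$beta_b,
                              seed = derive_seed(rep_seed, "arch"))
        } else {
          cell_arch
        }
        rec <- benchmark_replicate(
          arch, config$classifiers, config$feature_selection,
          config$n_case, config$n_control, seed = rep_seed)
        rec$architecture <- arch_name
        rec$replicate <- rep_i
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  rec <- dplyr::bind_rows(out)
  front <- c("architecture", "delta_hat", "replicate", "classifier",
             "feature_selection")
  rec <- rec[, c(front, setdiff(names(rec), front))]
  dplyr::arrange(rec, .data$architecture, .data$delta_hat, .data$replicate,
                 .data$classifier, .data$feature_selection)
}

#' Grouped summaries of a replicate table
#'
#' Mean, standard deviation and standard error (sd / sqrt(replicates)) of
#' AUC and delta-PRS per (architecture x delta-hat x classifier x
#' feature-selection) cell — the quantities behind mean-AUC-versus-delta-hat
#' curves with +/- 2 standard error intervals.
#'
#' @param records a replicate table from [run_grid()].
#' @return a tibble with one row per cell.
#' @export
summarize_grid <- function(records) {
  if (nrow(records) == 0L) stop("`records` must be non-empty")
  dplyr::summarise(
    dplyr::group_by(records, .data$architecture, .data$delta_hat,
                    .data$classifier, .data$feature_selection),
    n = dplyr::n(),
    mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
    se_auc = stats::sd(.data$auc) / sqrt(dplyr::n()),
    mean_delta_prs = mean(.data$delta_prs),
    sd_delta_prs = stats::sd(.data$delta_prs),
    se_delta_prs = stats::sd(.data$delta_prs) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Pooled Pearson correlation between AUC and delta-PRS
#'
#' For each architecture (and feature-selection arm), pools the
#' replicate-level (AUC, delta-PRS) pairs of one classifier across the
#' whole delta-hat grid and computes their Pearson correlation — the
#' summary used to quantify how tightly the PRS separation tracks
#' classifier performance.
#'
#' @param records a replicate table from [run_grid()].
#' @param classifier family whose AUC is correlated (default `"LR"`).
#' @return tibble with `architecture`, `feature_selection`, `n_pairs`,
#'   `correlation`. Degenerate groups (constant AUC or delta-PRS) yield
#'   `NA` with a warning.
#' @export
auc_prs_correlation <- function(records, classifier = "LR") {
  rec <- records[records$classifier == classifier, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for classifier ", classifier)
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$architecture, .data$feature_selection),
    n_pairs = dplyr::n(),
    correlation = if (stats::sd(.data$auc) == 0 || stats::sd(.data$delta_prs) == 0) {
      NA_real_
    } else {
      stats::cor(.data$auc, .data$delta_prs)
    },
    .groups = "drop"
  )
  if (anyNA(out$correlation)) {
    warning("correlation undefined for groups with constant AUC or delta-PRS")
  }
  out
}

#' Write a replicate or summary table as TSV
#'
#' @param records data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @importFrom dplyr .data
NULL
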