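#' Run the full prediction pipeline on a feature table
#'
#' Orchestrates the modeling chain on a subject-level feature table:
#' outlier-based feature filtering (reference statistics from the
#' training split), a 55/15/30 train/validation/test split, univariate
#' screening at p < 0.05 (Cox for continuous, chi-squared for
#' categorical), sequential forward selection against validation
#' concordance, neural Cox model training (single spec or exhaustive
#' grid), and evaluation on the held-out test split: C-index,
#' time-dependent AUC at the requested horizons, personalized survival
#' curves, and 3.3-month/50% risk stratification with a log-rank test
#' between the predicted risk groups. Every stage seed derives from the
#' master seed by a fixed offset, so a rerun reproduces identical
#' results.
#'
#' @param features data.frame of subject-level features (numeric and/or
#'   factor columns).
#' @param outcome data.frame with `time` (months) and `event`.
#' @param seed master seed.
#' @param split optional precomputed split (list train/validation/test);
#'   by default drawn from `seed`.
#' @param fractions split fractions (default 55/15/30).
#' @param alpha screening gate (default 0.05).
#' @param max_features SFS cap (default 10).
#' @param network a [networkSpec()] or NULL for the default
#'   architecture; ignored when `grid` is given.
#' @param grid optional list of [networkSpec()] for grid search.
#' @param eval_times ROC horizons in months (default 1, 2, 3, 6).
#' @param outlier_filter apply [outlierFilter()] to numeric columns
#'   (default TRUE).
#' @param stratify_months,stratify_cut stratification rule (defaults
#'   3.3 months, 0.5).
#' @return a list with elements `split`, `filter_report`, `screening`,
#'   `selection`, `fit`, `test` (scores, cindex, roc, stratification,
#'   log-rank), and `config`.
#' @export
runPipeline <- function(features, outcome, seed = 1L,
                        split = NULL,
                        fractions = c(0.55, 0.15, 0.30),
                        alpha = 0.05, max_features = 10L,
                        network = NULL, grid = NULL,
                        eval_times = c(1, 2, 3, 6),
                        outlier_filter = TRUE,
                        stratify_months = 3.3, stratify_cut = 0.5) {
  stopifnot(nrow(features) == nrow(outcome))
  n <- nrow(features)
  if (is.null(split)) split <- splitCohort(n, fractions, seed = seed + 11L)

  filter_report <- NULL
  if (outlier_filter) {
    fl <- outlierFilter(features, reference_rows = split$train)
    # never drop factor columns; outlierFilter only touches numeric ones
    features <- fl$filtered
    filter_report <- fl$report
  }

  screening <- screenFeatures(features[split$train, , drop = FALSE],
                              outcome[split$train, , drop = FALSE],
                              alpha = alpha)
  passed <- screening$feature[screening$pass]
  pvals <- setNames(screening$p, screening$feature)
  screening_empty <- length(passed) == 0
  if (screening_empty) {
    # allowed but flagged: fall back to the least implausible features so
    # a model can still be fitted
    warning("screening passed no feature at alpha = ", alpha,
            "; falling back to the three smallest p-values")
    ok <- screening$feature[is.finite(screening$p)]
    passed <- ok[order(pvals[ok])][seq_len(min(3, length(ok)))]
  }

  sfs <- sequentialForwardSelection(
    features, outcome, split, candidates = passed,
    screening_p = pvals, max_features = max_features)
  selected <- if (sfs$empty) passed[order(pvals[passed])][1] else
    sfs$selected

  X <- .design_matrix(features[, selected, drop = FALSE])
  if (is.null(network))
    network <- networkSpec(input_dim = ncol(X), seed = seed + 31L)
  else {
    network$input_dim <- ncol(X)
    network$seed <- seed + 31L
  }
  if (!is.null(grid)) {
    grid <- lapply(seq_along(grid), function(i) {
      g <- grid[[i]]
      g$input_dim <- ncol(X)
      g$seed <- seed + 31L + i
      g
    })
    gs <- gridSearch(grid, X[split$train, , drop = FALSE],
                     outcome[split$train, , drop = FALSE],
                     X[split$validation, , drop = FALSE],
                     outcome[split$validation, , drop = FALSE])
    fit <- gs$best_fit
    grid_log <- gs$log
  } else {
    fit <- trainSurvivalNetwork(network,
                                X[split$train, , drop = FALSE],
                                outcome[split$train, , drop = FALSE],
                                X[split$validation, , drop = FALSE],
                                outcome[split$validation, , drop = FALSE])
    grid_log <- NULL
  }

  te <- split$test
  test_scores <- predictRisk(fit, X[te, , drop = FALSE])
  test_outcome <- outcome[te, , drop = FALSE]
  ci <- concordanceIndex(test_outcome, test_scores)
  roc <- lapply(eval_times, function(tt)
    tryCatch(timeDependentRoc(test_outcome, test_scores, tt),
             error = function(e) NULL))
  names(roc) <- paste0("t", eval_times)
  curves <- predictSurvival(fit, scores = test_scores)
  strata <- stratifyRisk(curves, stratify_months, stratify_cut)
  lr <- if (nlevels(droplevels(strata)) == 2)
    tryCatch(logRank(test_outcome[strata == "low", , drop = FALSE],
                     test_outcome[strata == "high", , drop = FALSE]),
             error = function(e) NULL)
  else NULL

  list(split = split,
       filter_report = filter_report,
       screening = screening,
       screening_empty = screening_empty,
       selection = list(selected = selected, trace = sfs$trace),
       fit = fit,
       grid_log = grid_log,
       test = list(scores = test_scores, outcome = test_outcome,
                   cindex = ci$cindex, roc = roc, curves = curves,
                   stratification = strata, log_rank = lr),
       config = list(seed = seed, fractions = fractions, alpha = alpha,
                     max_features = max_features,
                     eval_times = eval_times,
                     stratify_months = stratify_months,
                     stratify_cut = stratify_cut))
}

# expand factors to 0/1 indicator columns (full dummy coding minus
# reference level), keep numerics as-is
.design_matrix <- function(df) {
  cols <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      x <- factor(x)
      for (lv in levels(x)[-1])
        cols[[paste0(nm, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Compare nested feature-set models on one cohort
#'
#' Fits the pipeline for several feature sets (e.g. clinical only;
#' clinical + intratumoral; clinical + intratumoral + vasculature) on
#' the identical split, and compares consecutive models' test AUCs by
#' bootstrap paired t-tests.
#'
#' @param feature_sets named list of feature data.frames (same rows).
#' @param outcome data.frame `time`, `event`.
#' @param seed master seed (shared split).
#' @param n_boot bootstrap replicates for the comparison (default 100).
#' @param ... passed to [runPipeline()].
#' @return a list: `runs` (one pipeline result per set), `comparisons`
#'   (bootstrap AUC comparison of each set against the last).
#' @export
compareFeatureSets <- function(feature_sets, outcome, seed = 1L,
                               n_boot = 100L, ...) {
  n <- nrow(outcome)
  split <- splitCohort(n, seed = seed + 11L)
  runs <- lapply(feature_sets, function(f)
    runPipeline(f, outcome, seed = seed, split = split, ...))
  k <- length(runs)
  comparisons <- NULL
  if (k >= 2) {
    ref <- runs[[k]]
    comparisons <- lapply(seq_len(k - 1), function(i)
      bootstrapCompare(ref$test$outcome,
                       ref$test$scores, runs[[i]]$test$scores,
                       n_boot = n_boot, seed = seed + 71L))
    names(comparisons) <- paste(names(feature_sets)[seq_len(k - 1)],
                                "vs", names(feature_sets)[k])
  }
  list(runs = runs, comparisons = comparisons)
}
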