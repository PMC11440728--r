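#' Random train/validation/test cohort split
#'
#' Simple random partition into training, validation and testing sets
#' (default 55/15/30), with largest-remainder rounding of the subset
#' sizes so they are disjoint and exhaustive.
#'
#' @param n number of subjects (>= 3).
#' @param fractions numeric(3) summing to 1.
#' @param seed integer seed.
#' @return a list of integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(splitCohort(206, seed = 1))   # 113, 31, 62
#' @export
splitCohort <- function(n, fractions = c(0.55, 0.15, 0.30), seed = 1L) {
  if (n < 3) stop("n must be >= 3")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  .with_seed(seed, {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(sizes[1])]),
         validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
         test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  })
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits a single-covariate Cox model with Breslow tie handling and
#' reports the coefficient, hazard ratio, standard error and Wald
#' p-value. Monotone-likelihood nonconvergence is flagged with an
#' infinite hazard-ratio sentinel.
#'
#' @param x numeric covariate vector (nonconstant).
#' @param outcome data.frame with columns `time` and `event` (>= 2
#'   events).
#' @return a list `beta`, `hr`, `se`, `p`, `converged`.
#' @export
univariateCox <- function(x, outcome) {
  if (sd(x) == 0) stop("constant feature")
  if (sum(outcome$event) < 2) stop("need at least 2 events")
  df <- data.frame(time = outcome$time, event = outcome$event, x = x)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  diverged <- !is.finite(beta) || abs(beta) > 15
  z <- beta / se
  list(beta = beta,
       hr = if (diverged) Inf * sign(beta) else exp(beta),
       se = se,
       p = 2 * pnorm(-abs(z)),
       converged = !diverged)
}

#' Pearson chi-squared test of a categorical feature against event status
#'
#' Pearson chi-square without continuity correction on the
#' level-by-event-status contingency table; levels with zero margin are
#' dropped with a warning.
#'
#' @param x factor (or coercible) categorical feature.
#' @param event 0/1 event indicators.
#' @return a list `statistic`, `df`, `p`.
#' @export
chiSquared <- function(x, event) {
  x <- factor(x)
  tab <- table(x, factor(event, levels = c(0, 1)))
  zero_rows <- rowSums(tab) == 0
  if (any(zero_rows)) {
    warning("dropping zero-margin levels: ",
            paste(rownames(tab)[zero_rows], collapse = ", "))
    tab <- tab[!zero_rows, , drop = FALSE]
  }
  zero_cols <- colSums(tab) == 0
  tab <- tab[, !zero_cols, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, df = 0, p = 1))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Univariate screening of a feature table
#'
#' First selection step: univariate Cox regression for continuous
#' (radiomic) columns and the chi-squared test against the progression
#' indicator for categorical (clinical) columns; features with p below
#' `alpha` pass. No multiplicity adjustment is applied.
#'
#' @param features data.frame of features (numeric and/or factor
#'   columns).
#' @param outcome data.frame with `time` and `event`, row-aligned.
#' @param alpha significance gate (default 0.05).
#' @return a data.frame with one row per feature: `feature`, `test`
#'   (cox/chisq), `statistic`, `hr` (NA for chisq), `p`, `pass`.
#' @export
screenFeatures <- function(features, outcome, alpha = 0.05) {
  stopifnot(nrow(features) == nrow(outcome))
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (is.numeric(x)) {
      if (sd(x) == 0)
        return(data.frame(feature = nm, test = "cox", statistic = NA_real_,
                          hr = NA_real_, p = NA_real_, pass = FALSE))
      r <- univariateCox(x, outcome)
      data.frame(feature = nm, test = "cox",
                 statistic = r$beta / r$se, hr = r$hr, p = r$p,
                 pass = is.finite(r$p) && r$p < alpha)
    } else {
      r <- chiSquared(x, outcome$event)
      data.frame(feature = nm, test = "chisq", statistic = r$statistic,
                 hr = NA_real_, p = r$p, pass = r$p < alpha)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sequential forward feature selection on validation concordance
#'
#' Second selection step: greedy forward selection over the screened
#' candidates. At each step the candidate whose addition maximizes the
#' validation C-index of a linear Cox model fitted on the training split
#' is added; ties are broken by the lower screening p-value. Selection
#' stops after `patience` consecutive non-improving steps or at
#' `max_features`.
#'
#' @param features data.frame of candidate features (factors are
#'   expanded to indicator columns internally via the Cox model).
#' @param outcome data.frame with `time`, `event`.
#' @param split list with `train` and `validation` indices (see
#'   [splitCohort()]).
#' @param candidates character vector of candidate column names.
#' @param screening_p optional named numeric vector of screening
#'   p-values used for tie-breaks.
#' @param max_features cap on the number of selected features (default
#'   15).
#' @param patience non-improving steps tolerated before stopping
#'   (default 1).
#' @return a list: `selected` (character), `trace` (data.frame of
#'   `feature`, `criterion` after each accepted step), `empty` flag.
#' @export
sequentialForwardSelection <- function(features, outcome, split,
                                       candidates,
                                       screening_p = NULL,
                                       max_features = 15L,
                                       patience = 1L) {
  if (length(candidates) == 0) stop("candidates must be nonempty")
  tr <- split$train; va <- split$validation
  if (sum(outcome$event[va]) < 1)
    stop("criterion undefined: no evaluable validation pairs")
  selected <- character(0)
  best_crit <- -Inf
  trace <- data.frame(feature = character(0), criterion = numeric(0))
  stalls <- 0L
  remaining <- candidates
  while (length(selected) < max_features && length(remaining) > 0) {
    crits <- vapply(remaining, function(cand) {
      .validation_cindex(features, outcome, tr, va, c(selected, cand))
    }, numeric(1))
    ok <- is.finite(crits)
    if (!any(ok)) break
    top <- max(crits[ok])
    tied <- remaining[ok & abs(crits - top) < 1e-12]
    pick <- if (length(tied) > 1 && !is.null(screening_p))
      tied[order(screening_p[tied])][1] else tied[1]
    if (top > best_crit + 1e-12) {
      selected <- c(selected, pick)
      remaining <- setdiff(remaining, pick)
      best_crit <- top
      stalls <- 0L
      trace <- rbind(trace,
                     data.frame(feature = pick, criterion = top))
    } else {
      stalls <- stalls + 1L
      if (stalls >= patience) break
      remaining <- setdiff(remaining, pick)
    }
  }
  list(selected = selected, trace = trace,
       empty = length(selected) == 0)
}

.validation_cindex <- function(features, outcome, tr, va, cols) {
  df <- features[, cols, drop = FALSE]
  df$.time <- outcome$time
  df$.event <- outcome$event
  fit <- tryCatch(suppressWarnings(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = df[tr, , drop = FALSE], ties = "breslow")),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  lp <- tryCatch(
    stats::predict(fit, newdata = df[va, , drop = FALSE], type = "lp"),
    error = function(e) NULL)
  if (is.null(lp) || any(!is.finite(lp))) return(NA_real_)
  r <- tryCatch(concordanceIndex(outcome[va, , drop = FALSE], lp),
                error = function(e) NULL)
  if (is.null(r)) NA_real_ else r$cindex
}
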