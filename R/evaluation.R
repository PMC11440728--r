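#' Concordance index
#'
#' C-index as the ratio of concordant pairs to evaluable pairs: a pair is
#' evaluable iff the observed times differ and the shorter time carries
#' an event; it is concordant when that subject has the higher predicted
#' risk, and tied risks contribute 0.5.
#'
#' @param outcome data.frame with `time`, `event`.
#' @param scores numeric risk scores (higher = shorter expected
#'   survival).
#' @return a list: `cindex`, `concordant` (count, including 0.5 tie
#'   credit), `evaluable` (count).
#' @examples
#' concordanceIndex(data.frame(time = 1:3, event = c(1, 1, 1)), c(3, 2, 1))
#' @export
concordanceIndex <- function(outcome, scores) {
  t <- outcome$time; e <- outcome$event; s <- scores
  n <- length(t)
  if (n < 2) stop("no evaluable pairs")
  Tdiff <- outer(t, t, `<`)              # [i, j]: t_i < t_j
  evaluable <- Tdiff & (e == 1)          # row i must carry an event
  n_eval <- sum(evaluable)
  if (n_eval == 0) stop("no evaluable pairs")
  Sgt <- outer(s, s, `>`)
  Seq <- outer(s, s, `==`)
  conc <- sum(Sgt & evaluable) + 0.5 * sum(Seq & evaluable)
  list(cindex = conc / n_eval, concordant = conc, evaluable = n_eval)
}

# Kaplan-Meier estimate of the censoring distribution G(t) and its left
# limit G(t-) evaluator
.censoring_km <- function(outcome) {
  fit <- survival::survfit(
    survival::Surv(outcome$time, 1 - outcome$event) ~ 1)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(at = function(t) pmax(step(t), 1e-12),
       at_left = function(t) pmax(step(t - 1e-9), 1e-12))
}

#' Time-dependent ROC curve and AUC
#'
#' Cumulative-cases / dynamic-controls ROC at horizon `t`: cases are
#' subjects with an event by `t`, controls those followed beyond `t`.
#' Censoring is handled by inverse-probability-of-censoring weights from
#' the Kaplan-Meier estimator of the censoring distribution (cases
#' weighted by 1/G(T-), controls by 1/G(t)); `ipcw = FALSE` gives the
#' unweighted variant. The AUC is the weighted Mann-Whitney statistic
#' (trapezoid integral of the ROC), and sensitivity/specificity are
#' reported at the Youden-optimal threshold.
#'
#' @param outcome data.frame `time`, `event`.
#' @param scores numeric risk scores.
#' @param t evaluation horizon (months).
#' @param ipcw use censoring weights (default TRUE).
#' @return a list: `auc`, `sensitivity`, `specificity`, `threshold`,
#'   `curve` (data.frame fpr/tpr), `n_cases`, `n_controls`.
#' @export
timeDependentRoc <- function(outcome, scores, t, ipcw = TRUE) {
  case <- outcome$time <= t & outcome$event == 1
  ctrl <- outcome$time > t
  if (!any(case)) stop("no cases (events by t = ", t, ")")
  if (!any(ctrl)) stop("no controls (followed beyond t = ", t, ")")
  if (ipcw) {
    G <- .censoring_km(outcome)
    w_case <- 1 / G$at_left(outcome$time[case])
    w_ctrl <- rep(1 / G$at(t), sum(ctrl))
  } else {
    w_case <- rep(1, sum(case))
    w_ctrl <- rep(1, sum(ctrl))
  }
  sc <- scores[case]; st <- scores[ctrl]
  gt <- outer(sc, st, `>`)
  eq <- outer(sc, st, `==`)
  Wmat <- outer(w_case, w_ctrl)
  auc <- sum(Wmat * (gt + 0.5 * eq)) / sum(Wmat)
  thr <- sort(unique(c(scores, -Inf)))
  sens <- vapply(thr, function(cu) sum(w_case[sc > cu]) / sum(w_case),
                 numeric(1))
  spec <- vapply(thr, function(cu) sum(w_ctrl[st <= cu]) / sum(w_ctrl),
                 numeric(1))
  youden <- which.max(sens + spec - 1)
  list(auc = auc,
       sensitivity = sens[youden], specificity = spec[youden],
       threshold = thr[youden],
       curve = data.frame(fpr = 1 - spec, tpr = sens),
       n_cases = sum(case), n_controls = sum(ctrl))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator as a right-continuous step function starting
#' at S(0) = 1.
#'
#' @param outcome data.frame `time`, `event`.
#' @return a [SurvivalCurve-class].
#' @export
kmEstimate <- function(outcome) {
  if (nrow(outcome) < 1) stop("empty outcome")
  if (sum(outcome$event) == 0)
    return(new("SurvivalCurve", time = c(0, max(outcome$time)),
               surv = c(1, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = outcome)
  keep <- fit$n.event > 0
  new("SurvivalCurve", time = c(0, fit$time[keep]),
      surv = c(1, fit$surv[keep]))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (df 1) comparing the survival curves of
#' two groups.
#'
#' @param outcome_a,outcome_b data.frames `time`, `event`.
#' @return a list `statistic`, `p`.
#' @export
logRank <- function(outcome_a, outcome_b) {
  if (nrow(outcome_a) == 0 || nrow(outcome_b) == 0)
    stop("both groups must be nonempty")
  df <- rbind(data.frame(time = outcome_a$time, event = outcome_a$event,
                         g = 0),
              data.frame(time = outcome_b$time, event = outcome_b$event,
                         g = 1))
  if (sum(df$event) == 0) stop("no events in either group")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  stat <- unname(sd_$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bootstrap comparison of two risk models' time-dependent AUCs
#'
#' Resamples subjects with replacement `n_boot` times, recomputes both
#' models' AUC(t) per replicate, and applies a paired t-test across
#' replicates at each horizon. Degenerate replicates (no cases or no
#' controls at some horizon) are redrawn and counted.
#'
#' @param outcome data.frame `time`, `event` (typically the test split).
#' @param scores_a,scores_b aligned risk-score vectors.
#' @param times evaluation horizons (default `c(1, 2, 3, 6)`).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param ipcw passed to [timeDependentRoc()].
#' @return a data.frame per horizon: `time`, `auc_a`, `auc_b` (means
#'   across replicates), `p` (paired t-test), `redrawn` count.
#' @export
bootstrapCompare <- function(outcome, scores_a, scores_b,
                             times = c(1, 2, 3, 6), n_boot = 100L,
                             seed = 1L, ipcw = TRUE) {
  n <- nrow(outcome)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  .with_seed(seed, {
    A <- matrix(NA_real_, n_boot, length(times))
    B <- matrix(NA_real_, n_boot, length(times))
    redrawn <- 0L
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oc <- outcome[idx, , drop = FALSE]
        ok <- all(vapply(times, function(tt)
          any(oc$time <= tt & oc$event == 1) && any(oc$time > tt),
          logical(1)))
        if (ok) break
        redrawn <- redrawn + 1L
        if (redrawn > 50L * n_boot) stop("too many degenerate replicates")
      }
      for (k in seq_along(times)) {
        A[r, k] <- timeDependentRoc(oc, scores_a[idx], times[k],
                                    ipcw = ipcw)$auc
        B[r, k] <- timeDependentRoc(oc, scores_b[idx], times[k],
                                    ipcw = ipcw)$auc
      }
    }
    p <- vapply(seq_along(times), function(k) {
      d <- A[, k] - B[, k]
      if (sd(d) == 0) return(1)
      t.test(A[, k], B[, k], paired = TRUE)$p.value
    }, numeric(1))
    data.frame(time = times, auc_a = colMeans(A), auc_b = colMeans(B),
               p = p, redrawn = redrawn)
  })
}

#' Monte-Carlo Shapley feature attribution
#'
#' Permutation-sampling estimate of the Shapley values of a risk-score
#' function against a background reference (by default the training
#' mean): for each sampled feature ordering, features are switched from
#' the background to the subject's values one at a time and the marginal
#' score changes are accumulated. Within every permutation the
#' contributions sum exactly to score(x) - score(background), so the
#' efficiency property holds for the average as well.
#'
#' @param model a [SurvivalNetworkFit-class], or a function mapping a
#'   numeric matrix to scores.
#' @param features numeric matrix/data.frame of subjects to explain.
#' @param background numeric vector (reference input); defaults to the
#'   column means of `features`.
#' @param n_permutations Monte-Carlo permutations per subject
#'   (default 64, >= 1).
#' @param seed integer seed.
#' @return a matrix (subjects x features) of attributions, with the
#'   background score as attribute `baseline`.
#' @export
shapleyAttribution <- function(model, features, background = NULL,
                               n_permutations = 64L, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as.matrix(features)
  f <- if (is.function(model)) model else function(m) predictRisk(model, m)
  if (is.null(background)) background <- colMeans(X)
  p <- ncol(X)
  .with_seed(seed, {
    out <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
    base_score <- f(matrix(background, 1, p,
                           dimnames = list(NULL, colnames(X))))
    for (i in seq_len(nrow(X))) {
      phi <- numeric(p)
      for (r in seq_len(n_permutations)) {
        ord <- sample.int(p)
        # stack of p+1 inputs: background progressively replaced by x_i
        Z <- matrix(background, p + 1L, p, byrow = TRUE,
                    dimnames = list(NULL, colnames(X)))
        for (k in seq_len(p))
          Z[(k + 1L):(p + 1L), ord[k]] <- X[i, ord[k]]
        sc <- f(Z)
        phi[ord] <- phi[ord] + diff(sc)
      }
      out[i, ] <- phi / n_permutations
    }
    attr(out, "baseline") <- as.numeric(base_score)
    out
  })
}
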