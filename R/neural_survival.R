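#' Network specification for the neural Cox model
#'
#' Hyperparameters of the multilayer-perceptron risk model. The defaults
#' (two hidden layers of 32 SELU units, dropout 0.2, weight penalty
#' 1e-4, full-batch Adam with early stopping on validation concordance)
#' are deliberately small enough for exhaustive grid search.
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of hidden-layer widths (empty = linear
#'   model).
#' @param activation one of "selu", "relu", "tanh", "identity".
#' @param dropout dropout rate in [0, 1).
#' @param weight_penalty L2 penalty on weights (>= 0).
#' @param learning_rate Adam step size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param restore_best keep the weights with the best validation C-index
#'   (default TRUE); FALSE keeps the final-epoch weights, which is the
#'   right choice when checking convergence to the linear Cox optimum.
#' @param seed integer seed controlling initialization and dropout.
#' @return a list of class `NetworkSpec`.
#' @export
networkSpec <- function(input_dim, hidden = c(32L, 32L),
                        activation = "selu", dropout = 0.2,
                        weight_penalty = 1e-4, learning_rate = 0.01,
                        max_epochs = 500L, patience = 20L,
                        restore_best = TRUE, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, weight_penalty >= 0,
            learning_rate > 0,
            activation %in% c("selu", "relu", "tanh", "identity"))
  spec <- list(input_dim = as.integer(input_dim),
               hidden = as.integer(hidden), activation = activation,
               dropout = dropout, weight_penalty = weight_penalty,
               learning_rate = learning_rate,
               max_epochs = as.integer(max_epochs),
               patience = as.integer(patience),
               restore_best = isTRUE(restore_best),
               seed = as.integer(seed))
  class(spec) <- "NetworkSpec"
  spec
}

#' Breslow Cox partial-likelihood loss
#'
#' Negative Breslow partial log-likelihood of a vector of risk scores,
#' averaged over events. Adding a constant to all scores leaves the loss
#' unchanged; a single subject with an event has loss 0.
#'
#' @param scores numeric risk scores (higher = worse prognosis).
#' @param outcome data.frame with `time` and `event` (>= 1 event).
#' @return scalar loss.
#' @examples
#' coxPartialLoss(c(0, 0), data.frame(time = c(1, 2), event = c(1, 1)))
#' @export
coxPartialLoss <- function(scores, outcome) {
  .cox_loss_grad(scores, outcome$time, outcome$event)$loss
}

# loss and gradient of the event-averaged negative Breslow partial
# log-likelihood
.cox_loss_grad <- function(eta, time, event) {
  D <- sum(event)
  if (D < 1) stop("no events: partial likelihood undefined")
  n <- length(eta)
  ord <- order(time)
  eta_o <- eta[ord]; ev_o <- event[ord]; t_o <- time[ord]
  m <- max(eta_o)
  w <- exp(eta_o - m)
  # risk-set sums: subjects with time >= t_j (ties share risk sets)
  rev_cs <- rev(cumsum(rev(w)))
  grp_new <- c(TRUE, t_o[-1] != t_o[-n])
  grp_id <- cumsum(grp_new)
  # risk-set sum per group = rev_cs at the first index of the group
  first_idx <- which(grp_new)
  S_grp <- rev_cs[first_idx]
  d_grp <- vapply(split(ev_o, grp_id), sum, numeric(1))
  has_ev <- d_grp > 0
  loss_total <- -sum(eta_o[ev_o == 1]) +
    sum(d_grp[has_ev] * (log(S_grp[has_ev]) + m))
  # gradient: -1{event} + w_k * cumsum over groups with t_j <= t_k of d_j/S_j
  ratio_grp <- ifelse(has_ev, d_grp / S_grp, 0)
  cum_ratio_grp <- cumsum(ratio_grp)
  cum_ratio <- cum_ratio_grp[grp_id]
  grad_o <- -ev_o + w * cum_ratio
  grad <- numeric(n)
  grad[ord] <- grad_o
  list(loss = loss_total / D, grad = grad / D)
}

.act <- function(z, kind) {
  switch(kind,
    selu = {
      l <- 1.0507009873554805; a <- 1.6732632423543772
      ifelse(z > 0, l * z, l * a * (exp(pmin(z, 0)) - 1))
    },
    relu = pmax(z, 0),
    tanh = tanh(z),
    identity = z)
}

.act_grad <- function(z, kind) {
  switch(kind,
    selu = {
      l <- 1.0507009873554805; a <- 1.6732632423543772
      ifelse(z > 0, l, l * a * exp(pmin(z, 0)))
    },
    relu = (z > 0) * 1,
    tanh = 1 - tanh(z)^2,
    identity = z * 0 + 1)
}

.init_weights <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(rnorm(fan_in * dims[l + 1], sd = sqrt(1 / fan_in)),
                     fan_in, dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

# forward pass; returns activations for backprop; drop_masks NULL at
# evaluation time
.forward <- function(X, wts, spec, drop_masks = NULL) {
  L <- length(wts$W)
  A <- list(X)
  Z <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% wts$W[[l]], 2, wts$b[[l]], `+`)
    if (l < L) {
      H <- .act(Z[[l]], spec$activation)
      if (!is.null(drop_masks) && spec$dropout > 0)
        H <- H * drop_masks[[l]] / (1 - spec$dropout)
      A[[l + 1]] <- H
    } else {
      A[[l + 1]] <- Z[[l]]
    }
  }
  list(A = A, Z = Z, out = as.numeric(A[[L + 1]]))
}

.backward <- function(fw, wts, spec, dout, drop_masks) {
  L <- length(wts$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(dout, ncol = 1)
  for (l in L:1) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta + 2 * spec$weight_penalty * wts$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(wts$W[[l]])
      if (!is.null(drop_masks) && spec$dropout > 0)
        delta <- delta * drop_masks[[l - 1]] / (1 - spec$dropout)
      delta <- delta * .act_grad(fw$Z[[l - 1]], spec$activation)
    }
  }
  list(W = gW, b = gb)
}

#' Train the neural Cox survival model
#'
#' Full-batch Adam training of the MLP risk score under the Breslow
#' partial-likelihood loss with L2 weight penalty, dropout, and early
#' stopping on the validation C-index; the weights achieving the best
#' validation concordance are kept. Inputs are standardized column-wise
#' using training-split statistics only. Training is deterministic given
#' the spec seed.
#'
#' @param spec a [networkSpec()].
#' @param x_train,x_val numeric matrices (subjects x features).
#' @param outcome_train,outcome_val data.frames with `time`, `event`.
#' @return a [SurvivalNetworkFit-class] including the Breslow baseline
#'   cumulative hazard estimated on the training set.
#' @export
trainSurvivalNetwork <- function(spec, x_train, outcome_train,
                                 x_val, outcome_val) {
  stopifnot(inherits(spec, "NetworkSpec"))
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (ncol(x_train) != spec$input_dim)
    stop("input_dim does not match x_train")
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xtr <- sweep(sweep(x_train, 2, ctr), 2, scl, `/`)
  Xva <- sweep(sweep(x_val, 2, ctr), 2, scl, `/`)
  t0 <- proc.time()[["elapsed"]]
  fit_env <- .with_seed(spec$seed, {
    wts <- .init_weights(spec)
    mW <- lapply(wts$W, function(w) w * 0); vW <- mW
    mb <- lapply(wts$b, function(x) x * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best_ci <- -Inf; best_wts <- wts; stall <- 0L
    n_hidden <- length(spec$hidden)
    losses <- numeric(0)
    epochs_run <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      drop_masks <- NULL
      if (spec$dropout > 0 && n_hidden > 0)
        drop_masks <- lapply(seq_len(n_hidden), function(l)
          matrix(rbinom(nrow(Xtr) * spec$hidden[l], 1, 1 - spec$dropout),
                 nrow(Xtr), spec$hidden[l]))
      fw <- .forward(Xtr, wts, spec, drop_masks)
      lg <- .cox_loss_grad(fw$out, outcome_train$time, outcome_train$event)
      if (!is.finite(lg$loss))
        stop("divergence: loss is not finite (epoch ", epoch, ")")
      losses <- c(losses, lg$loss)
      gr <- .backward(fw, wts, spec, lg$grad, drop_masks)
      for (l in seq_along(wts$W)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$W[[l]]^2
        mhat <- mW[[l]] / (1 - b1^epoch)
        vhat <- vW[[l]] / (1 - b2^epoch)
        wts$W[[l]] <- wts$W[[l]] -
          spec$learning_rate * mhat / (sqrt(vhat) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$b[[l]]^2
        wts$b[[l]] <- wts$b[[l]] - spec$learning_rate *
          (mb[[l]] / (1 - b1^epoch)) /
          (sqrt(vb[[l]] / (1 - b2^epoch)) + eps)
      }
      epochs_run <- epoch
      val_scores <- .forward(Xva, wts, spec)$out
      ci <- tryCatch(
        concordanceIndex(outcome_val, val_scores)$cindex,
        error = function(e) NA_real_)
      if (is.finite(ci) && ci > best_ci + 1e-6) {
        best_ci <- ci; best_wts <- wts; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$patience) break
      }
    }
    list(wts = if (isTRUE(spec$restore_best)) best_wts else wts,
         best_ci = best_ci, losses = losses,
         epochs = epochs_run)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  train_scores <- .forward(Xtr, fit_env$wts, spec)$out
  bl <- breslowBaseline(train_scores, outcome_train)
  new("SurvivalNetworkFit",
      spec = unclass(spec),
      weights = fit_env$wts,
      baseline = bl,
      standardization = list(center = ctr, scale = scl),
      log = list(epochs = fit_env$epochs,
                 final_loss = tail(fit_env$losses, 1),
                 losses = fit_env$losses,
                 validation_cindex = fit_env$best_ci,
                 training_seconds = elapsed))
}

#' Predict risk scores from a fitted network
#'
#' @param fit a [SurvivalNetworkFit-class].
#' @param x numeric matrix or data.frame of features (same columns as
#'   training).
#' @return numeric vector of risk scores (log relative hazards).
#' @export
predictRisk <- function(fit, x) {
  stopifnot(is(fit, "SurvivalNetworkFit"))
  X <- as.matrix(x)
  X <- sweep(sweep(X, 2, fit@standardization$center), 2,
             fit@standardization$scale, `/`)
  spec <- fit@spec
  class(spec) <- "NetworkSpec"
  .forward(X, fit@weights, spec)$out
}

#' Breslow baseline cumulative hazard
#'
#' H0(t) = sum over event times up to t of d_j / sum of exp(score) over
#' the risk set; a right-continuous nondecreasing step function with
#' H0(0) = 0.
#'
#' @param scores training risk scores.
#' @param outcome data.frame `time`, `event` (>= 1 event).
#' @return a list `time` (unique event times), `hazard` (cumulative).
#' @export
breslowBaseline <- function(scores, outcome) {
  if (sum(outcome$event) < 1) stop("no events: baseline undefined")
  ord <- order(outcome$time)
  t_o <- outcome$time[ord]; ev_o <- outcome$event[ord]
  w <- exp(scores[ord])
  n <- length(w)
  rev_cs <- rev(cumsum(rev(w)))
  grp_new <- c(TRUE, t_o[-1] != t_o[-n])
  grp_id <- cumsum(grp_new)
  first_idx <- which(grp_new)
  S_grp <- rev_cs[first_idx]
  d_grp <- vapply(split(ev_o, grp_id), sum, numeric(1))
  t_grp <- t_o[first_idx]
  has_ev <- d_grp > 0
  list(time = unname(t_grp[has_ev]),
       hazard = unname(cumsum(d_grp[has_ev] / S_grp[has_ev])))
}

#' Personalized survival curves
#'
#' S(t | x) = exp(-H0(t) * exp(score(x))) from the fitted network's
#' Breslow baseline; each curve starts at S(0) = 1 and is nonincreasing.
#'
#' @param fit a [SurvivalNetworkFit-class].
#' @param x feature matrix/data.frame, or NULL to use precomputed
#'   `scores`.
#' @param scores optional risk scores (overrides `x`).
#' @return a list of [SurvivalCurve-class], one per subject.
#' @export
predictSurvival <- function(fit, x = NULL, scores = NULL) {
  stopifnot(is(fit, "SurvivalNetworkFit"))
  if (length(fit@baseline) == 0) stop("model not fitted")
  if (is.null(scores)) {
    if (is.null(x)) stop("provide x or scores")
    scores <- predictRisk(fit, x)
  }
  H <- c(0, fit@baseline$hazard)
  tt <- c(0, fit@baseline$time)
  lapply(scores, function(s)
    new("SurvivalCurve", time = tt, surv = exp(-H * exp(s))))
}

#' Risk stratification from predicted survival curves
#'
#' Classifies subjects as low risk when the predicted
#' progression-free-survival probability at the threshold time exceeds
#' the probability cut: low risk iff S(3.3) > 0.5 with the defaults
#' (median progression time 3.3 months, 50% cut); the boundary S = cut
#' is high risk.
#'
#' @param curves list of [SurvivalCurve-class].
#' @param threshold_months evaluation time (default 3.3).
#' @param cut probability cut (default 0.5).
#' @return factor with levels `low`, `high`.
#' @export
stratifyRisk <- function(curves, threshold_months = 3.3, cut = 0.5) {
  s <- vapply(curves, survivalAt, numeric(1), times = threshold_months)
  factor(ifelse(s > cut, "low", "high"), levels = c("low", "high"))
}

#' Exhaustive hyperparameter grid search
#'
#' Trains every specification in the grid and selects the one with the
#' highest validation C-index; exact ties are broken by the shorter
#' recorded training time, then by grid order.
#'
#' @param grid list of [networkSpec()] objects.
#' @param x_train,outcome_train,x_val,outcome_val as in
#'   [trainSurvivalNetwork()].
#' @return a list: `best_fit`, `best_index`, `log` (data.frame with
#'   C-index and training time per grid point).
#' @export
gridSearch <- function(grid, x_train, outcome_train, x_val, outcome_val) {
  if (length(grid) == 0) stop("grid must be nonempty")
  fits <- vector("list", length(grid))
  ci <- numeric(length(grid)); tt <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- tryCatch(
      trainSurvivalNetwork(grid[[i]], x_train, outcome_train,
                           x_val, outcome_val),
      error = function(e) NULL)
    ci[i] <- if (is.null(fits[[i]])) -Inf
             else fits[[i]]@log$validation_cindex
    tt[i] <- if (is.null(fits[[i]])) Inf
             else fits[[i]]@log$training_seconds
  }
  if (all(!is.finite(ci))) stop("all grid configurations failed")
  best <- which(ci == max(ci))
  if (length(best) > 1) best <- best[order(tt[best])]
  best <- best[1]
  list(best_fit = fits[[best]], best_index = best,
       log = data.frame(index = seq_along(grid), cindex = ci,
                        training_seconds = tt))
}
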