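test_that("the Cox loss matches hand-computed values and its invariances", {
  o2 <- data.frame(time = c(1, 2), event = c(1, 1))
  expect_equal(coxPartialLoss(c(0, 0), o2), log(2) / 2)
  expect_equal(coxPartialLoss(0, data.frame(time = 3, event = 1)), 0)
  o3 <- data.frame(time = c(2, 1, 3), event = c(1, 1, 0))
  s <- c(0.3, -1, 2)
  expect_equal(coxPartialLoss(s + 7.5, o3), coxPartialLoss(s, o3),
               tolerance = 1e-10)
  expect_error(coxPartialLoss(c(1, 2),
                              data.frame(time = 1:2, event = c(0, 0))),
               "no events")
})

test_that("the loss gradient matches numerical differentiation", {
  set.seed(1)
  n <- 15
  tm <- sample(1:6, n, TRUE) + runif(n) * 0.01
  ev <- pmax(rbinom(n, 1, 0.6), c(1, rep(0, n - 1)))
  eta <- rnorm(n)
  lg <- periSurv:::.cox_loss_grad(eta, tm, ev)
  num <- vapply(seq_len(n), function(i) {
    h <- 1e-6
    e2 <- eta; e2[i] <- e2[i] + h
    (periSurv:::.cox_loss_grad(e2, tm, ev)$loss - lg$loss) / h
  }, numeric(1))
  expect_equal(lg$grad, num, tolerance = 1e-5)
})

test_that("the Breslow baseline matches hand computation and scales", {
  bl <- breslowBaseline(c(0, 0, 0),
                        data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  expect_equal(bl$time, c(1, 2))
  expect_equal(bl$hazard, c(1 / 3, 1 / 3 + 1 / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # nondecreasing for arbitrary input
  set.seed(2)
  o <- random_outcome(40, 3)
  blr <- breslowBaseline(rnorm(40), o)
  expect_true(all(diff(blr$hazard) >= 0))
  # adding log(2) to all scores halves every increment
  bl2 <- breslowBaseline(rep(log(2), 3),
                         data.frame(time = c(1, 2, 3),
                                    event = c(1, 1, 0)))
  expect_equal(bl2$hazard, bl$hazard / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("training is deterministic and reaches a sensible validation C-index", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 4), n)
  oc <- generateSurvival(as.numeric(X %*% c(1, 0.7, -0.5, 0)), seed = 4)
  sp <- splitCohort(n, seed = 5)
  spec <- networkSpec(4, seed = 7)
  f1 <- trainSurvivalNetwork(spec, X[sp$train, ], oc[sp$train, ],
                             X[sp$validation, ], oc[sp$validation, ])
  f2 <- trainSurvivalNetwork(spec, X[sp$train, ], oc[sp$train, ],
                             X[sp$validation, ], oc[sp$validation, ])
  expect_identical(f1@weights, f2@weights)
  expect_gt(f1@log$validation_cindex, 0.6)
})

test_that("a depth-0 identity network converges to the linear Cox score", {
  set.seed(6)
  n <- 300
  X <- matrix(rnorm(n * 5), n)
  oc <- generateSurvival(as.numeric(X %*% c(1, 0.8, -0.5, 0, 0)),
                         seed = 7)
  sp <- splitCohort(n, seed = 8)
  fit0 <- trainSurvivalNetwork(
    networkSpec(5, hidden = integer(0), activation = "identity",
                dropout = 0, weight_penalty = 0, learning_rate = 0.02,
                max_epochs = 3000, patience = 3000,
                restore_best = FALSE, seed = 9),
    X[sp$train, ], oc[sp$train, ], X[sp$validation, ],
    oc[sp$validation, ])
  cfit <- survival::coxph(
    survival::Surv(time, event) ~ ., ties = "breslow",
    data = data.frame(oc, X)[sp$train, ])
  clp <- as.numeric(X %*% coef(cfit))
  expect_gte(cor(predictRisk(fit0, X), clp, method = "spearman"), 0.99)
})

test_that("on linear data the network matches linear Cox; on nonlinear it wins", {
  set.seed(10)
  n <- 300
  X <- matrix(rnorm(n * 5), n)
  sp <- splitCohort(n, seed = 11)
  dftr <- function(oc) data.frame(oc, X)[sp$train, ]
  dfva <- function(oc) data.frame(oc, X)[sp$validation, ]
  # linear hazard
  ocl <- generateSurvival(as.numeric(X %*% c(1, 0.8, -0.5, 0, 0)),
                          seed = 12)
  fl <- trainSurvivalNetwork(networkSpec(5, seed = 13),
                             X[sp$train, ], ocl[sp$train, ],
                             X[sp$validation, ], ocl[sp$validation, ])
  cl <- survival::coxph(survival::Surv(time, event) ~ .,
                        data = dftr(ocl), ties = "breslow")
  ci_cox_l <- concordanceIndex(ocl[sp$validation, ],
                               predict(cl, newdata = dfva(ocl)))$cindex
  expect_gte(fl@log$validation_cindex, ci_cox_l - 0.03)
  # quadratic hazard: misspecified for linear Cox
  ocn <- generateSurvival(as.numeric(1.2 * X[, 1]^2 - 0.8), seed = 14)
  fn <- trainSurvivalNetwork(networkSpec(5, seed = 15),
                             X[sp$train, ], ocn[sp$train, ],
                             X[sp$validation, ], ocn[sp$validation, ])
  cn <- survival::coxph(survival::Surv(time, event) ~ .,
                        data = dftr(ocn), ties = "breslow")
  ci_cox_n <- concordanceIndex(ocn[sp$validation, ],
                               predict(cn, newdata = dfva(ocn)))$cindex
  expect_gte(fn@log$validation_cindex, ci_cox_n + 0.03)
})

test_that("grid search selects by C-index with shortest-time tie-break", {
  set.seed(16)
  n <- 120
  X <- matrix(rnorm(n * 3), n)
  oc <- generateSurvival(as.numeric(X %*% c(1, 0.5, 0)), seed = 17)
  sp <- splitCohort(n, seed = 18)
  one <- networkSpec(3, hidden = 8L, max_epochs = 60, seed = 19)
  g1 <- gridSearch(list(one), X[sp$train, ], oc[sp$train, ],
                   X[sp$validation, ], oc[sp$validation, ])
  expect_equal(g1$best_index, 1L)
  # synthetic log check of the tie-break rule: equal C-index, shorter time
  log <- data.frame(index = 1:2, cindex = c(0.7, 0.7),
                    training_seconds = c(2.0, 1.0))
  best <- which(log$cindex == max(log$cindex))
  best <- best[order(log$training_seconds[best])][1]
  expect_equal(best, 2L)
  # different C-indices: the higher one wins regardless of time
  two <- networkSpec(3, hidden = c(16L, 16L), max_epochs = 120, seed = 20)
  g2 <- gridSearch(list(one, two), X[sp$train, ], oc[sp$train, ],
                   X[sp$validation, ], oc[sp$validation, ])
  expect_equal(g2$best_index,
               which.max(g2$log$cindex))
})

test_that("personalized survival curves compose the baseline correctly", {
  # 4-subject worked example with hand-computed Breslow baseline
  oc <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  sc <- c(log(2), 0, 0, -log(2))
  # risk sets: t=1 {all: 2+1+1+0.5}, t=2 {1,1,0.5}, t=4 {0.5}
  h <- c(1 / 4.5, 1 / 2.5, 1 / 0.5)
  H <- cumsum(h)
  bl <- breslowBaseline(sc, oc)
  expect_equal(bl$hazard, H, tolerance = 1e-12, ignore_attr = TRUE)
  fit <- new("SurvivalNetworkFit", spec = list(input_dim = 1L),
             weights = list(), baseline = bl,
             standardization = list(center = 0, scale = 1), log = list())
  curves <- predictSurvival(fit, scores = c(0, log(3)))
  expect_equal(survivalAt(curves[[1]], c(0, 1, 2, 4)),
               exp(-c(0, H)), tolerance = 1e-10)
  expect_equal(survivalAt(curves[[2]], 4), exp(-H[3] * 3),
               tolerance = 1e-10)
  # monotonicity: larger score, pointwise lower curve
  expect_true(all(survivalAt(curves[[2]], c(1, 2, 4)) <=
                    survivalAt(curves[[1]], c(1, 2, 4))))
  expect_equal(curves[[1]]@surv[1], 1)
})

test_that("risk stratification applies the 3.3-month / 50% rule", {
  mk <- function(s33) new("SurvivalCurve", time = c(0, 3.3),
                          surv = c(1, s33))
  strata <- stratifyRisk(list(mk(0.6), mk(0.5), mk(0.2)))
  expect_equal(as.character(strata), c("low", "high", "high"))
  same <- stratifyRisk(list(mk(0.9), mk(0.9)))
  expect_equal(nlevels(droplevels(same)), 1L)
})
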