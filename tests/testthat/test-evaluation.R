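test_that("C-index matches hand-worked examples", {
  r <- concordanceIndex(data.frame(time = c(1, 2, 3),
                                   event = c(1, 1, 1)), c(3, 2, 1))
  expect_equal(r$cindex, 1)
  expect_equal(r$evaluable, 3)
  # censored middle subject: pairs (1,2) and (1,3) evaluable only
  # pair (2,3) is not evaluable: its shorter time is censored
  r2 <- concordanceIndex(data.frame(time = c(1, 2, 3),
                                    event = c(1, 0, 1)),
                         c(2.0, 3.0, 0.5))
  expect_equal(r2$evaluable, 2)
  expect_equal(r2$cindex, 0.5)
  expect_error(concordanceIndex(data.frame(time = c(1, 1),
                                           event = c(0, 0)), c(1, 2)),
               "evaluable")
})

test_that("C-index equals the O(n^2) brute-force oracle on random data", {
  for (r in 1:25) {
    o <- random_outcome(sample(5:50, 1), 500 + r)
    set.seed(600 + r)
    risk <- sample(rnorm(10), nrow(o), replace = TRUE)  # forces ties
    got <- concordanceIndex(o, risk)$cindex
    want <- oracle_cindex(o$time, o$event, risk)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("random risks give a chance-level C-index", {
  o <- random_outcome(200, 7)
  set.seed(8)
  cis <- replicate(20, concordanceIndex(o, rnorm(200))$cindex)
  expect_lt(abs(mean(cis) - 0.5), 0.05)
})

test_that("time-dependent AUC equals Mann-Whitney when censoring is absent", {
  set.seed(9)
  n <- 80
  o <- data.frame(time = rexp(n, 0.3), event = rep(1, n))
  sc <- rnorm(n) + 1.5 * (o$time < 2)
  for (t in c(1, 2, 4)) {
    case <- o$time <= t
    ctrl <- o$time > t
    if (!any(case) || !any(ctrl)) next
    roc <- timeDependentRoc(o, sc, t)
    expect_equal(roc$auc, oracle_mann_whitney(sc[case], sc[ctrl]),
                 tolerance = 1e-10)
  }
  # perfectly separating scores
  o2 <- data.frame(time = c(0.5, 0.7, 3, 4, 5), event = rep(1, 5))
  s2 <- c(10, 9, 1, 2, 0.5)
  expect_equal(timeDependentRoc(o2, s2, 1)$auc, 1)
  expect_error(timeDependentRoc(o2, s2, 10), "controls")
})

test_that("permuted scores give chance-level time-dependent AUC", {
  set.seed(10)
  o <- random_outcome(150, 11, cens = 0.25)
  aucs <- replicate(20, timeDependentRoc(o, rnorm(150),
                                         median(o$time))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("sensitivity and specificity come from the Youden threshold", {
  o <- data.frame(time = c(rep(0.5, 20), rep(5, 20)), event = rep(1, 40))
  sc <- c(rnorm(20, 3), rnorm(20, 0))
  roc <- timeDependentRoc(o, sc, 1)
  youden <- roc$sensitivity + roc$specificity - 1
  # no other threshold does better
  for (thr in sc) {
    sens <- mean(sc[1:20] > thr)
    spec <- mean(sc[21:40] <= thr)
    expect_lte(sens + spec - 1, youden + 1e-12)
  }
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmEstimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  expect_equal(survivalAt(km, c(0.5, 1, 2, 3)),
               c(1, 2 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  none <- kmEstimate(data.frame(time = c(2, 4), event = c(0, 0)))
  expect_true(all(none@surv == 1))
  o <- random_outcome(60, 12)
  kr <- kmEstimate(o)
  expect_true(all(diff(kr@surv) <= 1e-12))
  expect_equal(kr@surv[1], 1)
})

test_that("log-rank matches risk-set enumeration and handles identical groups", {
  a <- data.frame(time = c(1, 3, 5, 7), event = c(1, 1, 0, 1))
  same <- logRank(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # small worked dataset: observed/expected by direct risk-set bookkeeping
  b <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 1, 0))
  lr <- logRank(a, b)
  times <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  OmE <- 0; V <- 0
  for (t in times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t)
    d1 <- sum(a$time == t & a$event == 1)
    d2 <- sum(b$time == t & b$event == 1)
    d <- d1 + d2; n <- n1 + n2
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, OmE^2 / V, tolerance = 1e-8)
  expect_error(logRank(data.frame(time = 1, event = 0),
                       data.frame(time = 2, event = 0)), "no events")
})

test_that("log-rank type-I error is near nominal under the null", {
  set.seed(13)
  reps <- 200
  rej <- replicate(reps, {
    oa <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.75))
    ob <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.75))
    logRank(oa, ob)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("bootstrap model comparison is calibrated and deterministic", {
  set.seed(14)
  n <- 120
  o <- random_outcome(n, 15, cens = 0.2)
  good <- -o$time + rnorm(n, sd = 0.5)   # informative
  rand <- rnorm(n)
  cmp <- bootstrapCompare(o, good, good, times = c(1, 3), n_boot = 30,
                          seed = 16)
  expect_true(all(cmp$p > 0.99))
  cmp2 <- bootstrapCompare(o, good, rand, times = c(1, 3), n_boot = 30,
                           seed = 16)
  expect_true(all(cmp2$p < 0.05))
  expect_true(all(cmp2$auc_a > cmp2$auc_b))
  cmp3 <- bootstrapCompare(o, good, rand, times = c(1, 3), n_boot = 30,
                           seed = 16)
  expect_identical(cmp2, cmp3)
})

test_that("Shapley attributions satisfy null player, linearity, efficiency", {
  set.seed(17)
  X <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  beta <- c(2, -1, 0.5, 0)    # f4 is a null player
  f <- function(m) as.numeric(m %*% beta)
  phi <- shapleyAttribution(f, X, n_permutations = 40, seed = 18)
  mu <- colMeans(X)
  # closed-form Shapley value of an additive game
  for (j in 1:3)
    expect_equal(phi[, j], beta[j] * (X[, j] - mu[j]), tolerance = 1e-8)
  expect_true(all(abs(phi[, 4]) < 1e-10))
  # efficiency: attributions sum to score minus baseline
  expect_equal(rowSums(phi), f(X) - as.numeric(mu %*% beta),
               tolerance = 1e-8)
  expect_error(shapleyAttribution(f, X, n_permutations = 0), ">= 1")
})

test_that("Shapley explains a fitted survival network consistently", {
  set.seed(19)
  n <- 150
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  oc <- generateSurvival(as.numeric(X %*% c(1, -0.6, 0)), seed = 20)
  sp <- splitCohort(n, seed = 21)
  fit <- trainSurvivalNetwork(networkSpec(3, hidden = 8L, max_epochs = 150,
                                          seed = 22),
                              X[sp$train, ], oc[sp$train, ],
                              X[sp$validation, ], oc[sp$validation, ])
  sub <- X[sp$test[1:5], , drop = FALSE]
  phi <- shapleyAttribution(fit, sub, background = colMeans(X[sp$train, ]),
                            n_permutations = 30, seed = 23)
  base <- attr(phi, "baseline")
  expect_equal(rowSums(phi), predictRisk(fit, sub) - base,
               tolerance = 1e-6)
})
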