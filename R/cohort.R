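#' Default clinical marginal frequencies
#'
#' Marginal category probabilities of the clinical covariates used by
#' [generateClinicalTable()], chosen to match the published
#' characteristics of a 206-patient advanced lung-cancer immunotherapy
#' cohort (56.8% smokers, 58.7% stage IVB, 71.3% adenocarcinoma, 98.1%
#' high total protein, 91.3% normal mean corpuscular volume, 31.6%
#' female).
#'
#' @return a named list: one probability vector per categorical variable.
#' @export
clinicalMarginals <- function() {
  list(
    sex = c(female = 0.316, male = 0.684),
    smoking = c(smoker = 0.568, nonsmoker = 0.432),
    stage = c(II = 0.005, III = 0.024, IVA = 0.384, IVB = 0.587),
    histology = c(adenocarcinoma = 0.713, squamous = 0.131,
                  nos_carcinoma = 0.063, small_cell = 0.073, other = 0.020),
    total_protein = c(high = 0.981, normal = 0.019),
    mcv = c(high = 0.034, normal = 0.913, low = 0.053)
  )
}

#' Generate a synthetic clinical covariate table
#'
#' Draws categorical covariates independently from the given marginal
#' frequencies and age from a normal distribution centered at the
#' cohort's published median (62.2 years, SD from the reported IQR).
#'
#' @param n_subjects number of rows (>= 1).
#' @param marginals named list of per-variable probability vectors, each
#'   summing to 1 (default [clinicalMarginals()]).
#' @param seed integer seed.
#' @return a data.frame with columns `age` (numeric) and factor columns
#'   `sex`, `smoking`, `stage`, `histology`, `total_protein`, `mcv`.
#' @examples
#' head(generateClinicalTable(5, seed = 1))
#' @export
generateClinicalTable <- function(n_subjects, marginals = clinicalMarginals(),
                                  seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (abs(sum(p) - 1) > 1e-9)
      stop("marginals for '", nm, "' do not sum to 1")
    if (any(p < 0)) stop("marginals for '", nm, "' contain negatives")
  }
  .with_seed(seed, {
    out <- data.frame(age = pmin(pmax(rnorm(n_subjects, 62.2, 9.5), 25), 92))
    for (nm in names(marginals)) {
      p <- marginals[[nm]]
      out[[nm]] <- factor(
        sample(names(p), n_subjects, replace = TRUE, prob = p),
        levels = names(p))
    }
    out
  })
}

#' Generate survival outcomes from a proportional-hazards model
#'
#' Event times follow a Weibull baseline hazard multiplied by
#' exp(linear predictor); censoring times are drawn independently from a
#' uniform window whose width is calibrated numerically so that the
#' expected censored fraction equals `censoring_rate`. The recorded time
#' is the minimum of the two, with `event = 1` when the event came first.
#'
#' @param linear_predictor numeric vector of per-subject log relative
#'   hazards (finite).
#' @param baseline_shape,baseline_scale Weibull shape k and scale lambda
#'   of the baseline: S0(t) = exp(-(t/lambda)^k). Defaults give a median
#'   baseline progression time of 3.3 months.
#' @param censoring_rate target expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return a data.frame with numeric columns `time` (months) and `event`
#'   (1 = progression, 0 = censored).
#' @examples
#' o <- generateSurvival(rnorm(20), seed = 3)
#' table(o$event)
#' @export
generateSurvival <- function(linear_predictor,
                             baseline_shape = 1,
                             baseline_scale = 3.3 / log(2),
                             censoring_rate = 0.3,
                             seed = 1L) {
  lp <- linear_predictor
  if (any(!is.finite(lp))) stop("linear predictors must be finite")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  k <- baseline_shape
  lam <- baseline_scale
  .with_seed(seed, {
    e <- rexp(length(lp))
    t_event <- lam * (e / exp(lp))^(1 / k)
    if (censoring_rate == 0) {
      return(data.frame(time = t_event, event = rep(1, length(lp))))
    }
    cmax <- .calibrate_censor_window(lp, k, lam, censoring_rate)
    t_cens <- runif(length(lp), 0, cmax)
    data.frame(time = pmin(t_event, t_cens),
               event = as.numeric(t_event <= t_cens))
  })
}

# solve for the uniform censor window width c so that the expected
# censored fraction E_i[ (1/c) * int_0^c S_i(t) dt ] equals the target
.calibrate_censor_window <- function(lp, k, lam, rate) {
  expected_cens <- function(cmax) {
    grid <- seq(0, cmax, length.out = 257L)
    s <- vapply(lp, function(b) {
      surv <- exp(-(grid / lam)^k * exp(b))
      # trapezoid integral of S_i over [0, cmax], divided by cmax
      sum((surv[-1] + surv[-length(surv)]) / 2) * (grid[2] - grid[1]) / cmax
    }, numeric(1))
    mean(s)
  }
  f <- function(cmax) expected_cens(cmax) - rate
  hi <- lam
  while (f(hi) > 0 && hi < lam * 1e6) hi <- hi * 2
  uniroot(f, c(1e-6, hi), tol = 1e-6)$root
}

#' Default true hazard coefficients for the synthetic cohort
#'
#' Log-hazard weights of the phantom-derived and laboratory covariates
#' that drive survival in [generateCohort()]: larger tumors, higher
#' intratumoral heterogeneity, higher peritumoral vessel torsion, normal
#' (i.e. lower) total protein and high mean corpuscular volume all worsen
#' prognosis. Continuous features enter after cohort-level z-scoring.
#'
#' @return a named numeric vector; names of the form `column` or
#'   `column=level` for factor indicators.
#' @export
defaultHazardCoefficients <- function() {
  c("tumor_volume_cm3" = 0.55,
    "tumor_heterogeneity" = 0.50,
    "vessel_mean_torsion" = 0.70,
    "total_protein=normal" = 0.70,
    "mcv=high" = 0.80)
}

#' Generate a full synthetic cohort with known hazard structure
#'
#' Draws per-subject phantom parameters (tumor radius, heterogeneity,
#' vessel tortuosity), converts them to subject-level features (tumor
#' volume/diameter, mean branch torsion and curvature from the closed-form
#' helix geometry), attaches a clinical table and noise features, and
#' generates progression-free survival from a Weibull
#' proportional-hazards model whose log-hazard is a known linear
#' combination of those features.
#'
#' @param n_subjects cohort size (default 206).
#' @param hazard_coefficients named log-hazard weights (see
#'   [defaultHazardCoefficients()]); continuous columns are z-scored
#'   across the cohort before entering the linear predictor, factor
#'   indicators are referenced as `column=level`.
#' @param baseline_shape,baseline_scale,censoring_rate passed to
#'   [generateSurvival()].
#' @param marginals clinical marginals, see [generateClinicalTable()].
#' @param n_noise_features number of standard-normal nuisance features
#'   appended as `noise_1 ...` (default 10).
#' @param seed integer seed.
#' @return a list with `features` (data.frame, one row per subject),
#'   `outcome` (data.frame `time`, `event`) and `truth` (list with the
#'   per-subject true linear predictor `lp` and the raw phantom parameter
#'   draws `params`).
#' @examples
#' coh <- generateCohort(50, seed = 2)
#' str(coh$outcome)
#' @export
generateCohort <- function(n_subjects = 206L,
                           hazard_coefficients = defaultHazardCoefficients(),
                           baseline_shape = 1,
                           baseline_scale = 3.3 / log(2),
                           censoring_rate = 0.3,
                           marginals = clinicalMarginals(),
                           n_noise_features = 10L,
                           seed = 1L) {
  clin <- generateClinicalTable(n_subjects, marginals, seed = seed + 1L)
  feats <- .with_seed(seed + 2L, {
    radius <- runif(n_subjects, 5, 15)
    heterog <- runif(n_subjects, 0.05, 0.6)
    tort <- runif(n_subjects, 0.1, 1.5)
    amp <- pmin(tort, 1)
    pitch <- 3 / tort
    f <- data.frame(
      tumor_volume_cm3 = 4 / 3 * pi * radius^3 / 1000,
      tumor_diameter_mm = 2 * radius,
      tumor_heterogeneity = heterog,
      vessel_mean_torsion = pitch / (amp^2 + pitch^2),
      vessel_mean_curvature = amp / (amp^2 + pitch^2))
    if (n_noise_features > 0) {
      noise <- matrix(rnorm(n_subjects * n_noise_features),
                      nrow = n_subjects)
      colnames(noise) <- paste0("noise_", seq_len(n_noise_features))
      f <- cbind(f, as.data.frame(noise))
    }
    attr(f, "params") <- data.frame(tumor_radius_mm = radius,
                                    heterogeneity = heterog,
                                    tortuosity = tort)
    f
  })
  params <- attr(feats, "params")
  attr(feats, "params") <- NULL
  features <- cbind(feats, clin)
  lp <- .linear_predictor(features, hazard_coefficients)
  # recenter the linear predictor so the cohort-level median progression
  # time stays at the baseline median (3.3 months by default): covariate
  # dispersion would otherwise drag the mixture median down. A constant
  # shift leaves all hazard ratios untouched.
  lp <- lp - .median_preserving_offset(lp)
  outcome <- generateSurvival(lp, baseline_shape, baseline_scale,
                              censoring_rate, seed = seed + 3L)
  list(features = features, outcome = outcome,
       truth = list(lp = lp, params = params,
                    coefficients = hazard_coefficients))
}

# offset c such that mean_i S0(t_med)^(exp(lp_i - c)) = 0.5, i.e. the
# population survival at the baseline median time is one half
.median_preserving_offset <- function(lp) {
  f <- function(c0) mean(exp(-log(2) * exp(lp - c0))) - 0.5
  uniroot(f, c(-20, 20), tol = 1e-8)$root
}

.linear_predictor <- function(features, coefs) {
  lp <- numeric(nrow(features))
  for (nm in names(coefs)) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      col <- parts[1]; level <- parts[2]
      if (!col %in% names(features)) stop("unknown hazard column: ", col)
      lp <- lp + coefs[[nm]] * as.numeric(features[[col]] == level)
    } else {
      if (!nm %in% names(features)) stop("unknown hazard column: ", nm)
      x <- features[[nm]]
      s <- sd(x)
      z <- if (s > 0) (x - mean(x)) / s else x * 0
      lp <- lp + coefs[[nm]] * z
    }
  }
  lp
}
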