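# Synthetic cohort generation: discrete-time hazard model with covariate
# effects, administrative censoring and a date-ordered train/test split,
# emulating the tabular structure of a radiotherapy EMR registry.

#' Default covariate distributions for a head and neck cancer cohort
#'
#' Returns the per-variable distribution descriptors used by
#' [cohort_config()] when none are supplied. The mix of disease sites, HPV
#' status (with an explicit "Not tested" level), staging and treatment
#' variables is chosen to resemble a large single-institution radiotherapy
#' registry: male-dominant, oropharynx-heavy, with roughly half of tested
#' patients HPV positive.
#'
#' @return Named list of distribution descriptors. Continuous variables carry
#'   `type = "continuous"`, `mean`, `sd`; categorical variables carry
#'   `type = "categorical"`, `levels`, `probs`.
#' @export
default_covariate_specs <- function() {
  list(
    age = list(type = "continuous", mean = 62, sd = 11),
    sex = list(type = "categorical",
               levels = c("Male", "Female"), probs = c(0.74, 0.26)),
    t_stage = list(type = "categorical",
                   levels = c("T1", "T2", "T3", "T4"),
                   probs = c(0.20, 0.30, 0.28, 0.22)),
    n_stage = list(type = "categorical",
                   levels = c("N0", "N1", "N2", "N3"),
                   probs = c(0.30, 0.12, 0.48, 0.10)),
    overall_stage = list(type = "categorical",
                         levels = c("I", "II", "III", "IV"),
                         probs = c(0.12, 0.15, 0.22, 0.51)),
    disease_site = list(type = "categorical",
                        levels = c("Oropharynx", "Larynx", "Nasopharynx",
                                   "Hypopharynx", "Other"),
                        probs = c(0.50, 0.20, 0.12, 0.06, 0.12)),
    performance_status = list(type = "categorical",
                              levels = c("ECOG0", "ECOG1", "ECOG2+", "Missing"),
                              probs = c(0.45, 0.40, 0.12, 0.03)),
    hpv_status = list(type = "categorical",
                      levels = c("Positive", "Negative", "Not tested"),
                      probs = c(0.50, 0.25, 0.25)),
    dose_gy = list(type = "continuous", mean = 66, sd = 6),
    chemotherapy = list(type = "categorical",
                        levels = c("No", "Yes"), probs = c(0.45, 0.55))
  )
}

#' Default ground-truth log-hazard effects
#'
#' Per-level (categorical) and per-standard-deviation (continuous) log-hazard
#' coefficients used to simulate survival. The first level of each categorical
#' variable is the reference (effect 0) and is omitted. `log_volume` acts on
#' standardised log tumor volume. Signs follow established prognosis in head
#' and neck cancer: higher stage, worse performance status, HPV negativity and
#' larger tumor volume increase the hazard; higher dose and systemic therapy
#' are mildly protective.
#'
#' @return Named list: one named numeric vector per categorical variable, one
#'   scalar per continuous variable, plus `log_volume`.
#' @export
default_true_coefficients <- function() {
  list(
    age = 0.25,
    sex = c(Female = -0.10),
    t_stage = c(T2 = 0.15, T3 = 0.35, T4 = 0.60),
    n_stage = c(N1 = 0.10, N2 = 0.30, N3 = 0.60),
    overall_stage = c(II = 0.05, III = 0.15, IV = 0.30),
    disease_site = c(Larynx = 0.10, Nasopharynx = -0.20,
                     Hypopharynx = 0.40, Other = 0.20),
    performance_status = c(ECOG1 = 0.20, `ECOG2+` = 0.60, Missing = 0.20),
    hpv_status = c(Negative = 0.70, `Not tested` = 0.30),
    dose_gy = -0.10,
    chemotherapy = c(Yes = -0.15),
    log_volume = 0.45
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the simulated data-generating process: covariate
#' distributions, log-normal tumor volume, ground-truth log-hazard effects, a
#' per-month baseline hazard, administrative censoring and the RNG seed.
#'
#' Survival times arise from the discrete-time hazard
#' \eqn{h_k(x) = \min(1, h_{0k} \exp(\beta \cdot x))} over months
#' \eqn{k = 1, \dots, K}; any patient surviving all \eqn{K} months dies in the
#' final month (the last interval is absorbing), so with no censoring every
#' patient has an event. A `censoring_rate` fraction of patients receives an
#' administrative censoring time drawn uniformly on [24, 84] months and is
#' censored if death would occur later; censoring therefore never happens
#' before 24 months, which enforces the inclusion rule that censored patients
#' have at least 2 years of follow-up.
#'
#' @param n_patients Number of patients (>= 2).
#' @param covariate_specs Per-variable distribution descriptors; see
#'   [default_covariate_specs()].
#' @param volume_logmean,volume_logsd Log-space mean and SD of tumor volume
#'   (cc); defaults give a median of about 15 cc.
#' @param true_coefficients Ground-truth log-hazard effects; see
#'   [default_true_coefficients()].
#' @param baseline_hazard Per-month baseline event probability vector; its
#'   length sets the maximum follow-up. The default (constant 0.0018 over 240
#'   months) was calibrated once so that, combined with the default covariate
#'   effects, the marginal 2-year event fraction is close to 0.14.
#' @param censoring_rate Fraction of patients subject to administrative
#'   censoring on [24, 84] months.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#' @param cohort_label Label stored with every generated patient.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2552,
                          covariate_specs = default_covariate_specs(),
                          volume_logmean = log(15),
                          volume_logsd = 1.0,
                          true_coefficients = default_true_coefficients(),
                          baseline_hazard = rep(0.0018, 240),
                          censoring_rate = 0.55,
                          seed = 1L,
                          cohort_label = "internal") {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2) {
    stop("`n_patients` must be a single number >= 2", call. = FALSE)
  }
  for (nm in names(covariate_specs)) {
    spec <- covariate_specs[[nm]]
    if (identical(spec$type, "categorical")) {
      if (length(spec$levels) != length(spec$probs)) {
        stop("levels/probs length mismatch for variable '", nm, "'",
             call. = FALSE)
      }
      if (any(spec$probs < 0) || abs(sum(spec$probs) - 1) > 1e-8) {
        stop("category probabilities for '", nm,
             "' must be nonnegative and sum to 1", call. = FALSE)
      }
      if (anyDuplicated(spec$levels)) {
        stop("duplicate levels for variable '", nm, "'", call. = FALSE)
      }
    } else if (identical(spec$type, "continuous")) {
      if (!is.numeric(spec$mean) || !is.numeric(spec$sd) || spec$sd <= 0) {
        stop("continuous spec for '", nm, "' needs mean and sd > 0",
             call. = FALSE)
      }
    } else {
      stop("unknown spec type for variable '", nm, "'", call. = FALSE)
    }
  }
  if (any(baseline_hazard < 0) || any(baseline_hazard > 1)) {
    stop("`baseline_hazard` entries must lie in [0, 1]", call. = FALSE)
  }
  if (censoring_rate < 0 || censoring_rate > 1) {
    stop("`censoring_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (volume_logsd <= 0) stop("`volume_logsd` must be > 0", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients),
         covariate_specs = covariate_specs,
         volume_logmean = volume_logmean,
         volume_logsd = volume_logsd,
         true_coefficients = true_coefficients,
         baseline_hazard = as.numeric(baseline_hazard),
         censoring_rate = censoring_rate,
         seed = as.integer(seed),
         cohort_label = cohort_label),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_patients:    ", x$n_patients, "\n")
  cat("  variables:     ", paste(names(x$covariate_specs), collapse = ", "),
      "\n")
  cat("  follow-up:     ", length(x$baseline_hazard), "months\n")
  cat("  censoring_rate:", x$censoring_rate, "\n")
  cat("  seed:          ", x$seed, "\n")
  invisible(x)
}

# Evaluate a function with a temporary RNG state so generators are
# deterministic in `seed` without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground-truth linear predictor
#'
#' Computes \eqn{\beta \cdot x} for every patient from the configuration's
#' true coefficients: continuous variables are standardised by their spec mean
#' and SD, categorical variables contribute their level's coefficient
#' (reference levels contribute 0), and log tumor volume is standardised by
#' the configured log-space parameters.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param config The `cohort_config` that generated it (or one sharing its
#'   specs and coefficients).
#' @return Numeric vector of log-hazard linear predictors.
#' @export
true_linear_predictor <- function(cohort, config) {
  beta <- config$true_coefficients
  lp <- numeric(nrow(cohort))
  for (nm in names(config$covariate_specs)) {
    spec <- config$covariate_specs[[nm]]
    b <- beta[[nm]]
    if (is.null(b)) next
    if (identical(spec$type, "continuous")) {
      lp <- lp + b * (cohort[[nm]] - spec$mean) / spec$sd
    } else {
      eff <- b[match(as.character(cohort[[nm]]), names(b))]
      eff[is.na(eff)] <- 0
      lp <- lp + eff
    }
  }
  if (!is.null(beta$log_volume)) {
    lp <- lp + beta$log_volume *
      (log(cohort$volume_cc) - config$volume_logmean) / config$volume_logsd
  }
  lp
}

#' Generate a synthetic cohort
#'
#' Draws covariates, tumor volume and censored survival times from the
#' discrete-time hazard model described in [cohort_config()]. Death times fall
#' on integer months; censoring times are continuous on [24, 84] months.
#' `diagnosis_index` is a random permutation of `1:n` used by
#' [split_by_date()] to emulate a split by date of diagnosis.
#'
#' @param config A `cohort_config`.
#' @return A data frame of class `cohort` with columns `patient_id`, the
#'   covariates, `volume_cc`, `time_months`, `event` (1 = death),
#'   `diagnosis_index` and `cohort_label`. Every censored patient has
#'   `time_months >= 24`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    cov_df <- list(patient_id = sprintf("P%05d", seq_len(n)))
    for (nm in names(config$covariate_specs)) {
      spec <- config$covariate_specs[[nm]]
      cov_df[[nm]] <- if (identical(spec$type, "continuous")) {
        stats::rnorm(n, spec$mean, spec$sd)
      } else {
        sample(spec$levels, n, replace = TRUE, prob = spec$probs)
      }
    }
    cov_df$volume_cc <- stats::rlnorm(n, config$volume_logmean,
                                      config$volume_logsd)
    cohort <- as.data.frame(cov_df, stringsAsFactors = FALSE)

    lp <- true_linear_predictor(cohort, config)
    K <- length(config$baseline_hazard)
    rel_risk <- exp(lp)
    death_month <- rep.int(NA_integer_, n)
    alive <- rep.int(TRUE, n)
    for (k in seq_len(K)) {
      if (!any(alive)) break
      hk <- pmin(config$baseline_hazard[k] * rel_risk[alive], 1)
      dies <- stats::runif(sum(alive)) < hk
      idx <- which(alive)[dies]
      death_month[idx] <- k
      alive[idx] <- FALSE
    }
    # final interval is absorbing: everyone still alive dies at month K
    death_month[alive] <- K

    time <- as.numeric(death_month)
    event <- rep.int(1L, n)
    n_cens <- round(config$censoring_rate * n)
    if (n_cens > 0) {
      cens_ids <- sample.int(n, n_cens)
      cens_time <- stats::runif(n_cens, 24, 84)
      is_cens <- time[cens_ids] > cens_time
      time[cens_ids[is_cens]] <- cens_time[is_cens]
      event[cens_ids[is_cens]] <- 0L
    }

    cohort$time_months <- time
    cohort$event <- event
    cohort$diagnosis_index <- sample.int(n)
    cohort$cohort_label <- config$cohort_label
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Shift covariate distributions of a cohort configuration
#'
#' Returns a configuration identical to `config` except that the distribution
#' descriptors of the named variables are replaced, emulating an external
#' cohort from a different patient population. Ground-truth coefficients,
#' baseline hazard and volume effect are untouched, so the outcome model is
#' shared across cohorts and only the covariate mix shifts.
#'
#' @param config A `cohort_config`.
#' @param shift Named list; each element replaces fields of the matching
#'   `covariate_specs` entry (`probs` and/or `levels` for categorical,
#'   `mean`/`sd` for continuous). The special names `volume_logmean` and
#'   `volume_logsd` replace the volume parameters.
#' @param seed Optional new seed for the shifted configuration.
#' @param cohort_label Optional new label.
#' @return A new `cohort_config`.
#' @export
apply_shift <- function(config, shift, seed = NULL, cohort_label = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$covariate_specs
  vol_lm <- config$volume_logmean
  vol_ls <- config$volume_logsd
  for (nm in names(shift)) {
    if (nm == "volume_logmean") { vol_lm <- shift[[nm]]; next }
    if (nm == "volume_logsd")   { vol_ls <- shift[[nm]]; next }
    if (!nm %in% names(specs)) {
      stop("cannot shift unknown variable '", nm, "'", call. = FALSE)
    }
    for (field in names(shift[[nm]])) {
      specs[[nm]][[field]] <- shift[[nm]][[field]]
    }
  }
  cohort_config(
    n_patients = config$n_patients,
    covariate_specs = specs,
    volume_logmean = vol_lm,
    volume_logsd = vol_ls,
    true_coefficients = config$true_coefficients,
    baseline_hazard = config$baseline_hazard,
    censoring_rate = config$censoring_rate,
    seed = if (is.null(seed)) config$seed else as.integer(seed),
    cohort_label = if (is.null(cohort_label)) config$cohort_label
                   else cohort_label
  )
}

#' Generate a volume-coupled synthetic feature block
#'
#' Emulates engineered image features whose values are partly driven by tumor
#' volume: each of the `p` features is `volume_coupling * z + noise_sd * e`
#' with `z` the standardised log volume and `e` independent standard normal
#' noise. At `volume_coupling = 1` and vanishing noise every feature is a
#' monotone transform of volume (Spearman correlation 1); at
#' `volume_coupling = 0` features are pure noise.
#'
#' @param cohort A cohort data frame.
#' @param p Number of features (>= 1).
#' @param volume_coupling Mixing weight on standardised log volume, in [0, 1].
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A `feature_matrix` (see [encode()]) with features named
#'   `synth_feat_001`, ...
#' @export
generate_feature_block <- function(cohort, p, volume_coupling = 0.5,
                                   noise_sd = 1, seed = 1L) {
  if (p < 1) stop("`p` must be >= 1", call. = FALSE)
  if (volume_coupling < 0 || volume_coupling > 1) {
    stop("`volume_coupling` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  n <- nrow(cohort)
  z <- as.numeric(scale(log(cohort$volume_cc)))
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * p, 0, 1), n, p)
    vals <- volume_coupling * z + noise_sd * noise
    colnames(vals) <- sprintf("synth_feat_%03d", seq_len(p))
    new_feature_matrix(vals, schema = NULL)
  })
}

#' Split a cohort by diagnosis date
#'
#' Orders patients by `diagnosis_index` (a stand-in for date of diagnosis) and
#' assigns the earliest `train_fraction` share to training and the remainder
#' to the test set — the design in which the model never sees patients
#' diagnosed after the training cutoff.
#'
#' @param cohort A cohort data frame.
#' @param train_fraction Fraction in (0, 1); the number of training patients
#'   is `round(train_fraction * n)`.
#' @return List with elements `train` and `test`, a disjoint exhaustive
#'   partition.
#' @export
split_by_date <- function(cohort, train_fraction = 0.706) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  ord <- order(cohort$diagnosis_index)
  n_train <- round(train_fraction * nrow(cohort))
  n_train <- max(1L, min(nrow(cohort) - 1L, n_train))
  list(train = cohort[ord[seq_len(n_train)], , drop = FALSE],
       test = cohort[ord[-seq_len(n_train)], , drop = FALSE])
}

#' Binarize overall survival at a horizon
#'
#' Label 1 if the patient died at or before the horizon, 0 otherwise. Because
#' every censored patient has at least `horizon_months` of follow-up by the
#' cohort inclusion rule, no label is ambiguous and no censoring correction is
#' needed; a censored patient with shorter follow-up is an invariant
#' violation and raises an error. A death at exactly the horizon counts as an
#' event.
#'
#' @param cohort A cohort data frame.
#' @param horizon_months Horizon in months (default 24, i.e. 2-year survival).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_outcome <- function(cohort, horizon_months = 24) {
  if (horizon_months <= 0) stop("`horizon_months` must be > 0", call. = FALSE)
  bad <- cohort$event == 0 & cohort$time_months < horizon_months
  if (any(bad)) {
    stop(sum(bad), " censored patient(s) with follow-up shorter than the ",
         "horizon; binary labels would be ambiguous", call. = FALSE)
  }
  as.integer(cohort$event == 1 & cohort$time_months <= horizon_months)
}

#' Write / read a cohort as CSV
#'
#' One row per patient with the documented header (`patient_id`, covariates,
#' `volume_cc`, `time_months`, `event`, `diagnosis_index`, `cohort_label`).
#' Missing categorical values travel as their literal tokens (e.g.
#' `"Not tested"`).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a cohort configuration from YAML
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [cohort_config()]; omitted keys fall back to the defaults. Categorical
#' coefficient vectors are given as named maps.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  simple <- c("n_patients", "volume_logmean", "volume_logsd",
              "censoring_rate", "seed", "cohort_label")
  for (nm in intersect(simple, names(y))) args[[nm]] <- y[[nm]]
  if (!is.null(y$baseline_hazard)) {
    args$baseline_hazard <- as.numeric(unlist(y$baseline_hazard))
  }
  if (!is.null(y$covariate_specs)) {
    specs <- default_covariate_specs()
    for (nm in names(y$covariate_specs)) {
      s <- y$covariate_specs[[nm]]
      if (!is.null(s$levels)) s$levels <- as.character(unlist(s$levels))
      if (!is.null(s$probs)) s$probs <- as.numeric(unlist(s$probs))
      specs[[nm]] <- utils::modifyList(
        if (nm %in% names(specs)) specs[[nm]] else list(), s)
    }
    args$covariate_specs <- specs
  }
  if (!is.null(y$true_coefficients)) {
    args$true_coefficients <- lapply(y$true_coefficients, function(b) {
      if (is.list(b)) unlist(b) else b
    })
  }
  do.call(cohort_config, args)
}
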