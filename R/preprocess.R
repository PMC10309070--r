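# Covariate encoding: full one-hot for categoricals (with an explicit
# missing-value level), train-set standardisation for continuous variables,
# log transform + standardisation for tumor volume.

MISSING_TOKENS <- c("Missing", "Not tested", "NA", "")

new_feature_matrix <- function(values, schema = NULL) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values))) {
    stop("feature matrix contains non-finite entries", call. = FALSE)
  }
  structure(list(values = values,
                 feature_names = colnames(values),
                 schema = schema),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " patients x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Column-bind feature matrices
#'
#' @param ... `feature_matrix` objects with equal row counts.
#' @return A `feature_matrix` carrying the schema of the first argument.
#' @export
cbind_features <- function(...) {
  mats <- list(...)
  vals <- do.call(cbind, lapply(mats, function(m) m$values))
  new_feature_matrix(vals, schema = mats[[1]]$schema)
}

default_missing_level <- function(variable) {
  if (variable == "hpv_status") "Not tested" else "Missing"
}

#' Fit an encoding schema on a training cohort
#'
#' Collects the categorical levels and continuous standardisation statistics
#' from the training cohort only, so that test cohorts are encoded with
#' frozen training-set parameters. Each categorical variable gets an explicit
#' missing-value level (`"Not tested"` for HPV status, `"Missing"`
#' otherwise), appended if not already observed; at encoding time any unseen
#' level maps to that column. `volume_cc`, when included, is log-transformed
#' before standardisation.
#'
#' @param train_cohort A cohort data frame (the training split).
#' @param variables Character vector of cohort columns to encode.
#' @param log_volume Should `volume_cc` enter as standardised log volume?
#' @return An `encoding_schema`.
#' @export
fit_schema <- function(train_cohort,
                       variables = c("age", "sex", "t_stage", "n_stage",
                                     "overall_stage", "disease_site",
                                     "performance_status", "hpv_status",
                                     "dose_gy", "chemotherapy", "volume_cc"),
                       log_volume = TRUE) {
  missing_vars <- setdiff(variables, names(train_cohort))
  if (length(missing_vars)) {
    stop("variables not present in cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  categorical_levels <- list()
  continuous_stats <- list()
  for (nm in variables) {
    x <- train_cohort[[nm]]
    if (is.numeric(x)) {
      val <- if (nm == "volume_cc" && log_volume) log(x) else x
      m <- mean(val)
      s <- stats::sd(val)
      if (!is.finite(s) || s == 0) {
        stop("continuous variable '", nm, "' is constant on the training ",
             "cohort; cannot standardise", call. = FALSE)
      }
      continuous_stats[[nm]] <- c(mean = m, sd = s)
    } else {
      lev <- unique(as.character(x))
      miss <- default_missing_level(nm)
      lev <- union(setdiff(sort(lev), MISSING_TOKENS), miss)
      categorical_levels[[nm]] <- lev
    }
  }
  structure(list(variables = variables,
                 categorical_levels = categorical_levels,
                 continuous_stats = continuous_stats,
                 log_volume = log_volume),
            class = "encoding_schema")
}

#' @export
print.encoding_schema <- function(x, ...) {
  cat("<encoding_schema> ", length(x$variables), " variables (",
      length(x$categorical_levels), " categorical, ",
      length(x$continuous_stats), " continuous)\n", sep = "")
  invisible(x)
}

#' Encode a cohort into a numeric design matrix
#'
#' Applies a fitted [fit_schema()]: full one-hot columns (no reference-level
#' dropping — downstream models are regularised) for categoricals, train-set
#' standardisation for continuous variables, and standardised log volume when
#' configured. Column order follows the schema, so train and test matrices
#' are always column-compatible. Values unseen at training time (including
#' literal missing tokens) land in the variable's missing-value column.
#'
#' @param cohort A cohort data frame.
#' @param schema An `encoding_schema`.
#' @return A `feature_matrix` with names like `hpv_status=Negative`,
#'   `age`, `log_volume_cc`.
#' @export
encode <- function(cohort, schema) {
  stopifnot(inherits(schema, "encoding_schema"))
  n <- nrow(cohort)
  cols <- list()
  for (nm in schema$variables) {
    if (nm %in% names(schema$continuous_stats)) {
      st <- schema$continuous_stats[[nm]]
      val <- cohort[[nm]]
      out_nm <- nm
      if (nm == "volume_cc" && schema$log_volume) {
        val <- log(val)
        out_nm <- "log_volume_cc"
      }
      col <- matrix((val - st["mean"]) / st["sd"], ncol = 1)
      colnames(col) <- out_nm
      cols[[nm]] <- col
    } else {
      lev <- schema$categorical_levels[[nm]]
      miss <- default_missing_level(nm)
      x <- as.character(cohort[[nm]])
      x[is.na(x) | x %in% MISSING_TOKENS | !(x %in% lev)] <- miss
      block <- matrix(0, n, length(lev))
      block[cbind(seq_len(n), match(x, lev))] <- 1
      colnames(block) <- paste0(nm, "=", lev)
      cols[[nm]] <- block
    }
  }
  new_feature_matrix(do.call(cbind, cols), schema = schema)
}

#' Serialize / restore an encoding schema as JSON
#'
#' @param schema An `encoding_schema`.
#' @param path File path.
#' @return `schema_to_json` returns `path` invisibly; `schema_from_json`
#'   returns the restored `encoding_schema`.
#' @export
schema_to_json <- function(schema, path) {
  obj <- list(variables = schema$variables,
              categorical_levels = schema$categorical_levels,
              continuous_stats = lapply(schema$continuous_stats, as.list),
              log_volume = schema$log_volume)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(variables = obj$variables,
                 categorical_levels = as.list(obj$categorical_levels),
                 continuous_stats = lapply(obj$continuous_stats, unlist),
                 log_volume = obj$log_volume),
            class = "encoding_schema")
}
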