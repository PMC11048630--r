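#' Fit the feature preprocessor on a training partition
#'
#' The 45 numeric metrics are standardized (z-scored) and the 2 categorical
#' metrics are one-hot encoded.  Statistics are computed on the training
#' partition only and frozen, so test-time and predict-time transforms never
#' leak information.  Standard deviations use the population (divide-by-n)
#' form for bit-reproducibility; a constant column gets its deviation
#' replaced by 1 (with a warning) so its z-scores are exactly 0.  One-hot
#' widths equal the number of levels seen in training; levels are sorted so
#' the encoding does not depend on row order.
#'
#' Post-encoding input widths therefore exceed the raw metric counts
#' (47/25/22): the branch input sizes are derived from the fitted encoder.
#'
#' @param train Training plan table (data frame).
#' @param schema A `metric_schema`.
#' @return A `gpr_preprocessor`: centers/scales per numeric metric, level
#'   sets per categorical metric, the feature-column names, and the index
#'   blocks identifying the Linac and plan sub-vectors.
#' @export
fit_preprocessor <- function(train, schema) {
  if (nrow(train) == 0) stop("cannot fit a preprocessor on an empty training set")
  missing <- setdiff(schema$name, names(train))
  if (length(missing) > 0) {
    stop("training table is missing metric(s): ", paste(missing, collapse = ", "))
  }

  center <- numeric(0)
  scale <- numeric(0)
  levels <- list()
  feature_names <- character(0)
  feature_metric <- character(0)

  constant_cols <- character(0)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$dtype[i] == "numeric") {
      x <- as.numeric(train[[nm]])
      if (anyNA(x) || any(!is.finite(x))) {
        stop("numeric metric '", nm, "' has missing or non-finite training values")
      }
      m <- mean(x)
      s <- sqrt(mean((x - m)^2))  # population sd
      if (s < 1e-12) {
        constant_cols <- c(constant_cols, nm)
        s <- 1
      }
      center[nm] <- m
      scale[nm] <- s
      feature_names <- c(feature_names, nm)
      feature_metric <- c(feature_metric, nm)
    } else {
      lev <- sort(unique(as.character(train[[nm]])))
      if (length(lev) == 0) stop("categorical metric '", nm, "' has no levels")
      levels[[nm]] <- lev
      feature_names <- c(feature_names, paste0(nm, ".", lev))
      feature_metric <- c(feature_metric, rep(nm, length(lev)))
    }
  }
  if (length(constant_cols) > 0) {
    warning("constant numeric metric(s) ", paste(constant_cols, collapse = ", "),
            ": standard deviation replaced by 1 (transformed values will be 0)")
  }

  metric_cat <- schema$category[match(feature_metric, schema$name)]
  structure(list(
    schema = schema,
    center = center,
    scale = scale,
    levels = levels,
    feature_names = feature_names,
    feature_metric = feature_metric,
    linac_idx = which(metric_cat == "linac"),
    plan_idx = which(metric_cat == "plan")
  ), class = "gpr_preprocessor")
}

#' Transform a plan table into the model feature matrix
#'
#' Numeric entries become `(value - mean) / sd` with the frozen training
#' statistics; categorical entries become one-hot indicators.  A level not
#' seen in training maps to an all-zero indicator block, with a warning.
#'
#' @param pp A fitted `gpr_preprocessor`.
#' @param data Plan table to transform.
#' @return A numeric matrix (samples x features) with attributes
#'   `linac_idx` and `plan_idx` giving the branch index blocks.
#' @export
transform_features <- function(pp, data) {
  schema <- pp$schema
  missing <- setdiff(schema$name, names(data))
  if (length(missing) > 0) {
    stop("table is missing metric(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(data)
  X <- matrix(0, nrow = n, ncol = length(pp$feature_names),
              dimnames = list(data$sample_id, pp$feature_names))
  unseen <- character(0)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$dtype[i] == "numeric") {
      v <- as.numeric(data[[nm]])
      if (anyNA(v)) stop("numeric metric '", nm, "' has missing values")
      X[, nm] <- (v - pp$center[[nm]]) / pp$scale[[nm]]
    } else {
      lev <- pp$levels[[nm]]
      v <- as.character(data[[nm]])
      idx <- match(v, lev)
      new_lev <- unique(v[is.na(idx)])
      if (length(new_lev) > 0) unseen <- c(unseen, paste0(nm, "=", new_lev))
      seen <- which(!is.na(idx))
      cols <- match(paste0(nm, ".", lev), pp$feature_names)
      for (j in seq_along(lev)) {
        X[seen[idx[seen] == j], cols[j]] <- 1
      }
    }
  }
  if (length(unseen) > 0) {
    warning("unseen categorical level(s) mapped to all-zero indicators: ",
            paste(unique(unseen), collapse = ", "))
  }
  attr(X, "linac_idx") <- pp$linac_idx
  attr(X, "plan_idx") <- pp$plan_idx
  X
}

#' @exportS3Method base::print
print.gpr_preprocessor <- function(x, ...) {
  cat("GPR feature preprocessor:", length(x$center), "standardized numeric metrics,",
      length(x$levels), "one-hot categorical metrics ->",
      length(x$feature_names), "features\n")
  cat("  linac block:", length(x$linac_idx), "features; plan block:",
      length(x$plan_idx), "features\n")
  invisible(x)
}

#' Random 4:1 train/test split
#'
#' Draws `round(ratio * N)` training rows uniformly at random (the default
#' 0.8 ratio reproduces the 680/170 split of an 850-plan table).  With
#' `stratify_by`, rows are sampled proportionally within each level of the
#' named column (e.g. `"site"`).
#'
#' @param data Plan table.
#' @param ratio Training fraction, default `0.8` (a 4:1 split).
#' @param seed Integer seed; the same seed always yields the same membership.
#' @param stratify_by Optional column name for proportional stratification.
#' @return A list with elements `train` and `test` (disjoint data frames
#'   covering all rows).
#' @export
train_test_split <- function(data, ratio = 0.8, seed = 1, stratify_by = NULL) {
  n <- nrow(data)
  if (n < 5) stop("need at least 5 samples for a 4:1 split, got ", n)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  set.seed(seed)
  if (is.null(stratify_by)) {
    n_train <- round(ratio * n)
    train_idx <- sort(sample.int(n, n_train))
  } else {
    if (!stratify_by %in% names(data)) stop("no column '", stratify_by, "' to stratify by")
    groups <- split(seq_len(n), data[[stratify_by]])
    train_idx <- sort(unlist(lapply(groups, function(ix) {
      sample(ix, round(ratio * length(ix)))
    }), use.names = FALSE))
  }
  list(train = data[train_idx, , drop = FALSE],
       test = data[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Serialize / restore a fitted preprocessor
#'
#' The sidecar is plain JSON holding the schema, the frozen standardization
#' statistics and the one-hot level sets, so predict-time transforms are
#' reproducible across sessions.
#'
#' @param pp A `gpr_preprocessor`.
#' @param path JSON file path.
#' @return `write_preprocessor()`: `path`, invisibly;
#'   `read_preprocessor()`: the restored `gpr_preprocessor`.
#' @export
write_preprocessor <- function(pp, path) {
  payload <- list(
    format = "vmatqa_preprocessor_v1",
    schema = as.data.frame(pp$schema),
    center = as.list(pp$center),
    scale = as.list(pp$scale),
    levels = pp$levels
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "vmatqa_preprocessor_v1")) {
    stop("'", path, "' is not a vmatqa preprocessor sidecar")
  }
  schema <- metric_schema(payload$schema)
  pp <- list(
    schema = schema,
    center = unlist(payload$center),
    scale = unlist(payload$scale),
    levels = lapply(payload$levels, as.character),
    feature_names = NULL, feature_metric = NULL
  )
  # rebuild the feature layout from the schema + levels
  feature_names <- character(0)
  feature_metric <- character(0)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$dtype[i] == "numeric") {
      feature_names <- c(feature_names, nm)
      feature_metric <- c(feature_metric, nm)
    } else {
      lev <- pp$levels[[nm]]
      feature_names <- c(feature_names, paste0(nm, ".", lev))
      feature_metric <- c(feature_metric, rep(nm, length(lev)))
    }
  }
  pp$feature_names <- feature_names
  pp$feature_metric <- feature_metric
  metric_cat <- schema$category[match(feature_metric, schema$name)]
  pp$linac_idx <- which(metric_cat == "linac")
  pp$plan_idx <- which(metric_cat == "plan")
  structure(pp, class = "gpr_preprocessor")
}
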