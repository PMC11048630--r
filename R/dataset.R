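#' Validate one plan sample against a metric schema
#'
#' Produces a violation report rather than raising: hard problems (missing
#' metrics, non-finite numerics, percentages outside \[0,100\], GPRs outside
#' \[0,100\] or breaking the criterion ordering) are reported with severity
#' `"error"`; family-shape problems that real exported tables can violate
#' through rounding (cumulative families not nondecreasing in their
#' threshold, band sums above 100) are reported with severity `"warning"`.
#' An empty report means the sample is fully consistent.
#'
#' The GPR ordering constraint reflects the physics of gamma analysis: the
#' same plan measured under successively looser criteria can only pass more
#' points, so gpr(2/2) <= gpr(3/2) <= gpr(3/3).
#'
#' @param sample A named list or one-row data frame holding the metric values
#'   and optionally `gpr_2_2`, `gpr_3_2`, `gpr_3_3` (percent).
#' @param schema A `metric_schema`.
#' @return A data frame with columns `metric`, `rule`, `severity`, `message`
#'   (zero rows when the sample is valid).
#' @export
validate_sample <- function(sample, schema) {
  sample <- as.list(sample)
  bad <- list()
  note <- function(metric, rule, severity, message) {
    bad[[length(bad) + 1]] <<- data.frame(
      metric = metric, rule = rule, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (is.null(sample[[nm]]) || (length(sample[[nm]]) == 1 && is.na(sample[[nm]]) &&
                                  schema$dtype[i] == "numeric")) {
      note(nm, "missing_metric", "error", paste0("metric '", nm, "' is absent"))
      next
    }
    if (schema$dtype[i] == "numeric") {
      v <- suppressWarnings(as.numeric(sample[[nm]]))
      if (!is.finite(v)) {
        note(nm, "non_finite", "error", paste0("metric '", nm, "' is not finite"))
        next
      }
      if (schema$family[i] %in% c("cumulative_pct", "band_pct") && (v < 0 || v > 100)) {
        note(nm, "percent_range", "error",
             paste0("metric '", nm, "' = ", v, " outside [0, 100]"))
      }
    }
  }

  # cumulative families: nondecreasing in the threshold
  cum <- schema[schema$family == "cumulative_pct", , drop = FALSE]
  for (g in unique(cum$group)) {
    fam <- cum[cum$group == g, , drop = FALSE]
    fam <- fam[order(fam$order), , drop = FALSE]
    vals <- suppressWarnings(as.numeric(unlist(sample[fam$name])))
    if (length(vals) == nrow(fam) && all(is.finite(vals))) {
      if (any(diff(vals) < -1e-9)) {
        note(g, "cumulative_monotone", "warning",
             paste0("cumulative family '", g, "' not nondecreasing in its threshold"))
      }
    }
  }

  # band families: nonnegative with sum <= 100
  band <- schema[schema$family == "band_pct", , drop = FALSE]
  for (g in unique(band$group)) {
    fam <- band[band$group == g, , drop = FALSE]
    vals <- suppressWarnings(as.numeric(unlist(sample[fam$name])))
    if (length(vals) == nrow(fam) && all(is.finite(vals)) && sum(vals) > 100 + 1e-9) {
      note(g, "band_sum", "warning",
           paste0("band family '", g, "' percentages sum to ", round(sum(vals), 3),
                  " > 100"))
    }
  }

  # GPR columns: range and criterion ordering
  gcols <- gpr_columns()
  gvals <- vapply(gcols, function(cn) {
    v <- sample[[cn]]
    if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  for (k in seq_along(gcols)) {
    if (!is.na(gvals[k]) && (gvals[k] < 0 || gvals[k] > 100)) {
      note(gcols[k], "gpr_range", "error",
           paste0(gcols[k], " = ", gvals[k], " outside [0, 100]"))
    }
  }
  if (all(!is.na(gvals)) && any(diff(gvals) < -1e-9)) {
    note("gpr", "gpr_ordering", "error",
         "GPR ordering violated: require gpr_2_2 <= gpr_3_2 <= gpr_3_3")
  }

  if (length(bad) == 0) {
    data.frame(metric = character(), rule = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Validate every row of a plan table
#'
#' @param data A plan table (data frame with `sample_id` and metric columns).
#' @param schema A `metric_schema`.
#' @return A data frame of violations with a leading `sample_id` column
#'   (zero rows when the table is clean).
#' @export
validate_dataset <- function(data, schema) {
  if (!"sample_id" %in% names(data)) stop("plan table needs a 'sample_id' column")
  if (anyDuplicated(data$sample_id)) stop("sample_id values must be unique")
  reports <- lapply(seq_len(nrow(data)), function(i) {
    rep <- validate_sample(data[i, , drop = FALSE], schema)
    if (nrow(rep) > 0) cbind(sample_id = data$sample_id[i], rep) else NULL
  })
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) == 0) {
    data.frame(sample_id = character(), metric = character(), rule = character(),
               severity = character(), message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, reports)
  }
}

#' Split a sample's metric values into the Linac and plan blocks
#'
#' Partitions a sample's values by metric category, preserving schema order.
#' The two blocks are disjoint and together cover the full 47-metric vector;
#' with the default schema they have sizes 25 (linac) and 22 (plan).
#'
#' @param sample A named list or one-row data frame of metric values.
#' @param schema A `metric_schema`.
#' @return A list with elements `linac` and `plan`, each a named list of
#'   values in schema order.
#' @export
split_by_category <- function(sample, schema) {
  sample <- as.list(sample)
  metric_vals <- sample[names(sample) %in% schema$name]
  extra <- setdiff(names(sample),
                   c(schema$name, "sample_id", "site", gpr_columns()))
  if (length(extra) > 0) {
    stop("unknown metric column(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(schema$name, names(metric_vals))
  if (length(missing) > 0) {
    stop("sample is missing metric(s): ", paste(missing, collapse = ", "))
  }
  linac_names <- schema$name[schema$category == "linac"]
  plan_names <- schema$name[schema$category == "plan"]
  list(linac = metric_vals[linac_names], plan = metric_vals[plan_names])
}

#' Read / write a plan-complexity table
#'
#' The on-disk format is plain comma-delimited UTF-8 with a header row:
#' `sample_id`, `site`, the 47 metric names in schema order, then the
#' optional measured GPR columns `gpr_2_2`, `gpr_3_2`, `gpr_3_3` as
#' percentages.
#'
#' @param path CSV file path.
#' @param schema Schema used to type the columns (categorical metrics are
#'   read as character, numeric metrics as double).
#' @return `read_plan_table()`: a data frame; `write_plan_table()`: `path`,
#'   invisibly.
#' @export
read_plan_table <- function(path, schema = default_schema()) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(data)) stop("plan table needs a 'sample_id' column")
  data$sample_id <- as.character(data$sample_id)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(data)) next
    data[[nm]] <- if (schema$dtype[i] == "categorical") {
      as.character(data[[nm]])
    } else {
      as.numeric(data[[nm]])
    }
  }
  data
}

#' @rdname read_plan_table
#' @param data Plan table to write.
#' @export
write_plan_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
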