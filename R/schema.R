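#' Metric schema: the 47-metric complexity-table data model
#'
#' A `metric_schema` is an ordered table of metric definitions.  Each metric
#' has a `category` (`"linac"` for Linac-parameter metrics, `"plan"` for
#' plan-property metrics), a `dtype` (`"numeric"` or `"categorical"`), a unit,
#' and a `family` tag used by the validator and the synthetic generator:
#' `cumulative_pct` families (small-aperture scores `SAS<X>mm`, jaw-gap
#' fractions `jaw? gap 0-X mm`) are percentages nondecreasing in their
#' threshold `X`; `band_pct` families (leaf-gap bands) are nonnegative
#' percentages whose sum is at most 100; `scalar` metrics are unconstrained
#' positive quantities; `categorical` metrics are labels that are one-hot
#' encoded downstream.  Cumulative families carry a `group` id and an `order`
#' (the threshold in mm) so monotonicity can be checked positionally.
#'
#' @param defs A data frame with columns `name`, `category`, `dtype`, `unit`,
#'   `family`, and optionally `group` and `order`.
#' @return A validated `metric_schema` (a data frame).
#' @seealso [default_schema()], [load_schema()], [validate_sample()]
#' @export
metric_schema <- function(defs) {
  required <- c("name", "category", "dtype", "unit", "family")
  missing_cols <- setdiff(required, names(defs))
  if (length(missing_cols) > 0) {
    stop("schema is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  defs <- as.data.frame(defs, stringsAsFactors = FALSE)
  if (!"group" %in% names(defs)) defs$group <- NA_character_
  if (!"order" %in% names(defs)) defs$order <- NA_real_
  defs <- defs[, c("name", "category", "dtype", "unit", "family", "group", "order")]
  defs$order <- as.numeric(defs$order)

  if (any(!nzchar(defs$name)) || anyNA(defs$name)) {
    stop("schema error: metric names must be nonempty")
  }
  dup <- defs$name[duplicated(defs$name)]
  if (length(dup) > 0) {
    stop("schema error: duplicate metric name(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!all(defs$category %in% c("linac", "plan"))) {
    stop("schema error: unknown category (must be 'linac' or 'plan')")
  }
  if (!all(defs$dtype %in% c("numeric", "categorical"))) {
    stop("schema error: unknown dtype (must be 'numeric' or 'categorical')")
  }
  if (!all(defs$family %in% c("cumulative_pct", "band_pct", "scalar", "categorical"))) {
    stop("schema error: unknown family")
  }
  if (any(defs$dtype == "categorical" & defs$family != "categorical")) {
    stop("schema error: categorical dtype requires family 'categorical'")
  }
  cum <- defs$family == "cumulative_pct"
  if (any(cum & (is.na(defs$group) | is.na(defs$order)))) {
    stop("schema error: cumulative_pct metrics need 'group' and 'order'")
  }
  structure(defs, class = c("metric_schema", "data.frame"))
}

#' The bundled default 47-metric schema
#'
#' Reproduces the standard VMAT complexity-metric table: 25 Linac-parameter
#' metrics (six cumulative small-aperture scores, five leaf-gap band
#' percentages, two mean jaw gaps, and six cumulative jaw-gap fractions per
#' jaw) and 22 plan-property metrics (dose, control-point, monitor-unit,
#' geometry and modulation descriptors plus the `linac` and `doctor` labels).
#' The two categorical metrics are `linac` (which accelerator delivered the
#' plan) and `doctor` (treating physicist); all other metrics are numeric.
#'
#' @return A `metric_schema` with 47 rows: 25 `linac` + 22 `plan` metrics.
#' @examples
#' sch <- default_schema()
#' table(sch$category)
#' @export
default_schema <- function() {
  sas_mm <- c(2, 5, 10, 15, 20, 30)
  jaw_mm <- c(2, 5, 10, 15, 20, 30)
  band_lo <- c(2, 5, 10, 15, 20)
  band_hi <- c(5, 10, 15, 20, 30)

  linac_defs <- rbind(
    data.frame(name = paste0("SAS", sas_mm, "mm"), category = "linac",
               dtype = "numeric", unit = "percent", family = "cumulative_pct",
               group = "SAS", order = sas_mm),
    data.frame(name = paste0("leaf_gap_", band_lo, "_", band_hi, "mm"),
               category = "linac", dtype = "numeric", unit = "percent",
               family = "band_pct", group = "leaf_gap", order = band_lo),
    data.frame(name = c("mean_jawY_gap", "mean_jawX_gap"), category = "linac",
               dtype = "numeric", unit = "mm", family = "scalar",
               group = NA, order = NA),
    data.frame(name = paste0("jawY_gap_0_", jaw_mm, "mm"), category = "linac",
               dtype = "numeric", unit = "percent", family = "cumulative_pct",
               group = "jawY_gap", order = jaw_mm),
    data.frame(name = paste0("jawX_gap_0_", jaw_mm, "mm"), category = "linac",
               dtype = "numeric", unit = "percent", family = "cumulative_pct",
               group = "jawX_gap", order = jaw_mm)
  )

  plan_names <- c("fraction_dose", "mean_cp_number", "mean_cp_mu", "pmu",
                  "beam_number", "linac", "cas", "ciao", "mad", "pa", "pi",
                  "pm", "palg", "alt_x1", "alt_x2", "alg", "mcs", "doctor",
                  "positions", "mu1", "mu2", "tmu")
  plan_units <- c("Gy", "count", "MU", "MU", "count", "label",
                  "dimensionless", "cm2", "mm", "cm2", "dimensionless",
                  "dimensionless", "mm", "mm", "mm", "mm", "dimensionless",
                  "label", "code", "MU", "MU", "MU")
  plan_defs <- data.frame(
    name = plan_names, category = "plan",
    dtype = ifelse(plan_names %in% c("linac", "doctor"), "categorical", "numeric"),
    unit = plan_units,
    family = ifelse(plan_names %in% c("linac", "doctor"), "categorical", "scalar"),
    group = NA_character_, order = NA_real_
  )

  sch <- metric_schema(rbind(linac_defs, plan_defs))
  stopifnot(nrow(sch) == 47,
            sum(sch$category == "linac") == 25,
            sum(sch$category == "plan") == 22,
            sum(sch$dtype == "categorical") == 2)
  sch
}

#' Load a metric schema from YAML (or return the bundled default)
#'
#' The schema file is a YAML list of entries with fields `name`, `category`,
#' `dtype`, `unit`, `family`, and optionally `group` and `order`.  Users may
#' override which columns are categorical by editing the file.
#'
#' @param source Path to a YAML schema file, or `NULL` for the bundled
#'   default 47-metric schema.
#' @return A validated `metric_schema`.
#' @export
load_schema <- function(source = NULL) {
  if (is.null(source)) {
    return(default_schema())
  }
  entries <- yaml::read_yaml(source)
  if (!is.list(entries) || length(entries) == 0) {
    stop("schema error: '", source, "' does not contain a list of metric definitions")
  }
  defs <- do.call(rbind, lapply(entries, function(e) {
    data.frame(name = e$name, category = e$category, dtype = e$dtype,
               unit = if (is.null(e$unit)) "dimensionless" else e$unit,
               family = if (is.null(e$family)) "scalar" else e$family,
               group = if (is.null(e$group)) NA_character_ else e$group,
               order = if (is.null(e$order)) NA_real_ else as.numeric(e$order),
               stringsAsFactors = FALSE)
  }))
  metric_schema(defs)
}

#' Write a metric schema to YAML
#'
#' @param schema A `metric_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(name = schema$name[i], category = schema$category[i],
              dtype = schema$dtype[i], unit = schema$unit[i],
              family = schema$family[i])
    if (!is.na(schema$group[i])) e$group <- schema$group[i]
    if (!is.na(schema$order[i])) e$order <- schema$order[i]
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @exportS3Method base::print
print.metric_schema <- function(x, ...) {
  cat("Metric schema:", nrow(x), "metrics (",
      sum(x$category == "linac"), "linac,",
      sum(x$category == "plan"), "plan;",
      sum(x$dtype == "categorical"), "categorical )\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... and", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' Gamma criteria and their TG-218 style tolerance / action limits
#'
#' The three standard gamma criteria with the limits used for plan
#' classification: a plan passes when its GPR reaches the tolerance limit,
#' falls in the tolerance zone between the action and tolerance limits, and
#' requires intervention below the action limit.  The 3%/2 mm limits
#' (tolerance 95%, action 90%) follow TG-218; the 2%/2 mm and 3%/3 mm limits
#' are the matched clinical settings (90/84 and 97/93).
#'
#' @return A data frame with columns `criterion` (`"2_2"`, `"3_2"`, `"3_3"`),
#'   `dose_pct`, `dist_mm`, `tolerance_limit`, `action_limit` (all percent).
#' @export
gamma_criteria <- function() {
  data.frame(
    criterion = c("2_2", "3_2", "3_3"),
    dose_pct = c(2, 3, 3),
    dist_mm = c(2, 2, 3),
    tolerance_limit = c(90, 95, 97),
    action_limit = c(84, 90, 93),
    stringsAsFactors = FALSE
  )
}

gpr_columns <- function() c("gpr_2_2", "gpr_3_2", "gpr_3_3")

criterion_column <- function(criterion) {
  crit <- gamma_criteria()
  if (!criterion %in% crit$criterion) {
    stop("unknown gamma criterion '", criterion, "' (expected one of ",
         paste(crit$criterion, collapse = ", "), ")")
  }
  paste0("gpr_", criterion)
}
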