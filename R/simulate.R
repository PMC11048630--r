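#' Synthetic plan-table generator configuration
#'
#' The generator emulates the statistical structure the model assumes, with
#' a known ground truth so every pipeline stage is testable: two latent
#' per-plan complexity factors (a Linac aperture-complexity factor driving
#' the 25 Linac-parameter metrics and a plan modulation factor driving the
#' 22 plan-property metrics), a latent delivery difficulty combining them
#' with an interaction term and machine/site offsets, and GPR triples that
#' decrease smoothly with difficulty, confined to the observed clinical
#' ranges \[78.90, 100\] (2%/2 mm), \[89.00, 100\] (3%/2 mm),
#' \[91.10, 100\] (3%/3 mm) with the physical ordering
#' gpr(2/2) <= gpr(3/2) <= gpr(3/3).
#'
#' Cancer-site labels follow the empirical ten-site case mix of a large
#' single-institution VMAT QA cohort (850 plans: Abdomen 80, Brain 28,
#' Breast 4, H&N 117, Npc 127, Pelvis 162, Prostate 56, Rectum 186,
#' Stomach 42, Other 48), normalized to proportions.
#'
#' The latent difficulty of plan *n* is
#' `d_n = alpha * c_lm + beta * c_pm + gamma * c_lm * c_pm
#'        + machine_offset[linac] + site_offset[site]`,
#' with `c_lm`, `c_pm` standard normal.  The interaction `gamma` is nonzero
#' by default so that fusing the two metric categories carries structural
#' information that neither category holds alone; set it to 0 for null
#' experiments.  The noiseless GPR map is
#' `gpr = clip(100 - scale_k * softplus(d_n), range_k)` with per-criterion
#' scales proportional to the range widths, which preserves the criterion
#' ordering under clipping.
#'
#' @param n Number of plans (default 850).
#' @param seed Integer seed.
#' @param site_proportions Named site probabilities summing to 1.
#' @param site_offsets Named per-site additive offsets on the difficulty
#'   scale.
#' @param linac_levels,machine_offsets Accelerator labels (drawn uniformly)
#'   and their difficulty offsets.
#' @param doctor_levels Treating-physicist labels (drawn uniformly).
#' @param alpha,beta,gamma Effect sizes of the Linac composite, plan
#'   composite and their interaction.
#' @param metric_noise_sd Observation noise on the latent scale inside each
#'   generated metric.
#' @param gpr_scale GPR points lost per softplus unit of difficulty at
#'   2%/2 mm; the 3%/2 mm and 3%/3 mm scales are reduced proportionally to
#'   their range widths.
#' @param noise_sd Measurement noise sd of the recorded GPR labels, in GPR
#'   points (shared across the three criteria of a plan, as a common
#'   session effect, so the criterion ordering survives).
#' @param clip_ranges 3x2 matrix of per-criterion \[min, max\] label ranges.
#' @param corrupt_fraction Fraction of plans whose recorded labels carry an
#'   extra measurement-error offset (default 0; the audit experiments use
#'   63/850).
#' @param corrupt_offset The offset, in GPR points (default -8).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 850, seed = 1,
                             site_proportions = NULL,
                             site_offsets = NULL,
                             linac_levels = c("Linac1", "Linac2", "Linac3"),
                             machine_offsets = c(Linac1 = -0.2, Linac2 = 0,
                                                 Linac3 = 0.2),
                             doctor_levels = paste0("D0", 1:5),
                             alpha = 0.9, beta = 0.9, gamma = 0.6,
                             metric_noise_sd = 0.3,
                             gpr_scale = 4,
                             noise_sd = 1,
                             clip_ranges = rbind(`2_2` = c(78.90, 100.00),
                                                 `3_2` = c(89.00, 100.00),
                                                 `3_3` = c(91.10, 100.00)),
                             corrupt_fraction = 0,
                             corrupt_offset = -8) {
  if (is.null(site_proportions)) {
    counts <- c(Abdomen = 80, Brain = 28, Breast = 4, `H&N` = 117, Npc = 127,
                Pelvis = 162, Prostate = 56, Rectum = 186, Stomach = 42,
                Other = 48)
    site_proportions <- counts / sum(counts)
  }
  if (abs(sum(site_proportions) - 1) > 1e-8) {
    stop("site proportions must sum to 1")
  }
  if (is.null(site_offsets)) {
    site_offsets <- c(Abdomen = 0.10, Brain = -0.10, Breast = 0.00,
                      `H&N` = 0.20, Npc = 0.15, Pelvis = 0.05,
                      Prostate = -0.20, Rectum = 0.00, Stomach = -0.05,
                      Other = 0.00)
  }
  missing_off <- setdiff(names(site_proportions), names(site_offsets))
  if (length(missing_off) > 0) {
    site_offsets[missing_off] <- 0
  }
  if (noise_sd < 0 || metric_noise_sd < 0) stop("noise sds must be nonnegative")
  if (any(clip_ranges[, 1] >= clip_ranges[, 2])) stop("clip ranges must be ordered")
  if (corrupt_fraction < 0 || corrupt_fraction > 1) {
    stop("corrupt_fraction must be in [0, 1]")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 site_proportions = site_proportions, site_offsets = site_offsets,
                 linac_levels = linac_levels, machine_offsets = machine_offsets,
                 doctor_levels = doctor_levels,
                 alpha = alpha, beta = beta, gamma = gamma,
                 metric_noise_sd = metric_noise_sd, gpr_scale = gpr_scale,
                 noise_sd = noise_sd, clip_ranges = clip_ranges,
                 corrupt_fraction = corrupt_fraction,
                 corrupt_offset = corrupt_offset),
            class = "generator_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# a random nondecreasing cumulative profile ending at 1, one row per sample:
# gamma increments proportional to a base profile, normalized.
cumulative_profile <- function(n, base_increments) {
  k <- length(base_increments)
  inc <- matrix(rgamma(n * k, shape = 8 * rep(base_increments, each = n),
                       rate = 1), n, k)
  cum <- t(apply(inc, 1, cumsum))
  cum / cum[, k]
}

#' Draw synthetic plan-complexity metrics (no GPR labels)
#'
#' Generates `n` plans whose metrics respect every schema family constraint:
#' cumulative percentage families are nondecreasing in their threshold and
#' lie in \[0, 100\]; leaf-gap band percentages are nonnegative and sum to
#' at most 100; scalar metrics come from positive lognormal-type
#' distributions; `linac` and `doctor` are drawn from their label sets and
#' `site` from the configured proportions.  All generated rows pass
#' [validate_sample()] with zero violations.
#'
#' @param n Number of plans.
#' @param config A [generator_config()]; `config$seed` is used unless the
#'   caller has already seeded the stream (`use_seed = FALSE`).
#' @param use_seed Whether to seed the RNG from `config$seed` (default TRUE).
#' @return A plan table (data frame) with columns `sample_id`, `site` and
#'   the 47 metrics, carrying the latent factors as attribute `"latent"`
#'   (data frame: `sample_id`, `c_lm`, `c_pm`).
#' @export
sample_metrics <- function(n = config$n, config = generator_config(),
                           use_seed = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (use_seed) set.seed(config$seed)
  ns <- config$metric_noise_sd

  c_lm <- rnorm(n)
  c_pm <- rnorm(n)
  site <- sample(names(config$site_proportions), n, replace = TRUE,
                 prob = config$site_proportions)
  linac <- sample(config$linac_levels, n, replace = TRUE)
  doctor <- sample(config$doctor_levels, n, replace = TRUE)

  d <- data.frame(sample_id = sprintf("plan%04d", seq_len(n)), site = site,
                  stringsAsFactors = FALSE)

  # --- Linac-parameter metrics (driven by c_lm) ---
  sas_total <- 100 * plogis(-1.2 + 0.9 * c_lm + rnorm(n, 0, ns))
  sas_frac <- cumulative_profile(n, c(0.08, 0.17, 0.25, 0.20, 0.15, 0.15))
  sas_mm <- c(2, 5, 10, 15, 20, 30)
  for (j in seq_along(sas_mm)) {
    d[[paste0("SAS", sas_mm[j], "mm")]] <- sas_total * sas_frac[, j]
  }

  band_total <- 80 * plogis(0.2 + 0.5 * c_lm + rnorm(n, 0, ns))
  band_w <- matrix(rgamma(n * 5, shape = rep(c(2, 3, 3, 2, 1), each = n)), n, 5)
  band_w <- band_w / rowSums(band_w)
  band_names <- c("leaf_gap_2_5mm", "leaf_gap_5_10mm", "leaf_gap_10_15mm",
                  "leaf_gap_15_20mm", "leaf_gap_20_30mm")
  for (j in 1:5) d[[band_names[j]]] <- band_total * band_w[, j]

  d$mean_jawY_gap <- exp(log(45) - 0.25 * c_lm + rnorm(n, 0, ns / 2))
  d$mean_jawX_gap <- exp(log(55) - 0.25 * c_lm + rnorm(n, 0, ns / 2))

  jawY_total <- 100 * plogis(-1.5 + 0.8 * c_lm + rnorm(n, 0, ns))
  jawY_frac <- cumulative_profile(n, c(0.05, 0.10, 0.20, 0.20, 0.20, 0.25))
  jawX_total <- 100 * plogis(-1.8 + 0.8 * c_lm + rnorm(n, 0, ns))
  jawX_frac <- cumulative_profile(n, c(0.05, 0.10, 0.20, 0.20, 0.20, 0.25))
  for (j in seq_along(sas_mm)) {
    d[[paste0("jawY_gap_0_", sas_mm[j], "mm")]] <- jawY_total * jawY_frac[, j]
    d[[paste0("jawX_gap_0_", sas_mm[j], "mm")]] <- jawX_total * jawX_frac[, j]
  }

  # --- plan-property metrics (driven by c_pm) ---
  d$fraction_dose <- sample(c(1.8, 2.0, 2.2, 2.5, 3.0), n, replace = TRUE,
                            prob = c(0.15, 0.50, 0.15, 0.10, 0.10))
  d$mean_cp_number <- round(exp(log(80) + 0.15 * c_pm + rnorm(n, 0, ns / 3)))
  d$mean_cp_mu <- exp(log(6) + 0.20 * c_pm + rnorm(n, 0, ns / 2))
  d$pmu <- exp(log(500) + 0.25 * c_pm + rnorm(n, 0, ns / 2))
  d$beam_number <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  d$linac <- linac
  d$cas <- 100 * plogis(-0.5 + 0.6 * c_pm + rnorm(n, 0, ns))
  d$ciao <- exp(log(120) + 0.20 * c_pm + rnorm(n, 0, ns / 2))
  d$mad <- exp(log(18) + 0.25 * c_pm + rnorm(n, 0, ns / 2))
  d$pa <- exp(log(90) + 0.20 * c_pm + rnorm(n, 0, ns / 2))
  d$pi <- exp(log(1.5) + 0.30 * c_pm + rnorm(n, 0, ns / 2))
  d$pm <- exp(log(1.0) + 0.30 * c_pm + rnorm(n, 0, ns / 2))
  d$palg <- exp(log(20) - 0.25 * c_pm + rnorm(n, 0, ns / 2))
  d$alt_x1 <- exp(log(18) - 0.20 * c_pm + rnorm(n, 0, ns / 2))
  d$alt_x2 <- exp(log(22) - 0.20 * c_pm + rnorm(n, 0, ns / 2))
  d$alg <- (d$alt_x1 + d$alt_x2) / 2 * exp(rnorm(n, 0, ns / 6))
  d$mcs <- plogis(0.8 - 0.7 * c_pm + rnorm(n, 0, ns))
  d$doctor <- doctor
  d$positions <- sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  d$mu1 <- exp(log(250) + 0.30 * c_pm + rnorm(n, 0, ns / 2))
  d$mu2 <- exp(log(230) + 0.30 * c_pm + rnorm(n, 0, ns / 2))
  d$tmu <- d$mu1 + d$mu2

  # order columns: sample_id, site, schema order
  d <- d[, c("sample_id", "site", default_schema()$name)]
  attr(d, "latent") <- data.frame(sample_id = d$sample_id, c_lm = c_lm,
                                  c_pm = c_pm, stringsAsFactors = FALSE)
  d
}

latent_difficulty <- function(samples, latent, config) {
  config$alpha * latent$c_lm + config$beta * latent$c_pm +
    config$gamma * latent$c_lm * latent$c_pm +
    config$machine_offsets[samples$linac] +
    config$site_offsets[samples$site]
}

#' Noiseless ground-truth GPR triple for generated plans
#'
#' Maps latent difficulty `d_n` to the three criteria:
#' `gpr_k = clip(100 - scale_k * softplus(d_n), range_k)`, with scales
#' proportional to the criterion range widths so the looser criteria lose
#' GPR more slowly.  As `d_n -> -Inf` all three approach 100; as
#' `d_n -> +Inf` they reach the range floors (78.90, 89.00, 91.10).  The
#' construction guarantees `gpr_2_2 <= gpr_3_2 <= gpr_3_3` for every plan.
#'
#' @param samples A plan table from [sample_metrics()] (with its `"latent"`
#'   attribute), or any table whose latent factors are supplied via
#'   `latent`.
#' @param config A [generator_config()].
#' @param latent Optional latent data frame (`c_lm`, `c_pm`) overriding the
#'   attribute.
#' @return A data frame `sample_id`, `d`, `gpr_2_2`, `gpr_3_2`, `gpr_3_3`
#'   (noiseless, percent).
#' @export
true_gpr <- function(samples, config = generator_config(), latent = NULL) {
  if (is.null(latent)) latent <- attr(samples, "latent")
  if (is.null(latent)) stop("samples carry no latent factors; supply 'latent'")
  d <- latent_difficulty(samples, latent, config)
  rng <- config$clip_ranges
  widths <- rng[, 2] - rng[, 1]
  scales <- config$gpr_scale * widths / widths[1]
  sp <- softplus(d)
  out <- data.frame(sample_id = samples$sample_id, d = unname(d),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(rng))) {
    out[[paste0("gpr_", rownames(rng)[k])]] <-
      clip(100 - scales[k] * sp, rng[k, 1], rng[k, 2])
  }
  out
}

#' Generate a labelled synthetic plan table with ground-truth sidecar
#'
#' Labels are the noiseless ground truth plus Gaussian measurement noise
#' (one shared draw per plan across the three criteria), truncated to the
#' per-criterion ranges.  In measurement-error mode
#' (`corrupt_fraction > 0`), a random subset of plans additionally receives
#' `corrupt_offset` GPR points before truncation, emulating mismeasured QA
#' sessions; the corrupted ids are flagged in the sidecar, never in the
#' plan table itself.
#'
#' @param config A [generator_config()].
#' @return A list of class `gpr_simulation`: `data` (labelled plan table),
#'   `truth` (sidecar: `sample_id`, latent factors, difficulty `d`,
#'   noiseless GPRs, `corrupted` flag) and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  samples <- sample_metrics(config$n, config, use_seed = FALSE)
  truth <- true_gpr(samples, config)
  n <- config$n

  noise <- rnorm(n, 0, config$noise_sd)
  corrupted <- runif(n) < config$corrupt_fraction
  offset <- ifelse(corrupted, config$corrupt_offset, 0)
  rng <- config$clip_ranges
  for (k in seq_len(nrow(rng))) {
    col <- paste0("gpr_", rownames(rng)[k])
    samples[[col]] <- clip(truth[[col]] + noise + offset, rng[k, 1], rng[k, 2])
  }
  latent <- attr(samples, "latent")
  truth <- cbind(truth[, "sample_id", drop = FALSE],
                 c_lm = latent$c_lm, c_pm = latent$c_pm,
                 truth[, setdiff(names(truth), "sample_id")],
                 corrupted = corrupted)
  attr(samples, "latent") <- NULL
  structure(list(data = samples, truth = truth, config = config),
            class = "gpr_simulation")
}

#' @exportS3Method base::print
print.gpr_simulation <- function(x, ...) {
  cat("Synthetic VMAT QA dataset:", nrow(x$data), "plans,",
      sum(x$truth$corrupted), "with corrupted labels\n")
  cat("  gpr_2_2 range:", paste(round(range(x$data$gpr_2_2), 2), collapse = " - "),
      "; noise sd:", x$config$noise_sd, "GPR points\n")
  invisible(x)
}
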