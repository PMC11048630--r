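# shared fixtures: everything is generated in code at test time

# a small two-metric schema for preprocessing unit tests
tiny_schema <- function() {
  metric_schema(data.frame(
    name = c("a", "b", "cat"),
    category = c("linac", "plan", "plan"),
    dtype = c("numeric", "numeric", "categorical"),
    unit = c("mm", "MU", "label"),
    family = c("scalar", "scalar", "categorical"),
    stringsAsFactors = FALSE
  ))
}

# a reduced-width model configuration for fast training tests
small_config <- function(...) {
  mbnn_config(fm_widths = c(32, 64, 32), lm_widths = c(16, 32, 16),
              pm_widths = c(16, 32, 16), ...)
}

# parameters whose branch layers are all zero, so every head outputs
# plogis(bias) exactly: lets tests pin head outputs to chosen values
const_head_params <- function(n_fm, n_lm, n_pm, config, head_p) {
  params <- init_mbnn(n_fm, n_lm, n_pm, config, seed = 1)
  zero_branch <- function(layers) {
    lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  }
  for (br in c("fm", "lm", "pm")) params[[br]] <- zero_branch(params[[br]])
  for (k in names(head_p)) {
    nm <- paste0("head_", k)
    params[[nm]]$w <- 0 * params[[nm]]$w
    params[[nm]]$b <- stats::qlogis(head_p[[k]])
  }
  params
}

# a plan table whose labels are an exact (noise-free) linear function of two
# metrics, clipped well inside the sigmoid-reachable band
linear_plan_table <- function(n = 300, seed = 42) {
  sim <- sample_metrics(n, generator_config(n = n, seed = seed))
  z1 <- scale(sim$SAS10mm)[, 1]
  z2 <- scale(sim$mcs)[, 1]
  y <- pmin(pmax(94 - 2 * z1 + 1.5 * z2, 80), 99.5)
  sim$gpr_2_2 <- y
  sim$gpr_3_2 <- pmin(y + 2, 99.7)
  sim$gpr_3_3 <- pmin(y + 3, 99.9)
  attr(sim, "latent") <- NULL
  sim
}
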