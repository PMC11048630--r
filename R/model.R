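#' Multi-branch network configuration
#'
#' Defaults follow the reference architecture: FM-Net (full 47-metric input)
#' with hidden widths 128-512-128, LM-Net (25 Linac metrics) and PM-Net
#' (22 plan metrics) with 64-256-64; ReLU activations in the feature
#' extractors and sigmoid prediction heads; fusion weights
#' (w_fm, w_lm, w_pm, w_fuse) = (0.3, 0.15, 0.15, 0.4) summing to 1; loss
#' weights lambda1 = lambda2 = 0.5; dropout probability 0.6 on the last
#' hidden layer of each branch.
#'
#' @param fm_widths,lm_widths,pm_widths Hidden-layer widths per branch; the
#'   last width is the branch feature width.
#' @param fusion_weights Named nonnegative weights `fm`, `lm`, `pm`, `fuse`
#'   summing to 1, combining the four scalar head outputs into the final
#'   prediction.
#' @param lambda1,lambda2 Nonnegative weights of the LM and PM absolute-error
#'   loss terms.
#' @param dropout Dropout probability in \[0, 1) applied to the last hidden
#'   layer during training.
#' @param dropout_all_branches If `TRUE` (default) dropout is applied to the
#'   last hidden layer of every branch; if `FALSE`, to FM-Net only.
#' @param loss_on Which prediction the squared-error term scores: the fused
#'   final output (`"final"`, default) or the FM head (`"fm_head"`).
#' @param loss_scale Unit of the training loss relative to the sigmoid
#'   output: with the default 100, squared and absolute errors are computed
#'   in GPR percentage points (the unit in which GPRs, MAEs and the loss
#'   formulas are written), while the heads keep predicting fractions.
#' @return An `mbnn_config` list.
#' @export
mbnn_config <- function(fm_widths = c(128, 512, 128),
                        lm_widths = c(64, 256, 64),
                        pm_widths = c(64, 256, 64),
                        fusion_weights = c(fm = 0.3, lm = 0.15, pm = 0.15, fuse = 0.4),
                        lambda1 = 0.5, lambda2 = 0.5,
                        dropout = 0.6,
                        dropout_all_branches = TRUE,
                        loss_on = c("final", "fm_head"),
                        loss_scale = 100) {
  loss_on <- match.arg(loss_on)
  for (w in list(fm_widths, lm_widths, pm_widths)) {
    if (length(w) < 1 || any(w != round(w)) || any(w <= 0)) {
      stop("hidden widths must be positive integers")
    }
  }
  if (!all(c("fm", "lm", "pm", "fuse") %in% names(fusion_weights))) {
    stop("fusion_weights needs named entries fm, lm, pm, fuse")
  }
  fusion_weights <- fusion_weights[c("fm", "lm", "pm", "fuse")]
  if (any(fusion_weights < 0)) stop("fusion weights must be nonnegative")
  if (abs(sum(fusion_weights) - 1) > 1e-8) stop("fusion weights must sum to 1")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be nonnegative")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (loss_scale <= 0) stop("loss_scale must be positive")
  structure(list(
    fm_widths = as.integer(fm_widths),
    lm_widths = as.integer(lm_widths),
    pm_widths = as.integer(pm_widths),
    fusion_weights = fusion_weights,
    lambda1 = lambda1, lambda2 = lambda2,
    dropout = dropout,
    dropout_all_branches = dropout_all_branches,
    loss_on = loss_on,
    loss_scale = loss_scale
  ), class = "mbnn_config")
}

# uniform fan-in initialization of one dense layer (fan_in x fan_out)
init_layer <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
       b = runif(fan_out, -bound, bound))
}

init_branch <- function(n_in, widths) {
  fan_ins <- c(n_in, widths[-length(widths)])
  mapply(init_layer, fan_ins, widths, SIMPLIFY = FALSE)
}

init_head <- function(n_in) {
  l <- init_layer(n_in, 1L)
  list(w = drop(l$W), b = l$b)
}

#' Initialize the multi-branch network parameters
#'
#' Draws all weights and biases with uniform fan-in initialization,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, reproducibly under the given seed.
#' Which branches are materialised depends on `variant`: the full MBNN has
#' three feature extractors and four heads (fm, lm, pm, fuse on the
#' concatenated feature); a single-branch variant has one extractor and one
#' head.
#'
#' @param n_fm,n_lm,n_pm Post-encoding input widths of the full, Linac and
#'   plan feature blocks.
#' @param config An [mbnn_config()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param variant `"mbnn"` (default), `"fm"`, `"lm"` or `"pm"`.
#' @return An `mbnn_params` list of layer weights.
#' @export
init_mbnn <- function(n_fm, n_lm, n_pm, config = mbnn_config(), seed = NULL,
                      variant = c("mbnn", "fm", "lm", "pm")) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  params <- list(variant = variant)
  d_lm <- config$lm_widths[length(config$lm_widths)]
  d_pm <- config$pm_widths[length(config$pm_widths)]
  d_fm <- config$fm_widths[length(config$fm_widths)]
  if (variant %in% c("mbnn", "lm")) {
    params$lm <- init_branch(n_lm, config$lm_widths)
    params$head_lm <- init_head(d_lm)
  }
  if (variant %in% c("mbnn", "pm")) {
    params$pm <- init_branch(n_pm, config$pm_widths)
    params$head_pm <- init_head(d_pm)
  }
  if (variant %in% c("mbnn", "fm")) {
    params$fm <- init_branch(n_fm, config$fm_widths)
    params$head_fm <- init_head(d_fm)
  }
  if (variant == "mbnn") {
    params$head_fuse <- init_head(d_lm + d_pm + d_fm)
  }
  params$n_in <- c(fm = n_fm, lm = n_lm, pm = n_pm)
  structure(params, class = "mbnn_params")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# forward through one branch; returns activations for backprop.
# dropout (inverted) is applied to the last hidden layer in training mode,
# drawing the mask from the current RNG stream.
branch_forward <- function(X, layers, dropout = 0, training = FALSE) {
  L <- length(layers)
  A <- vector("list", L)
  Z <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(inp %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    A[[l]] <- relu(Z[[l]])
    inp <- A[[l]]
  }
  mask <- NULL
  out <- A[[L]]
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask <- matrix(runif(length(out)) < keep, nrow(out), ncol(out)) / keep
    out <- out * mask
  }
  list(X = X, Z = Z, A = A, mask = mask, out = out)
}

head_forward <- function(f, head) {
  z <- drop(f %*% head$w) + head$b
  list(z = z, p = plogis(z))
}

#' Forward pass of the multi-branch network
#'
#' LM-Net sees only the Linac feature block, PM-Net only the plan block, and
#' FM-Net the full vector.  The three branch features are concatenated (in
#' the order lm, pm, fm) into the fused feature; each of the four feature
#' vectors feeds a linear + sigmoid head, and the final prediction is the
#' convex combination of the four head outputs under the fusion weights.
#' Dropout is active only in training mode, so evaluation-mode forwards are
#' deterministic.
#'
#' @param X Feature matrix (samples x features) from [transform_features()],
#'   or any matrix with `linac_idx`/`plan_idx` attributes or supplied blocks.
#' @param params `mbnn_params` from [init_mbnn()] or training.
#' @param config The matching [mbnn_config()].
#' @param training Logical; enables dropout (used by the trainer).
#' @param linac_idx,plan_idx Optional explicit block indices (default: taken
#'   from `X`'s attributes).
#' @return A list: `features` (per-branch feature matrices and the fused
#'   concatenation), `heads` (per-head sigmoid outputs in (0,1)),
#'   `p_final` (fused prediction, fraction of 1), and forward caches.
#' @export
mbnn_forward <- function(X, params, config, training = FALSE,
                         linac_idx = attr(X, "linac_idx"),
                         plan_idx = attr(X, "plan_idx")) {
  variant <- params$variant
  X <- as.matrix(X)
  out <- list(variant = variant)
  drop_all <- config$dropout_all_branches
  p_drop <- config$dropout

  if (variant == "mbnn") {
    if (is.null(linac_idx) || is.null(plan_idx)) {
      stop("feature matrix lacks linac/plan block indices")
    }
    if (length(linac_idx) != params$n_in[["lm"]] ||
        length(plan_idx) != params$n_in[["pm"]] ||
        ncol(X) != params$n_in[["fm"]]) {
      stop("feature width mismatch: model expects (fm, lm, pm) inputs of ",
           paste(params$n_in, collapse = "/"), ", got ",
           paste(c(ncol(X), length(linac_idx), length(plan_idx)), collapse = "/"))
    }
    lm_fwd <- branch_forward(X[, linac_idx, drop = FALSE], params$lm,
                             if (drop_all) p_drop else 0, training)
    pm_fwd <- branch_forward(X[, plan_idx, drop = FALSE], params$pm,
                             if (drop_all) p_drop else 0, training)
    fm_fwd <- branch_forward(X, params$fm, p_drop, training)
    f_fuse <- cbind(lm_fwd$out, pm_fwd$out, fm_fwd$out)
    h_lm <- head_forward(lm_fwd$out, params$head_lm)
    h_pm <- head_forward(pm_fwd$out, params$head_pm)
    h_fm <- head_forward(fm_fwd$out, params$head_fm)
    h_fuse <- head_forward(f_fuse, params$head_fuse)
    w <- config$fusion_weights
    p_final <- w[["fm"]] * h_fm$p + w[["lm"]] * h_lm$p +
      w[["pm"]] * h_pm$p + w[["fuse"]] * h_fuse$p
    out$features <- list(lm = lm_fwd$out, pm = pm_fwd$out, fm = fm_fwd$out,
                         fuse = f_fuse)
    out$heads <- list(fm = h_fm$p, lm = h_lm$p, pm = h_pm$p, fuse = h_fuse$p)
    out$p_final <- p_final
    out$cache <- list(lm = lm_fwd, pm = pm_fwd, fm = fm_fwd,
                      h = list(fm = h_fm, lm = h_lm, pm = h_pm, fuse = h_fuse))
  } else {
    Xb <- switch(variant,
                 fm = X,
                 lm = if (ncol(X) == params$n_in[["lm"]]) X else {
                   if (is.null(linac_idx)) stop("feature matrix lacks linac block indices")
                   X[, linac_idx, drop = FALSE]
                 },
                 pm = if (ncol(X) == params$n_in[["pm"]]) X else {
                   if (is.null(plan_idx)) stop("feature matrix lacks plan block indices")
                   X[, plan_idx, drop = FALSE]
                 })
    if (ncol(Xb) != params$n_in[[variant]]) {
      stop("feature width mismatch for branch '", variant, "'")
    }
    fwd <- branch_forward(Xb, params[[variant]], p_drop, training)
    h <- head_forward(fwd$out, params[[paste0("head_", variant)]])
    out$features <- stats::setNames(list(fwd$out), variant)
    out$heads <- stats::setNames(list(h$p), variant)
    out$p_final <- h$p
    out$cache <- list(branch = fwd, h = h)
  }
  out
}

#' Composite training loss
#'
#' `l_fm` is the mean squared error of the final fused prediction (or of the
#' FM head when `loss_on = "fm_head"`); `l_lm` and `l_pm` are the mean
#' absolute errors of the LM and PM head outputs.  The total is
#' `L = l_fm + lambda1 * l_lm + lambda2 * l_pm`.  All predictions and
#' targets are fractions in \[0, 1\] (GPR percent / 100).
#'
#' @param pred A forward-pass result from [mbnn_forward()], or a list with
#'   elements `p_final`, and optionally `heads$lm`, `heads$pm`.
#' @param targets Numeric vector of target GPR fractions in \[0, 1\].
#' @param config An [mbnn_config()] supplying `lambda1`, `lambda2`, `loss_on`.
#' @return A list `l_fm`, `l_lm`, `l_pm`, `total` (all nonnegative).
#' @export
mbnn_loss <- function(pred, targets, config = mbnn_config()) {
  if (length(targets) == 0) stop("empty batch")
  if (length(pred$p_final) != length(targets)) {
    stop("predictions and targets have different lengths")
  }
  if (any(targets < 0 | targets > 1)) stop("targets must be fractions in [0, 1]")
  p_scored <- if (config$loss_on == "fm_head" && !is.null(pred$heads$fm)) {
    pred$heads$fm
  } else {
    pred$p_final
  }
  l_fm <- mean((targets - p_scored)^2)
  l_lm <- if (!is.null(pred$heads$lm)) mean(abs(targets - pred$heads$lm)) else 0
  l_pm <- if (!is.null(pred$heads$pm)) mean(abs(targets - pred$heads$pm)) else 0
  list(l_fm = l_fm, l_lm = l_lm, l_pm = l_pm,
       total = l_fm + config$lambda1 * l_lm + config$lambda2 * l_pm)
}

# gradients of the composite loss for one batch (full MBNN variant).
# The loss is computed in loss_scale units (percent for the default 100):
# the squared term picks up scale^2, the absolute terms scale^1.
# Returns a list mirroring the params structure.
mbnn_backward <- function(fwd, targets, params, config) {
  B <- length(targets)
  w <- config$fusion_weights
  s <- config$loss_scale
  h <- fwd$cache$h
  grads <- list()

  if (config$loss_on == "fm_head") {
    g_final <- numeric(B)
    g_fm_extra <- 2 * s^2 * (h$fm$p - targets) / B
  } else {
    g_final <- 2 * s^2 * (fwd$p_final - targets) / B
    g_fm_extra <- 0
  }
  g_p <- list(
    fm = w[["fm"]] * g_final + g_fm_extra,
    lm = w[["lm"]] * g_final + config$lambda1 * s * sign(h$lm$p - targets) / B,
    pm = w[["pm"]] * g_final + config$lambda2 * s * sign(h$pm$p - targets) / B,
    fuse = w[["fuse"]] * g_final
  )

  d_lm <- ncol(fwd$features$lm)
  d_pm <- ncol(fwd$features$pm)
  d_fm <- ncol(fwd$features$fm)

  g_f <- list()
  for (k in c("fm", "lm", "pm", "fuse")) {
    g_z <- g_p[[k]] * h[[k]]$p * (1 - h[[k]]$p)
    f_k <- if (k == "fuse") fwd$features$fuse else fwd$features[[k]]
    head_k <- params[[paste0("head_", k)]]
    grads[[paste0("head_", k)]] <- list(w = drop(crossprod(f_k, g_z)),
                                        b = sum(g_z))
    g_f[[k]] <- outer(g_z, head_k$w)
  }

  g_feat <- list(
    lm = g_f$lm + g_f$fuse[, seq_len(d_lm), drop = FALSE],
    pm = g_f$pm + g_f$fuse[, d_lm + seq_len(d_pm), drop = FALSE],
    fm = g_f$fm + g_f$fuse[, d_lm + d_pm + seq_len(d_fm), drop = FALSE]
  )
  for (br in c("lm", "pm", "fm")) {
    grads[[br]] <- branch_backward(fwd$cache[[br]], g_feat[[br]], params[[br]])
  }
  grads
}

# gradients for a single-branch variant: squared error on the head output,
# in loss_scale units
single_backward <- function(fwd, targets, params, config) {
  B <- length(targets)
  variant <- fwd$variant
  h <- fwd$cache$h
  g_p <- 2 * config$loss_scale^2 * (h$p - targets) / B
  g_z <- g_p * h$p * (1 - h$p)
  f <- fwd$cache$branch$out
  head <- params[[paste0("head_", variant)]]
  grads <- list()
  grads[[paste0("head_", variant)]] <- list(w = drop(crossprod(f, g_z)), b = sum(g_z))
  g_feat <- outer(g_z, head$w)
  grads[[variant]] <- branch_backward(fwd$cache$branch, g_feat, params[[variant]])
  grads
}

branch_backward <- function(cache, g_out, layers) {
  L <- length(layers)
  if (!is.null(cache$mask)) g_out <- g_out * cache$mask
  g <- vector("list", L)
  g_A <- g_out
  for (l in rev(seq_len(L))) {
    g_Z <- g_A * (cache$Z[[l]] > 0)
    A_prev <- if (l == 1) cache$X else cache$A[[l - 1]]
    g[[l]] <- list(W = crossprod(A_prev, g_Z), b = colSums(g_Z))
    if (l > 1) g_A <- tcrossprod(g_Z, layers[[l]]$W)
  }
  g
}

#' Predict GPR percentages
#'
#' Evaluation-mode forward pass (dropout off) returning `100 * p_final`,
#' guaranteed inside \[0, 100\] by the sigmoid heads and convex fusion.
#'
#' @param X Feature matrix from [transform_features()].
#' @param params,config Model parameters and configuration.
#' @return Numeric vector of predicted GPR percentages.
#' @export
predict_gpr <- function(X, params, config) {
  100 * mbnn_forward(X, params, config, training = FALSE)$p_final
}

#' @exportS3Method base::print
print.mbnn_config <- function(x, ...) {
  cat("MBNN configuration\n")
  cat("  FM-Net hidden widths:", paste(x$fm_widths, collapse = "-"), "\n")
  cat("  LM-Net hidden widths:", paste(x$lm_widths, collapse = "-"), "\n")
  cat("  PM-Net hidden widths:", paste(x$pm_widths, collapse = "-"), "\n")
  cat("  fusion weights (fm/lm/pm/fuse):",
      paste(x$fusion_weights, collapse = "/"), "\n")
  cat("  loss: l_fm(", x$loss_on, ") + ", x$lambda1, "*l_lm + ",
      x$lambda2, "*l_pm; dropout ", x$dropout, "\n", sep = "")
  invisible(x)
}
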