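#' Training configuration
#'
#' Defaults follow the reference training regime: 200 epochs of mini-batch
#' stochastic gradient descent, batch size 200, initial learning rate 1e-3
#' decayed by a factor 0.98 every five epochs, no momentum.  The incomplete
#' final batch of each epoch is used, not dropped.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Initial SGD learning rate (> 0).
#' @param lr_decay Multiplicative decay factor in (0, 1].
#' @param decay_every Epoch period of the decay (default 5).
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200, batch_size = 200, learning_rate = 1e-3,
                         lr_decay = 0.98, decay_every = 5, momentum = 0,
                         seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the stepwise schedule:
#' `rate = learning_rate * lr_decay ^ floor(epoch / decay_every)` with
#' 0-based epochs, so epochs 0-4 run at the initial rate, epochs 5-9 at
#' one decay step, and so on.  The sequence is nonincreasing and piecewise
#' constant with period `decay_every`.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$learning_rate * config$lr_decay^(epoch %/% config$decay_every)
}

sgd_update <- function(params, grads, velocity, lr, momentum) {
  apply_leaf <- function(p, g, v) {
    if (is.null(v)) v <- 0 * p
    v <- momentum * v - lr * g
    list(p = p + v, v = v)
  }
  for (nm in names(grads)) {
    if (startsWith(nm, "head_")) {
      for (fld in c("w", "b")) {
        up <- apply_leaf(params[[nm]][[fld]], grads[[nm]][[fld]],
                         velocity[[nm]][[fld]])
        params[[nm]][[fld]] <- up$p
        velocity[[nm]][[fld]] <- up$v
      }
    } else {
      if (is.null(velocity[[nm]])) {
        velocity[[nm]] <- vector("list", length(grads[[nm]]))
      }
      for (l in seq_along(grads[[nm]])) {
        for (fld in c("W", "b")) {
          up <- apply_leaf(params[[nm]][[l]][[fld]], grads[[nm]][[l]][[fld]],
                           velocity[[nm]][[l]][[fld]])
          params[[nm]][[l]][[fld]] <- up$p
          velocity[[nm]][[l]][[fld]] <- up$v
        }
      }
    }
  }
  list(params = params, velocity = velocity)
}

#' Train a multi-branch network by mini-batch SGD
#'
#' Runs exactly `train_config$epochs` epochs of mini-batch SGD on the
#' composite loss.  Each epoch reshuffles the training rows (seed-driven, so
#' batch composition is reproducible), walks consecutive batches including
#' the incomplete final one, and applies the stepwise learning-rate
#' schedule.  The parameters after the final epoch are returned (no
#' best-epoch selection).
#'
#' @param X Training feature matrix from [transform_features()].
#' @param y Target GPR fractions in \[0, 1\] (percent / 100).
#' @param config An [mbnn_config()].
#' @param tc A [train_config()]; its `seed` governs initialization,
#'   shuffling and dropout end to end.
#' @param variant `"mbnn"` (full model) or a single branch `"fm"`, `"lm"`,
#'   `"pm"` (that branch and its head only, squared-error loss on the head).
#' @param X_val,y_val Optional held-out features/fraction targets; when
#'   given, the per-epoch history records the held-out MAE in GPR percent.
#' @param init Optional pre-initialized `mbnn_params` (default: initialized
#'   from the seeded stream).
#' @return A list with `params` (trained `mbnn_params`), `config`, and
#'   `history` (one row per epoch: lr, loss components, optional val MAE).
#' @export
train_mbnn <- function(X, y, config = mbnn_config(), tc = train_config(),
                       variant = c("mbnn", "fm", "lm", "pm"),
                       X_val = NULL, y_val = NULL, init = NULL) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("empty training set")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (anyNA(y)) stop("training targets contain missing values (unlabeled samples)")
  if (any(y < 0 | y > 1)) stop("targets must be GPR fractions in [0, 1]")
  linac_idx <- attr(X, "linac_idx")
  plan_idx <- attr(X, "plan_idx")

  set.seed(tc$seed)
  params <- if (is.null(init)) {
    init_mbnn(ncol(X), length(linac_idx), length(plan_idx), config,
              seed = NULL, variant = variant)
  } else {
    init
  }

  velocity <- list()
  hist <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, tc)
    order_idx <- sample.int(n)
    starts <- seq(1, n, by = tc$batch_size)
    ep_loss <- c(l_fm = 0, l_lm = 0, l_pm = 0, total = 0)
    for (s in starts) {
      idx <- order_idx[s:min(s + tc$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- mbnn_forward(Xb, params, config, training = TRUE,
                          linac_idx = linac_idx, plan_idx = plan_idx)
      s <- config$loss_scale
      loss <- if (variant == "mbnn") {
        lf <- mbnn_loss(fwd, yb, config)
        # the optimized objective lives in loss_scale units (GPR points)
        list(l_fm = s^2 * lf$l_fm, l_lm = s * lf$l_lm, l_pm = s * lf$l_pm,
             total = s^2 * lf$l_fm + config$lambda1 * s * lf$l_lm +
               config$lambda2 * s * lf$l_pm)
      } else {
        l <- s^2 * mean((yb - fwd$p_final)^2)
        list(l_fm = l, l_lm = 0, l_pm = 0, total = l)
      }
      grads <- if (variant == "mbnn") {
        mbnn_backward(fwd, yb, params, config)
      } else {
        single_backward(fwd, yb, params, config)
      }
      up <- sgd_update(params, grads, velocity, lr, tc$momentum)
      # sgd_update strips the non-layer fields; restore them
      for (nm in names(up$params)) params[[nm]] <- up$params[[nm]]
      velocity <- up$velocity
      wgt <- length(idx) / n
      ep_loss <- ep_loss + wgt * unlist(loss)
    }
    row <- data.frame(epoch = epoch, lr = lr, l_fm = ep_loss[["l_fm"]],
                      l_lm = ep_loss[["l_lm"]], l_pm = ep_loss[["l_pm"]],
                      loss = ep_loss[["total"]])
    if (!is.null(X_val)) {
      pred_val <- 100 * mbnn_forward(X_val, params, config, training = FALSE,
                                     linac_idx = attr(X_val, "linac_idx"),
                                     plan_idx = attr(X_val, "plan_idx"))$p_final
      row$val_mae <- gpr_mae(100 * y_val, pred_val)
    }
    hist[[epoch + 1L]] <- row
  }
  list(params = params, config = config, history = do.call(rbind, hist))
}

#' Fit one model per gamma criterion
#'
#' Convenience wrapper over the full pipeline for a labelled plan table:
#' 4:1 train/test split, preprocessor fit on the training partition only,
#' MBNN training, and held-out evaluation.  One independent model is fit
#' per gamma criterion.
#'
#' @param data Labelled plan table containing the `gpr_<criterion>` column.
#' @param criterion `"2_2"`, `"3_2"` or `"3_3"`.
#' @param schema A `metric_schema` (default: bundled 47-metric schema).
#' @param config An [mbnn_config()].
#' @param tc A [train_config()].
#' @param split_seed Seed of the 4:1 split (default: `tc$seed`).
#' @param variant Model variant, as in [train_mbnn()].
#' @return An `mbnn_fit`: trained parameters, configs, preprocessor, split
#'   membership, per-epoch history (with held-out MAE) and `test_mae`.
#' @export
fit_criterion <- function(data, criterion, schema = default_schema(),
                          config = mbnn_config(), tc = train_config(),
                          split_seed = tc$seed,
                          variant = c("mbnn", "fm", "lm", "pm")) {
  variant <- match.arg(variant)
  col <- criterion_column(criterion)
  if (!col %in% names(data)) {
    stop("plan table has no measured column '", col, "'")
  }
  if (anyNA(data[[col]])) stop("column '", col, "' contains unlabeled samples")

  parts <- train_test_split(data, ratio = 0.8, seed = split_seed)
  pp <- fit_preprocessor(parts$train, schema)
  X_train <- transform_features(pp, parts$train)
  X_test <- transform_features(pp, parts$test)
  y_train <- parts$train[[col]] / 100
  y_test <- parts$test[[col]] / 100

  fitted <- train_mbnn(X_train, y_train, config = config, tc = tc,
                       variant = variant, X_val = X_test, y_val = y_test)
  pred_test <- 100 * mbnn_forward(X_test, fitted$params, config,
                                  training = FALSE)$p_final
  structure(list(
    params = fitted$params,
    config = config,
    train_config = tc,
    preprocessor = pp,
    criterion = criterion,
    history = fitted$history,
    split = list(train_ids = parts$train$sample_id,
                 test_ids = parts$test$sample_id,
                 seed = split_seed),
    variant = variant,
    test_mae = gpr_mae(parts$test[[col]], pred_test)
  ), class = "mbnn_fit")
}

#' Predict GPR percentages from a fitted model
#'
#' @param object An `mbnn_fit` from [fit_criterion()].
#' @param newdata A plan table with the 47 metric columns.
#' @param ... Unused.
#' @return Named numeric vector of predicted GPR percentages (names =
#'   `sample_id`).
#' @export
predict.mbnn_fit <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) stop("empty plan table")
  X <- transform_features(object$preprocessor, newdata)
  p <- predict_gpr(X, object$params, object$config)
  stats::setNames(p, newdata$sample_id)
}

#' @exportS3Method base::print
print.mbnn_fit <- function(x, ...) {
  cat("MBNN fit (variant '", x$variant, "') for gamma criterion ",
      gsub("_", "%/", x$criterion), " mm\n", sep = "")
  cat("  train/test:", length(x$split$train_ids), "/", length(x$split$test_ids),
      "samples; epochs:", nrow(x$history), "\n")
  cat("  held-out MAE:", round(x$test_mae, 3), "GPR points\n")
  invisible(x)
}
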