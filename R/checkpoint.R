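#' Save / restore a fitted model checkpoint
#'
#' A checkpoint is a single versioned JSON file holding the model
#' configuration, the learned weights, the frozen preprocessor, the
#' training configuration and the split seeds, so predictions can be
#' reproduced in a fresh session.
#'
#' @param fit An `mbnn_fit` from [fit_criterion()].
#' @param path JSON file path.
#' @return `write_checkpoint()`: `path`, invisibly; `read_checkpoint()`: the
#'   restored `mbnn_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  ser_branch <- function(layers) {
    lapply(layers, function(l) list(W = l$W, b = l$b))
  }
  params <- fit$params
  payload <- list(
    format = "vmatqa_checkpoint_v1",
    criterion = fit$criterion,
    variant = fit$variant,
    config = {
      cfg <- unclass(fit$config)
      cfg$fusion_weights <- as.list(cfg$fusion_weights)  # keep names in JSON
      cfg
    },
    train_config = unclass(fit$train_config),
    split = fit$split,
    test_mae = fit$test_mae,
    n_in = as.list(params$n_in),
    branches = {
      br <- list()
      for (nm in intersect(c("fm", "lm", "pm"), names(params))) {
        br[[nm]] <- ser_branch(params[[nm]])
      }
      br
    },
    heads = {
      hd <- list()
      for (nm in grep("^head_", names(params), value = TRUE)) {
        hd[[sub("^head_", "", nm)]] <- list(w = params[[nm]]$w, b = params[[nm]]$b)
      }
      hd
    },
    preprocessor = list(
      schema = as.data.frame(fit$preprocessor$schema),
      center = as.list(fit$preprocessor$center),
      scale = as.list(fit$preprocessor$scale),
      levels = fit$preprocessor$levels
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "vmatqa_checkpoint_v1")) {
    stop("'", path, "' is not a vmatqa checkpoint")
  }
  cfg <- payload$config
  config <- mbnn_config(fm_widths = cfg$fm_widths, lm_widths = cfg$lm_widths,
                        pm_widths = cfg$pm_widths,
                        fusion_weights = unlist(cfg$fusion_weights),
                        lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                        dropout = cfg$dropout,
                        dropout_all_branches = cfg$dropout_all_branches,
                        loss_on = cfg$loss_on, loss_scale = cfg$loss_scale)
  tc <- payload$train_config
  tcfg <- train_config(epochs = tc$epochs, batch_size = tc$batch_size,
                       learning_rate = tc$learning_rate, lr_decay = tc$lr_decay,
                       decay_every = tc$decay_every, momentum = tc$momentum,
                       seed = tc$seed)
  params <- list(variant = payload$variant)
  for (nm in names(payload$branches)) {
    br <- payload$branches[[nm]]
    params[[nm]] <- if (is.data.frame(br)) {
      # simplifyVector collapses the layer list into a W/b data frame
      lapply(seq_len(nrow(br)), function(i) {
        list(W = as.matrix(br$W[[i]]), b = as.numeric(br$b[[i]]))
      })
    } else {
      lapply(br, function(l) list(W = as.matrix(l$W), b = as.numeric(l$b)))
    }
  }
  for (nm in names(payload$heads)) {
    params[[paste0("head_", nm)]] <- list(w = as.numeric(payload$heads[[nm]]$w),
                                          b = as.numeric(payload$heads[[nm]]$b))
  }
  params$n_in <- unlist(payload$n_in)
  class(params) <- "mbnn_params"

  # rebuild the preprocessor through its own serializer logic
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(c(list(format = "vmatqa_preprocessor_v1"),
                         payload$preprocessor),
                       tmp, auto_unbox = TRUE, digits = NA, null = "null")
  pp <- read_preprocessor(tmp)

  structure(list(
    params = params, config = config, train_config = tcfg,
    preprocessor = pp, criterion = payload$criterion,
    history = NULL,
    split = payload$split, variant = payload$variant,
    test_mae = payload$test_mae
  ), class = "mbnn_fit")
}
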