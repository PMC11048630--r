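#' Parse a hidden-width grid string
#'
#' `"128-512-128"` denotes three hidden layers of those widths.
#'
#' @param grid A dash-separated string of positive integers.
#' @return Integer vector of widths.
#' @export
parse_widths <- function(grid) {
  parts <- strsplit(grid, "-", fixed = TRUE)[[1]]
  widths <- suppressWarnings(as.integer(parts))
  if (length(widths) == 0 || anyNA(widths) || any(widths <= 0)) {
    stop("malformed width grid '", grid, "'")
  }
  widths
}

default_width_grids <- function() {
  c("128-512-1024-512-128", "128-1024-256-64", "128-512-128", "128-1024-128",
    "64-256-64", "32-128-32", "512-64", "256-64")
}

# shared scaffold: split once per seed, preprocess on train, return blocks
ablation_split <- function(data, schema, seed) {
  parts <- train_test_split(data, ratio = 0.8, seed = seed)
  pp <- fit_preprocessor(parts$train, schema)
  list(parts = parts, pp = pp,
       X_train = transform_features(pp, parts$train),
       X_test = transform_features(pp, parts$test))
}

#' Branch ablation: full MBNN vs single-branch networks
#'
#' Trains the full multi-branch model and each single-branch variant
#' (FM-only on all metrics, LM-only on the 25 Linac metrics, PM-only on the
#' 22 plan metrics) with identical seeds, splits and preprocessing, and
#' reports the held-out MAE per criterion.  Because the synthetic ground
#' truth contains an interaction between the two metric categories, the
#' fused model has a structural advantage the single branches cannot
#' express.
#'
#' @param data Labelled plan table.
#' @param schema A `metric_schema`.
#' @param config An [mbnn_config()] (branch widths shared across variants).
#' @param tc A [train_config()]; its seed is overridden per run.
#' @param seeds Integer vector of seeds (one independent split + training
#'   per seed).
#' @param criteria Gamma criteria to evaluate (default all three).
#' @return A tidy data frame: `variant`, `criterion`, `seed`, `mae`.
#' @export
run_branch_ablation <- function(data, schema = default_schema(),
                                config = mbnn_config(), tc = train_config(),
                                seeds = 1:5,
                                criteria = c("2_2", "3_2", "3_3")) {
  variants <- c("mbnn", "fm", "lm", "pm")
  rows <- list()
  for (seed in seeds) {
    sc <- ablation_split(data, schema, seed)
    for (criterion in criteria) {
      col <- criterion_column(criterion)
      y_train <- sc$parts$train[[col]] / 100
      y_test <- sc$parts$test[[col]]
      for (variant in variants) {
        tc_run <- tc
        tc_run$seed <- as.integer(seed)
        fitted <- train_mbnn(sc$X_train, y_train, config = config, tc = tc_run,
                             variant = variant)
        pred <- 100 * mbnn_forward(sc$X_test, fitted$params, config,
                                   training = FALSE)$p_final
        rows[[length(rows) + 1]] <- data.frame(
          variant = variant, criterion = criterion, seed = seed,
          mae = gpr_mae(y_test, pred), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Hidden-width ablation on the full-metrics branch
#'
#' Evaluates FM-Net alone under a grid of hidden-layer settings (the default
#' grid spans two to five hidden layers, e.g. `"128-512-128"`), with
#' identical splits and preprocessing per seed.
#'
#' @inheritParams run_branch_ablation
#' @param grids Character vector of dash-separated width settings.
#' @param criterion Single gamma criterion (default `"2_2"`).
#' @return A tidy data frame: `grid`, `criterion`, `seed`, `mae`.
#' @export
run_width_ablation <- function(data, schema = default_schema(),
                               grids = default_width_grids(),
                               tc = train_config(), seeds = 1,
                               criterion = "2_2") {
  widths_list <- lapply(grids, parse_widths)
  col <- criterion_column(criterion)
  rows <- list()
  for (seed in seeds) {
    sc <- ablation_split(data, schema, seed)
    y_train <- sc$parts$train[[col]] / 100
    y_test <- sc$parts$test[[col]]
    for (g in seq_along(grids)) {
      cfg <- mbnn_config(fm_widths = widths_list[[g]])
      tc_run <- tc
      tc_run$seed <- as.integer(seed)
      fitted <- train_mbnn(sc$X_train, y_train, config = cfg, tc = tc_run,
                           variant = "fm")
      pred <- 100 * mbnn_forward(sc$X_test, fitted$params, cfg,
                                 training = FALSE)$p_final
      rows[[length(rows) + 1]] <- data.frame(
        grid = grids[g], criterion = criterion, seed = seed,
        mae = gpr_mae(y_test, pred), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classical-regressor baselines on the shared feature matrix
#'
#' Fits SVM (radial kernel), random forest, k-nearest-neighbour and lasso
#' regressors on exactly the features and splits the MBNN sees, plus the
#' MBNN itself, and reports held-out MAE per criterion.  Baseline
#' hyperparameters are the library defaults (lasso's penalty chosen by
#' cross-validation on the training partition); all stochastic steps run
#' under the per-run seed.
#'
#' @inheritParams run_branch_ablation
#' @param methods Subset of `c("mbnn", "svm", "rf", "knn", "lasso")`.
#' @return A tidy data frame: `method`, `criterion`, `seed`, `mae`.
#' @export
run_baselines <- function(data, schema = default_schema(),
                          config = mbnn_config(), tc = train_config(),
                          seeds = 1, criteria = c("2_2", "3_2", "3_3"),
                          methods = c("mbnn", "svm", "rf", "knn", "lasso")) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    sc <- ablation_split(data, schema, seed)
    X_train <- sc$X_train
    X_test <- sc$X_test
    for (criterion in criteria) {
      col <- criterion_column(criterion)
      y_train <- sc$parts$train[[col]]
      y_test <- sc$parts$test[[col]]
      for (method in methods) {
        set.seed(seed)
        pred <- switch(method,
          mbnn = {
            tc_run <- tc
            tc_run$seed <- as.integer(seed)
            fitted <- train_mbnn(X_train, y_train / 100, config = config,
                                 tc = tc_run, variant = "mbnn")
            100 * mbnn_forward(X_test, fitted$params, config,
                               training = FALSE)$p_final
          },
          svm = {
            m <- e1071::svm(x = X_train, y = y_train)
            as.numeric(predict(m, X_test))
          },
          rf = {
            m <- randomForest::randomForest(x = X_train, y = y_train)
            as.numeric(predict(m, X_test))
          },
          knn = {
            m <- caret::knnreg(X_train, y_train)
            as.numeric(predict(m, X_test))
          },
          lasso = {
            cv <- glmnet::cv.glmnet(X_train, y_train, alpha = 1)
            as.numeric(predict(cv, X_test, s = "lambda.min"))
          })
        rows[[length(rows) + 1]] <- data.frame(
          method = method, criterion = criterion, seed = seed,
          mae = gpr_mae(y_test, pred), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
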