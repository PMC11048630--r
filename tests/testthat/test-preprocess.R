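make_tiny_table <- function() {
  data.frame(sample_id = c("s1", "s2"), site = "Other",
             a = c(1, 3), b = c(10, 10), cat = c("L1", "L2"),
             stringsAsFactors = FALSE)
}

test_that("standardization uses training statistics with population sd", {
  sch <- tiny_schema()
  train <- make_tiny_table()
  expect_warning(pp <- fit_preprocessor(train, sch), "constant")  # b is constant
  expect_equal(pp$center[["a"]], 2)
  expect_equal(pp$scale[["a"]], 1)  # population sd of (1, 3)
  expect_equal(pp$scale[["b"]], 1)  # zero-variance guard

  X <- transform_features(pp, train)
  expect_equal(unname(X[, "a"]), c(-1, 1))
  expect_equal(unname(X[, "b"]), c(0, 0))
  # z-score identity: a value equal to its training mean maps to 0
  at_mean <- train
  at_mean$a <- c(2, 2)
  expect_equal(unname(transform_features(pp, at_mean)[, "a"]), c(0, 0))
  # numeric round trip
  expect_equal(unname(X[, "a"] * pp$scale[["a"]] + pp$center[["a"]]), train$a)
})

test_that("one-hot encoding width equals training levels; unseen maps to zeros", {
  sch <- tiny_schema()
  train <- data.frame(sample_id = paste0("s", 1:3), site = "Other",
                      a = c(1, 2, 3), b = c(1, 2, 3),
                      cat = c("L1", "L2", "L3"), stringsAsFactors = FALSE)
  pp <- fit_preprocessor(train, sch)
  expect_equal(sum(startsWith(pp$feature_names, "cat.")), 3)
  X <- transform_features(pp, train)
  expect_equal(unname(rowSums(X[, startsWith(colnames(X), "cat.")])), rep(1, 3))

  new <- train[1, ]
  new$cat <- "L9"
  expect_warning(Xn <- transform_features(pp, new), "unseen")
  expect_equal(unname(Xn[, startsWith(colnames(Xn), "cat.")]), c(0, 0, 0))
})

test_that("feature blocks partition the encoded columns by category", {
  sim <- generate_dataset(generator_config(n = 60, seed = 4))
  pp <- fit_preprocessor(sim$data, default_schema())
  expect_length(intersect(pp$linac_idx, pp$plan_idx), 0)
  expect_equal(sort(c(pp$linac_idx, pp$plan_idx)),
               seq_along(pp$feature_names))
  expect_length(pp$linac_idx, 25)  # no categorical metrics in the linac block

  X <- transform_features(pp, sim$data)
  num_cols <- names(pp$center)
  expect_true(all(abs(colMeans(X[, num_cols])) < 1e-9))
  pop_sd <- apply(X[, num_cols], 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_true(all(abs(pop_sd - 1) < 1e-9))
})

test_that("4:1 split arithmetic, determinism and partition property hold", {
  big <- data.frame(sample_id = sprintf("p%03d", 1:850), x = rnorm(850))
  parts <- train_test_split(big, seed = 9)
  expect_equal(nrow(parts$train), 680)
  expect_equal(nrow(parts$test), 170)
  expect_length(intersect(parts$train$sample_id, parts$test$sample_id), 0)
  expect_setequal(c(parts$train$sample_id, parts$test$sample_id), big$sample_id)

  again <- train_test_split(big, seed = 9)
  expect_identical(parts$train$sample_id, again$train$sample_id)

  tiny <- big[1:5, ]
  parts5 <- train_test_split(tiny, seed = 1)
  expect_equal(c(nrow(parts5$train), nrow(parts5$test)), c(4, 1))
  expect_error(train_test_split(big[1:4, ], seed = 1), "at least 5")
})

test_that("stratified split keeps per-group proportions", {
  d <- data.frame(sample_id = sprintf("p%03d", 1:100),
                  site = rep(c("A", "B"), c(60, 40)))
  parts <- train_test_split(d, seed = 2, stratify_by = "site")
  expect_equal(sum(parts$train$site == "A"), 48)
  expect_equal(sum(parts$train$site == "B"), 32)
})

test_that("preprocessor sidecar round-trips through JSON", {
  sim <- generate_dataset(generator_config(n = 40, seed = 5))
  pp <- fit_preprocessor(sim$data, default_schema())
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocessor(pp, path)
  back <- read_preprocessor(path)
  expect_equal(back$center, pp$center)
  expect_equal(back$scale, pp$scale)
  expect_identical(back$feature_names, pp$feature_names)
  expect_equal(transform_features(back, sim$data),
               transform_features(pp, sim$data))
})

test_that("fitting on an empty table errors", {
  expect_error(fit_preprocessor(make_tiny_table()[0, ], tiny_schema()), "empty")
})
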