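# independent brute-force oracle for the mean absolute error
mae_oracle <- function(y, p) {
  total <- 0
  for (i in seq_along(y)) total <- total + abs(y[i] - p[i])
  total / length(y)
}

test_that("MAE matches hand cases and the loop oracle", {
  expect_equal(gpr_mae(c(90, 95), c(92, 94)), 1.5)
  expect_equal(gpr_mae(c(93, 97), c(93, 97)), 0)
  set.seed(20)
  for (rep in 1:25) {
    y <- runif(40, 78, 100)
    p <- runif(40, 78, 100)
    expect_equal(gpr_mae(y, p), mae_oracle(y, p), tolerance = 1e-12)
    expect_identical(gpr_mae(y, p), gpr_mae(p, y))  # symmetry of |y - p|
  }
  expect_error(gpr_mae(numeric(0), numeric(0)), "empty")
  expect_error(gpr_mae(1:3, 1:2), "equal length")
})

test_that("limit classification follows the tolerance/action thresholds", {
  expect_equal(classify_limit(91, "2_2"), "pass")
  expect_equal(classify_limit(85, "2_2"), "tolerance_zone")
  expect_equal(classify_limit(83, "2_2"), "action")
  expect_equal(classify_limit(89, "3_2"), "action")
  expect_equal(classify_limit(95, "3_2"), "pass")
  expect_equal(classify_limit(96, "3_3"), "tolerance_zone")

  # monotone: raising the GPR never moves the class toward "action"
  rank <- c(action = 1, tolerance_zone = 2, pass = 3)
  for (crit in gamma_criteria()$criterion) {
    cls <- rank[classify_limit(seq(50, 100, by = 0.5), crit)]
    expect_true(all(diff(cls) >= 0))
  }
  expect_error(classify_limit(104, "2_2"), "outside")
  expect_error(classify_limit(90, "4_4"), "unknown")
})

test_that("error bands use strict inner thresholds and count exhaustively", {
  expect_equal(unname(error_bands(c(90, 90, 90), c(90, 90, 90))), c(3, 3, 0))
  eb <- error_bands(c(90, 90, 90), c(92, 94, 96))  # errors 2, 4, 6
  expect_equal(unname(eb), c(1, 2, 1))
  expect_named(eb, c("lt3", "lt5", "ge5"))
  # an error of exactly 5 falls in the flagged band
  exact5 <- error_bands(90, 95)
  expect_equal(unname(exact5), c(0, 0, 1))
  set.seed(21)
  y <- runif(100, 80, 100); p <- runif(100, 80, 100)
  eb2 <- error_bands(y, p)
  expect_equal(unname(eb2[["lt5"]] + eb2[["ge5"]]), 100)
})

test_that("anomaly flagging respects the deviation threshold and partitions", {
  none <- flag_anomalies(paste0("p", 1:3), c(90, 92, 94), c(91, 90, 95))
  expect_equal(nrow(none), 0)

  rep <- flag_anomalies(paste0("p", 1:3), c(95, 90, 88), c(87, 93, 94),
                        partition = c("train", "test", "train"))
  # deviations -8, 3, 6 -> two flags
  expect_equal(nrow(rep), 2)
  expect_equal(rep$sample_id, c("p1", "p3"))
  expect_equal(rep$deviation, c(-8, 6))
  expect_equal(rep$partition, c("train", "train"))
  expect_true(all(abs(rep$deviation) > attr(rep, "threshold")))
})

test_that("relabelling replaces exactly the requested rows", {
  tbl <- linear_plan_table(n = 20, seed = 30)
  fix <- data.frame(sample_id = tbl$sample_id[c(3, 7)], gpr_2_2 = c(95, 96))
  out <- apply_relabels(tbl, fix)
  expect_equal(out$gpr_2_2[c(3, 7)], c(95, 96))
  expect_equal(out$gpr_2_2[-c(3, 7)], tbl$gpr_2_2[-c(3, 7)])
  expect_error(apply_relabels(tbl, data.frame(sample_id = "nope", gpr_2_2 = 1)),
               "unknown sample_id")
})

test_that("width grids parse and malformed grids error", {
  expect_equal(parse_widths("128-512-128"), c(128L, 512L, 128L))
  expect_equal(parse_widths("512-64"), c(512L, 64L))
  expect_error(parse_widths("128--512"), "malformed")
  expect_error(parse_widths("128-abc"), "malformed")
  expect_length(vmatqa:::default_width_grids(), 8)
})

test_that("ablation and baseline harnesses emit the expected report shapes", {
  tbl <- linear_plan_table(n = 100, seed = 31)
  cfg <- small_config()
  tc <- train_config(epochs = 5, batch_size = 40, seed = 1)

  br <- run_branch_ablation(tbl, config = cfg, tc = tc, seeds = 1,
                            criteria = "2_2")
  expect_equal(nrow(br), 4)
  expect_setequal(br$variant, c("mbnn", "fm", "lm", "pm"))

  wd <- run_width_ablation(tbl, grids = c("16-32-16", "8-16"), tc = tc,
                           seeds = 1)
  expect_equal(nrow(wd), 2)
  expect_true(all(wd$mae >= 0))

  # harnesses are seed-reproducible end to end
  br2 <- run_branch_ablation(tbl, config = cfg, tc = tc, seeds = 1,
                             criteria = "2_2")
  expect_equal(br, br2)
})

test_that("classical baselines share the feature pipeline; lasso nails a linear target", {
  tbl <- linear_plan_table(n = 150, seed = 32)
  bl <- run_baselines(tbl, seeds = 1, criteria = "2_2",
                      methods = c("svm", "rf", "knn", "lasso"))
  expect_equal(nrow(bl), 4)
  expect_true(all(bl$mae >= 0))
  # the labels are an exact linear function of two standardized metrics
  expect_lt(bl$mae[bl$method == "lasso"], 0.2)
})

test_that("fit evaluation reports MAE, bands and limit tallies coherently", {
  tbl <- linear_plan_table(n = 100, seed = 33)
  fit <- fit_criterion(tbl, "2_2", config = small_config(),
                       tc = train_config(epochs = 30, batch_size = 40, seed = 2))
  ev <- evaluate_fit(fit, tbl)
  expect_equal(ev$n, 100)
  expect_equal(unname(ev$bands[["lt5"]] + ev$bands[["ge5"]]), 100)
  expect_equal(sum(ev$limits), 100)
  expect_equal(ev$mae, mean(ev$predictions$abs_error))
})
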