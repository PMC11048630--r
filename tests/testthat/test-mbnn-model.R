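test_that("initialization is seed-reproducible with the declared shapes", {
  cfg <- mbnn_config()
  p1 <- init_mbnn(47, 25, 22, cfg, seed = 11)
  p2 <- init_mbnn(47, 25, 22, cfg, seed = 11)
  expect_identical(p1, p2)
  p3 <- init_mbnn(47, 25, 22, cfg, seed = 12)
  expect_false(identical(p1$fm[[1]]$W, p3$fm[[1]]$W))

  expect_equal(dim(p1$fm[[1]]$W), c(47, 128))
  expect_equal(dim(p1$fm[[2]]$W), c(128, 512))
  expect_equal(dim(p1$fm[[3]]$W), c(512, 128))
  expect_equal(dim(p1$lm[[1]]$W), c(25, 64))
  expect_length(p1$head_fuse$w, 64 + 64 + 128)
})

test_that("branch parameter counts match the closed-form layer arithmetic", {
  cfg <- mbnn_config()
  params <- init_mbnn(47, 25, 22, cfg, seed = 3)
  count_branch <- function(layers) {
    sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
  }
  closed_form <- function(n_in, widths) {
    fan_in <- c(n_in, widths[-length(widths)])
    sum(fan_in * widths + widths)
  }
  expect_equal(count_branch(params$fm), closed_form(47, c(128, 512, 128)))
  expect_equal(count_branch(params$lm), closed_form(25, c(64, 256, 64)))
  expect_equal(count_branch(params$pm), closed_form(22, c(64, 256, 64)))
})

test_that("fusion combines the four head outputs with the convex weights", {
  cfg <- mbnn_config()
  params <- const_head_params(10, 6, 4, cfg,
                              list(fm = 0.9, lm = 0.8, pm = 0.8, fuse = 0.9))
  X <- matrix(rnorm(30), 3, 10)
  fwd <- mbnn_forward(X, params, cfg, linac_idx = 1:6, plan_idx = 7:10)
  expect_equal(unname(fwd$heads$fm), rep(0.9, 3))
  expect_equal(unname(fwd$p_final),
               rep(0.3 * 0.9 + 0.15 * 0.8 + 0.15 * 0.8 + 0.4 * 0.9, 3))
  expect_equal(unname(fwd$p_final), rep(0.87, 3))

  # all heads equal -> the convex combination is that value
  ones <- const_head_params(10, 6, 4, cfg,
                            list(fm = 0.999, lm = 0.999, pm = 0.999, fuse = 0.999))
  fwd1 <- mbnn_forward(X, ones, cfg, linac_idx = 1:6, plan_idx = 7:10)
  expect_equal(unname(fwd1$p_final), rep(0.999, 3))
})

test_that("head outputs are sigmoid-bounded and fusion is convex", {
  cfg <- small_config()
  set.seed(8)
  params <- init_mbnn(20, 12, 8, cfg, seed = 8)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 5, sd = 3), 5, 20)
    fwd <- mbnn_forward(X, params, cfg, linac_idx = 1:12, plan_idx = 13:20)
    for (h in fwd$heads) expect_true(all(h > 0 & h < 1))
    hmat <- do.call(cbind, fwd$heads)
    expect_true(all(fwd$p_final >= apply(hmat, 1, min) - 1e-12))
    expect_true(all(fwd$p_final <= apply(hmat, 1, max) + 1e-12))
  }
})

test_that("branches are isolated: each sees only its own feature block", {
  cfg <- small_config()
  params <- init_mbnn(20, 12, 8, cfg, seed = 5)
  X <- matrix(rnorm(20), 1, 20)
  base <- mbnn_forward(X, params, cfg, linac_idx = 1:12, plan_idx = 13:20)

  X_plan <- X
  X_plan[, 15] <- X_plan[, 15] + 10  # perturb a plan-block feature
  fwd <- mbnn_forward(X_plan, params, cfg, linac_idx = 1:12, plan_idx = 13:20)
  expect_identical(fwd$features$lm, base$features$lm)
  expect_identical(fwd$heads$lm, base$heads$lm)
  expect_false(identical(fwd$features$pm, base$features$pm))

  X_linac <- X
  X_linac[, 3] <- X_linac[, 3] - 10  # perturb a linac-block feature
  fwd2 <- mbnn_forward(X_linac, params, cfg, linac_idx = 1:12, plan_idx = 13:20)
  expect_identical(fwd2$features$pm, base$features$pm)
  expect_identical(fwd2$heads$pm, base$heads$pm)
})

test_that("evaluation-mode forwards are bit-identical; dropout only in training", {
  cfg <- small_config()  # dropout 0.6 by default
  params <- init_mbnn(20, 12, 8, cfg, seed = 6)
  X <- matrix(rnorm(100), 5, 20)
  a <- mbnn_forward(X, params, cfg, linac_idx = 1:12, plan_idx = 13:20)
  b <- mbnn_forward(X, params, cfg, linac_idx = 1:12, plan_idx = 13:20)
  expect_identical(a$p_final, b$p_final)

  set.seed(1)
  t1 <- mbnn_forward(X, params, cfg, training = TRUE, linac_idx = 1:12,
                     plan_idx = 13:20)
  set.seed(2)
  t2 <- mbnn_forward(X, params, cfg, training = TRUE, linac_idx = 1:12,
                     plan_idx = 13:20)
  expect_false(identical(t1$p_final, t2$p_final))  # different dropout masks
  set.seed(1)
  t1b <- mbnn_forward(X, params, cfg, training = TRUE, linac_idx = 1:12,
                      plan_idx = 13:20)
  expect_identical(t1$p_final, t1b$p_final)  # same mask under the same seed
})

test_that("composite loss reproduces hand-computed cases and decomposes", {
  cfg <- mbnn_config()
  # single sample: y = 0.9, p_final = 1.0, p_lm = 0.8, p_pm = 0.9
  pred <- list(p_final = 1.0, heads = list(lm = 0.8, pm = 0.9))
  loss <- mbnn_loss(pred, 0.9, cfg)
  expect_equal(loss$l_fm, 0.01)
  expect_equal(loss$l_lm, 0.1)
  expect_equal(loss$l_pm, 0)
  expect_equal(loss$total, 0.06)

  # exact predictions at every head give zero loss
  exact <- list(p_final = c(0.9, 0.95), heads = list(lm = c(0.9, 0.95),
                                                     pm = c(0.9, 0.95)))
  expect_equal(mbnn_loss(exact, c(0.9, 0.95), cfg)$total, 0)

  # degenerate weighting collapses to the squared term
  cfg0 <- mbnn_config(lambda1 = 0, lambda2 = 0)
  l0 <- mbnn_loss(pred, 0.9, cfg0)
  expect_equal(l0$total, l0$l_fm)

  # decomposition identity on random values
  set.seed(10)
  rnd <- list(p_final = runif(20), heads = list(lm = runif(20), pm = runif(20)))
  y <- runif(20)
  lr <- mbnn_loss(rnd, y, cfg)
  expect_equal(lr$total, lr$l_fm + cfg$lambda1 * lr$l_lm + cfg$lambda2 * lr$l_pm)

  expect_error(mbnn_loss(rnd, numeric(0), cfg), "empty")
  expect_error(mbnn_loss(rnd, y[1:3], cfg), "length")
})

test_that("predicted GPRs are percentages in [0, 100], batch-consistent", {
  cfg <- small_config()
  params <- init_mbnn(20, 12, 8, cfg, seed = 9)
  X <- matrix(rnorm(20 * 7, sd = 5), 7, 20)
  attr(X, "linac_idx") <- 1:12
  attr(X, "plan_idx") <- 13:20
  p <- predict_gpr(X, params, cfg)
  expect_true(all(p >= 0 & p <= 100))
  single <- vapply(1:7, function(i) {
    Xi <- X[i, , drop = FALSE]
    attr(Xi, "linac_idx") <- 1:12
    attr(Xi, "plan_idx") <- 13:20
    predict_gpr(Xi, params, cfg)
  }, numeric(1))
  expect_equal(unname(p), unname(single))

  expect_error(mbnn_forward(X[, 1:10], params, cfg, linac_idx = 1:5,
                            plan_idx = 6:10), "width mismatch")
})
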