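test_that("bundled schema has the expected shape and stable order", {
  sch <- default_schema()
  expect_equal(nrow(sch), 47)
  expect_equal(sum(sch$category == "linac"), 25)
  expect_equal(sum(sch$category == "plan"), 22)
  expect_equal(sum(sch$dtype == "categorical"), 2)
  expect_setequal(sch$name[sch$dtype == "categorical"], c("linac", "doctor"))
  # order is stable: linac block first, SAS family leading
  expect_equal(sch$name[1:2], c("SAS2mm", "SAS5mm"))
  expect_identical(sch$name, default_schema()$name)
  expect_identical(load_schema(NULL)$name, sch$name)
})

test_that("schema files round-trip through YAML and invalid schemas error", {
  sch <- default_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  back <- load_schema(path)
  expect_equal(as.data.frame(back), as.data.frame(sch))

  dup <- as.data.frame(sch)
  dup$name[2] <- dup$name[1]
  expect_error(metric_schema(dup), "duplicate")
  bad <- as.data.frame(sch)
  bad$category[1] <- "machine"
  expect_error(metric_schema(bad), "category")
  badcat <- as.data.frame(sch)
  badcat$family[badcat$name == "doctor"] <- "scalar"
  expect_error(metric_schema(badcat), "categorical")
})

test_that("sample validation reports family, range and ordering problems", {
  sch <- default_schema()
  good <- generate_dataset(generator_config(n = 3, seed = 1))$data

  expect_equal(nrow(validate_sample(good[1, ], sch)), 0)

  shrink <- good[1, ]
  shrink$SAS2mm <- 10
  shrink$SAS5mm <- 5
  rep <- validate_sample(shrink, sch)
  expect_true("cumulative_monotone" %in% rep$rule)
  expect_equal(rep$severity[rep$rule == "cumulative_monotone"], "warning")

  disorder <- good[1, ]
  disorder$gpr_2_2 <- 95
  disorder$gpr_3_2 <- 93
  rep <- validate_sample(disorder, sch)
  expect_true("gpr_ordering" %in% rep$rule)

  out_of_range <- good[1, ]
  out_of_range$gpr_3_3 <- 104
  expect_true("gpr_range" %in% validate_sample(out_of_range, sch)$rule)

  gone <- good[1, ]
  gone$mcs <- NA_real_
  expect_true("missing_metric" %in% validate_sample(gone, sch)$rule)

  oversum <- good[1, ]
  oversum$leaf_gap_2_5mm <- 90
  oversum$leaf_gap_5_10mm <- 40
  expect_true("band_sum" %in% validate_sample(oversum, sch)$rule)
})

test_that("category split partitions the 47 metrics into 25 + 22", {
  sch <- default_schema()
  samp <- generate_dataset(generator_config(n = 1, seed = 2))$data[1, ]
  parts <- split_by_category(samp, sch)
  expect_length(parts$linac, 25)
  expect_length(parts$plan, 22)
  expect_length(intersect(names(parts$linac), names(parts$plan)), 0)
  # concatenating the two parts in schema order restores the full row
  expect_identical(c(names(parts$linac), names(parts$plan)),
                   c(sch$name[sch$category == "linac"],
                     sch$name[sch$category == "plan"]))
  expect_setequal(c(names(parts$linac), names(parts$plan)), sch$name)

  samp$foo <- 1
  expect_error(split_by_category(samp, sch), "unknown metric")
})

test_that("plan tables round-trip through CSV", {
  sim <- generate_dataset(generator_config(n = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plan_table(sim$data, path)
  back <- read_plan_table(path)
  expect_identical(back$sample_id, sim$data$sample_id)
  expect_identical(back$linac, sim$data$linac)
  for (col in c("SAS2mm", "mcs", "tmu", "gpr_2_2", "gpr_3_3")) {
    expect_equal(back[[col]], sim$data[[col]], tolerance = 1e-10)
  }
})

test_that("gamma criteria carry ordered tolerance and action limits", {
  crit <- gamma_criteria()
  expect_equal(crit$tolerance_limit, c(90, 95, 97))
  expect_equal(crit$action_limit, c(84, 90, 93))
  expect_true(all(crit$action_limit < crit$tolerance_limit))
})
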