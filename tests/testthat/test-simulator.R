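test_that("gamma parameterization has the stated means", {
  # shape * scale = (sigma/m) * (m^2/sigma) = m for the infection draw
  set.seed(71)
  m <- 2e-4; sigma_m <- m / 0.09
  mu <- rgamma(2e4, shape = sigma_m / m, scale = m^2 / sigma_m)
  expect_equal(mean(mu), m, tolerance = 0.02)

  # simulator mean chain: E[x] ~ X * m
  ng <- 1L
  spec <- sim_spec(master_fractions = 0.001, gene_of_guide = "A", phi = 0,
                   depth_initial = 3e5, depth_final = 3e5,
                   n_replicates = 1e4)
  sim <- simulate_screen(spec, seed = 72)
  se <- sd(as.numeric(sim$x)) / sqrt(length(sim$x))
  expect_lt(abs(mean(sim$x) - 300), 3 * se)
})

test_that("fully efficient knockout of a lethal gene leaves zero reads", {
  spec <- sim_spec(master_fractions = rep(0.25, 4),
                   gene_of_guide = c("A", "A", "B", "B"),
                   phi = c(A = 1, B = 0), epsilon = 1, n_replicates = 3)
  sim <- simulate_screen(spec, seed = 73)
  expect_true(all(sim$y[1:2, ] == 0L))
  expect_true(all(sim$y[3:4, ] > 0L))
})

test_that("simulation is reproducible and seed-sensitive", {
  spec <- sim_spec(rep(0.1, 10), paste0("g", rep(1:5, each = 2)), phi = 0.3)
  a <- simulate_screen(spec, seed = 99)
  b <- simulate_screen(spec, seed = 99)
  c <- simulate_screen(spec, seed = 100)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, c$y))
})

test_that("zero master fractions give zero counts with a warning", {
  spec <- sim_spec(c(0.5, 0), c("A", "B"), phi = 0, n_replicates = 2)
  expect_warning(sim <- simulate_screen(spec, seed = 1), "zero master")
  expect_true(all(sim$x[2, ] == 0L & sim$y[2, ] == 0L))
})

test_that("master sampling preserves the template distribution", {
  expect_equal(sample_master(rep(7, 20), 5, seed = 1), rep(0.2, 5))
  tpl <- synthetic_master_template(5000, seed = 2)
  fr <- sample_master(tpl, 1e4, seed = 3)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  ks <- suppressWarnings(
    ks.test(log(fr / mean(fr)), log(tpl / sum(tpl) / mean(tpl / sum(tpl)))))
  expect_lt(unname(ks$statistic), 0.05)
  expect_error(sample_master(numeric(0), 5), "empty")
  expect_error(sample_master(1:3, 5, replace = FALSE), "fewer")
})

test_that("benchmark layouts reproduce the published designs", {
  bm <- build_benchmark("absolute", scale = 1, seed = 1)
  expect_equal(nrow(bm$truth), 5250L)
  expect_equal(sum(bm$truth$phi == 0), 3150L)
  expect_equal(sum(bm$truth$phi == 0.99), 600L)
  expect_equal(sum(bm$truth$is_control), 300L)
  expect_equal(nrow(bm$dataset$y), 5250L * 4L)
  expect_equal(ncol(bm$dataset$y), 3L)

  bd <- build_benchmark("differential", level = 0.6, scale = 1, seed = 1)
  expect_equal(nrow(bd$truth), 300L + 300L + 300L + 3150L)
  expect_equal(sum(bd$truth$class == "differential"), 300L)
  expect_equal(sum(bd$truth$is_null_control), 900L)
  expect_equal(ncol(bd$dataset$y), 6L)
  expect_equal(bd$dataset$panels, rep(c("test", "control"), each = 3))
  td <- bd$truth[bd$truth$class == "differential", ]
  expect_true(all(td$phi_test == 0.6 & td$phi_control == 0))

  bs <- build_benchmark("absolute", scale = 0.1, seed = 1)
  expect_equal(sum(bs$truth$phi == 0), 315L)
  expect_equal(sum(bs$truth$phi == 0.99), 60L)
  expect_error(build_benchmark("absolute", scale = 2), "scale")
  expect_error(build_benchmark("absolute", levels = c(0.5, 1.2)), "levels")
})

test_that("summary statistics and dispersion fitting behave", {
  # identical replicates: all variation statistics collapse to zero
  x <- matrix(rep(c(100L, 200L, 300L), 2), 3, 2)
  st <- screen_summary_stats(x, x)
  expect_equal(unname(st["cv_x"]), 0)
  expect_equal(unname(st["lr_var"]), 0)
  expect_error(screen_summary_stats(x[, 1, drop = FALSE], x[, 1, drop = FALSE]),
               ">= 2 replicates")
  expect_error(fit_template_dispersions(x[, 1, drop = FALSE],
                                        x[, 1, drop = FALSE], rep(1 / 3, 3)),
               "single replicate")
})
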