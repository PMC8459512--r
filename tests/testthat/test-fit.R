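test_that("a gene with exactly proportional counts fits phi ~ 0", {
  # y = x and equal scaling: no depletion signal at all
  x <- matrix(c(200L, 180L, 220L, 190L), 2, 2)
  ds <- screen_dataset(y = x, x = x, gene_of_guide = c("A", "A"),
                       master = c(0.4, 0.4), cells = 500,
                       guide_ids = c("sg1", "sg2"))
  lib <- guide_library(c("sg1", "sg2"), c("A", "A"), gc = c(0.4, 0.6))
  fit <- suppressWarnings(
    fit_essentiality(ds, lib, config = fit_config(update_omega = FALSE)))
  expect_lt(abs(fit$results$phi_hat), 1e-3)
  expect_lt(fit$results$llr, 1e-3)
})

test_that("the coordinate ascent recovers essentiality on a simulated screen", {
  sc <- small_screen()
  fit <- small_fit()
  r <- fit$results[match(sc$genes, fit$results$gene), ]
  expect_lte(abs(median(r$phi_hat[1:40])), 0.05)            # true phi = 0
  expect_lt(abs(median(r$phi_hat[41:50]) - 0.5), 0.1)       # true phi = 0.5
  expect_lt(abs(median(r$phi_hat[51:60]) - 0.99), 0.05)     # true phi = 0.99
  # strong essentiality separates cleanly from nonessential genes
  expect_gte(rank_auc(r$llr[51:60], r$llr[1:40]), 0.95)
})

test_that("nesting and ascent invariants hold on the fitted model", {
  fit <- small_fit()
  expect_true(all(fit$results$llr >= 0))
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_true(all(fit$results$p_empirical >= 0 & fit$results$p_empirical <= 1))
  # T = full - null by construction
  expect_equal(fit$results$llr,
               pmax(fit$results$loglik_full - fit$results$loglik_null, 0))
})

test_that("absolute LLR agrees between fit results and the public helper", {
  sc <- small_screen()
  fit <- small_fit()
  st <- fit$state
  names(st$phi) <- fit$results$gene
  ds <- sc$dataset
  ds$master <- fit$master
  g <- sc$genes[55]
  t_direct <- absolute_llr(ds, g, st, fit$config$opts)
  t_fit <- fit$results$llr[fit$results$gene == g]
  expect_equal(t_direct, t_fit, tolerance = 1e-6)
})

test_that("differential test is null on symmetric panels and gated one-sided", {
  # identical count tables in both panels
  ng <- 8L
  genes <- paste0("g", 1:ng)
  gog <- rep(genes, each = 2)
  set.seed(41)
  half <- matrix(rpois(ng * 2 * 2, 150), ng * 2, 2)
  y <- cbind(half, half)
  x <- y
  gids <- paste0("sg", 1:(2 * ng))
  ds <- screen_dataset(y = y, x = x, gene_of_guide = gog,
                       master = rep(1 / (2 * ng), 2 * ng), cells = 4000,
                       guide_ids = gids,
                       panels = c("test", "test", "control", "control"))
  lib <- guide_library(gids, gog, gc = runif(2 * ng))
  fit <- suppressWarnings(
    fit_essentiality(ds, lib, config = fit_config(update_omega = FALSE)))
  d <- differential_essentiality(fit)
  expect_true(all(abs(d$phi_test - d$phi_control) < 0.02))
  expect_true(all(d$llr < 0.01))
  expect_true(all(d$llr >= 0))
})

test_that("one-sided gate zeroes the statistic when control is more essential", {
  ng <- 10L; gpg <- 3L
  genes <- paste0("g", 1:ng)
  gog <- rep(genes, each = gpg)
  m <- rep(1 / (ng * gpg), ng * gpg)
  # four genes essential only in the CONTROL panel; six nonessential genes
  # anchor the scaling factors
  phi_c <- stats::setNames(c(rep(0.99, 4), rep(0, 6)), genes)
  spec <- sim_spec(m, gog, phi = phi_c,
                   phi_test = stats::setNames(rep(0, ng), genes),
                   n_replicates = 2)
  sim <- simulate_screen(spec, seed = 8)
  ds <- screen_dataset(y = sim$y, x = sim$x, gene_of_guide = gog,
                       cells = 250 * ng * gpg, panels = sim$panels)
  set.seed(9)
  lib <- guide_library(rownames(sim$y), gog, gc = runif(ng * gpg))
  fit <- suppressWarnings(
    fit_essentiality(ds, lib, negative_controls = genes[5:10],
                     config = fit_config(update_omega = FALSE)))
  d1 <- suppressWarnings(differential_essentiality(fit, one_sided = FALSE))
  expect_true(all(d1$llr[1:4] > 10))       # huge two-sided signal
  d2 <- suppressWarnings(differential_essentiality(fit, one_sided = TRUE))
  expect_true(all(d2$llr[1:4] == 0))       # zeroed: wrong direction
})

test_that("the differential test demands panel labels", {
  fit <- small_fit()   # fitted on a dataset without panels
  expect_error(differential_essentiality(fit), "panel")
})

test_that("empirical p-values follow the add-one and plug-in conventions", {
  null <- 1:99
  expect_equal(empirical_pvalues(100, null), 0.01)
  expect_equal(empirical_pvalues(100, null, method = "plugin"), 0)
  expect_equal(empirical_pvalues(50, null), 0.51)   # >= ties: 50..99
  # monotone nonincreasing in the statistic
  p <- empirical_pvalues(c(5, 50, 98, 1000), null)
  expect_true(all(diff(p) <= 0))
  expect_error(empirical_pvalues(1, numeric(0)), "empty")
  expect_warning(empirical_pvalues(1, 1:5), "coarse")

  # self-application is near-uniform
  set.seed(51)
  nulls <- rchisq(300, df = 1)
  ps <- empirical_pvalues(nulls, nulls)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(adjust_pvalues(0.001, n = 10), 0.01)
  expect_equal(adjust_pvalues(0.5, n = 10), 1)
  p <- c(0.001, 0.02, 0.9)
  expect_equal(adjust_pvalues(p), pmin(1, p * 3))
  expect_error(adjust_pvalues(1.2), "\\[0, 1\\]")
})

test_that("per-GC-bin efficiencies are recovered from pooled guides", {
  # two GC clusters with efficiencies 0.95 and 0.5; essential genes carry
  # the signal, nonessential genes anchor the normalization
  ng <- 50L; gpg <- 6L
  genes <- paste0("g", 1:ng)
  gog <- rep(genes, each = gpg)
  n_guides <- ng * gpg
  set.seed(61)
  gc <- ifelse(seq_len(n_guides) %% 2 == 0, runif(n_guides, 0.25, 0.35),
               runif(n_guides, 0.65, 0.75))
  eps_true <- ifelse(gc < 0.5, 0.95, 0.5)
  phi <- stats::setNames(c(rep(0.8, 25), rep(0, 25)), genes)
  m <- rep(1 / n_guides, n_guides)
  sim <- simulate_screen(sim_spec(m, gog, phi = phi, epsilon = eps_true,
                                  n_replicates = 3), seed = 62)
  ds <- screen_dataset(y = sim$y, x = sim$x, gene_of_guide = gog,
                       cells = 250 * n_guides)
  lib <- guide_library(rownames(sim$y), gog, gc = gc, n_bins = 2)
  fit <- suppressWarnings(
    fit_essentiality(ds, lib, negative_controls = genes[26:50]))
  eps_hat <- plogis(fit$state$omega)
  expect_gt(eps_hat[1], eps_hat[2])   # low-GC bin is the efficient one here
  expect_lt(abs(eps_hat[1] - 0.95), 0.15)
  expect_lt(abs(eps_hat[2] - 0.5), 0.15)
})
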