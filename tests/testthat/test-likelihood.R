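test_that("logistic efficiency follows the closed form and saturates safely", {
  expect_equal(guide_efficiency(0, 1), 0.5)
  expect_equal(guide_efficiency(log(3), 1), 0.75)
  e <- guide_efficiency(500, 1)
  expect_lt(e, 1)
  expect_gt(e, 1 - 1e-11)
  e2 <- guide_efficiency(-500, 1)
  expect_gt(e2, 0)
  expect_error(guide_efficiency(c(1, 2), matrix(1, 1, 3)), "dimension")
})

test_that("expected survivors is n (1 - eps phi) with guarded domain", {
  expect_equal(expected_survivors(100, 1, 1), 0)
  expect_equal(expected_survivors(100, 1, 0), 100)
  expect_equal(expected_survivors(100, 0.5, -1), 150)
  expect_error(expected_survivors(100, 1, 1.2), "phi")
  expect_error(expected_survivors(-1, 1, 0), "nonnegative")
})

test_that("guide-sample likelihood matches the brute-force oracle", {
  # the spec'd toy instance
  expect_equal(
    guide_sample_loglik(y = 1, x = 1, m = 0.2, cells = 5, epsilon = 1,
                        phi = 0, opts = likelihood_options("exact")),
    brute_loglik(y = 1, x = 1, m = 0.2, cells = 5, epsilon = 1, phi = 0),
    tolerance = 1e-12)

  # randomized instances: exact mode, master/uniform priors, missing x
  set.seed(101)
  for (i in 1:25) {
    cells <- sample(5:60, 1)
    m <- runif(1, 0.05, 0.9)
    g <- runif(1, 0.5, 2); gp <- runif(1, 0.5, 2)
    eps <- runif(1, 0.3, 1); phi <- runif(1, -1, 1)
    n <- rpois(1, cells * m)
    x <- rpois(1, g * n)
    y <- rpois(1, gp * n * max(0, 1 - eps * phi))
    for (variant in list(
      list(x = x, m = m), list(x = NULL, m = m), list(x = x, m = NULL))) {
      got <- guide_sample_loglik(y = y, x = variant$x, m = variant$m,
                                 cells = cells, gamma = g, gamma_prime = gp,
                                 epsilon = eps, phi = phi,
                                 opts = likelihood_options("exact"))
      want <- brute_loglik(y = y, x = variant$x, m = variant$m,
                           cells = cells, gamma = g, gamma_prime = gp,
                           epsilon = eps, phi = phi)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("zero-mean and impossible-data conventions hold", {
  # y = 0 under eps*phi = 1: every summand's final factor is Pois(0|0) = 1,
  # so the value is the (truncated) prior mass, ~0
  z <- guide_sample_loglik(y = 0, m = 0.2, cells = 5, epsilon = 1, phi = 1,
                           opts = likelihood_options("exact"))
  expect_equal(z, log(ppois(5, 1)), tolerance = 1e-12)
  expect_gt(z, -1e-3)

  # positive count with zero mean everywhere: -Inf, not an error
  expect_identical(
    guide_sample_loglik(y = 3, m = 0.2, cells = 5, gamma_prime = 0,
                        epsilon = 1, phi = 0,
                        opts = likelihood_options("exact")),
    -Inf)
})

test_that("bundled summation with width 1 equals exact mode", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(20:200, 1)
    m <- runif(1, 0.1, 0.9)
    g <- runif(1, 0.5, 2); gp <- runif(1, 0.5, 2)
    eps <- runif(1, 0.3, 1); phi <- runif(1, -1, 1)
    n <- rpois(1, cells * m)
    x <- rpois(1, g * n)
    y <- rpois(1, gp * n * max(0, 1 - eps * phi))
    expect_equal(
      guide_sample_loglik(y, x, m, cells, g, gp, eps, phi,
                          opts = likelihood_options("bundled", 1)),
      guide_sample_loglik(y, x, m, cells, g, gp, eps, phi,
                          opts = likelihood_options("exact")),
      tolerance = 1e-12)
  }
})

test_that("gene log-likelihood is additive over guides and samples", {
  y <- matrix(c(12L, 15L), 1, 2)
  x <- matrix(c(10L, 11L), 1, 2)
  ds <- screen_dataset(y = y, x = x, gene_of_guide = "A",
                       master = 0.3, cells = 40)
  st <- model_state(phi = c(A = 0.4), omega = 2, features = matrix(1, 1, 1),
                    gamma = c(1, 1.1), gamma_prime = c(0.9, 1))
  opts <- likelihood_options("exact")
  # single guide, single sample
  expect_equal(gene_loglik(ds, "A", st, opts, samples = 1),
               guide_sample_loglik(y = 12, x = 10, m = 0.3, cells = 40,
                                   gamma = 1, gamma_prime = 0.9,
                                   epsilon = st$epsilon, phi = 0.4, opts))
  # both samples: sum of the two cells
  expect_equal(gene_loglik(ds, "A", st, opts),
               gene_loglik(ds, "A", st, opts, samples = 1) +
                 gene_loglik(ds, "A", st, opts, samples = 2))
  expect_error(gene_loglik(ds, "nope", st, opts), "unknown gene")

  # duplicated guide rows double the log-likelihood exactly
  ds2 <- screen_dataset(y = rbind(y, y), x = rbind(x, x),
                        gene_of_guide = c("A", "A"), master = c(0.3, 0.3),
                        cells = 40, guide_ids = c("sg1", "sg2"))
  st2 <- model_state(phi = c(A = 0.4), omega = 2,
                     features = matrix(1, 2, 1),
                     gamma = c(1, 1.1), gamma_prime = c(0.9, 1))
  expect_equal(gene_loglik(ds2, "A", st2, opts),
               2 * gene_loglik(ds, "A", st, opts))
})

test_that("gene log-likelihood matches a probability-space product oracle", {
  set.seed(21)
  gog <- c("A", "A", "A")
  m <- c(0.2, 0.3, 0.1)
  cells <- 30
  g <- c(1.2, 0.8); gp <- c(1, 1.4)
  y <- matrix(rpois(6, 8), 3, 2)
  x <- matrix(rpois(6, 7), 3, 2)
  ds <- screen_dataset(y = y, x = x, gene_of_guide = gog, master = m,
                       cells = cells)
  st <- model_state(phi = c(A = 0.3), omega = 1, features = matrix(1, 3, 1),
                    gamma = g, gamma_prime = gp)
  want <- 0
  for (gi in 1:3) for (s in 1:2) {
    want <- want + brute_loglik(y[gi, s], x[gi, s], m[gi], cells, g[s],
                                gp[s], st$epsilon[gi], 0.3)
  }
  expect_equal(gene_loglik(ds, "A", st, likelihood_options("exact")), want,
               tolerance = 1e-9)
})

test_that("with phi = 0 the likelihood is invariant to efficiency weights", {
  sc <- small_screen()
  ds <- sc$dataset
  ds$master <- sc$master
  f <- attr(sc$library, "features")
  opts <- likelihood_options("bundled", 10, prior_tail = 1e-8)
  st1 <- model_state(phi = stats::setNames(rep(0, 60), sc$genes),
                     omega = rep(8, 10), features = f,
                     gamma = rep(1.2, 3), gamma_prime = rep(1.1, 3))
  st2 <- model_state(phi = stats::setNames(rep(0, 60), sc$genes),
                     omega = seq(-3, 6, by = 1), features = f,
                     gamma = rep(1.2, 3), gamma_prime = rep(1.1, 3))
  g <- sc$genes[5]
  expect_equal(gene_loglik(ds, g, st1, opts), gene_loglik(ds, g, st2, opts))
})

test_that("per-gene likelihood profile in phi is continuous and unimodal", {
  sc <- small_screen()
  ds <- sc$dataset
  ds$master <- sc$master
  st <- model_state(phi = sc$phi, omega = rep(8, 10),
                    features = attr(sc$library, "features"),
                    gamma = rep(1.2, 3), gamma_prime = rep(1.1, 3))
  grid <- seq(-2, 1, by = 0.02)
  opts <- likelihood_options("bundled", 10, prior_tail = 1e-8)
  for (g in c(sc$genes[1], sc$genes[45], sc$genes[55])) {
    prof <- vapply(grid, function(p) gene_loglik(ds, g, st, opts, phi = p),
                   numeric(1))
    expect_true(all(is.finite(prof)))
    # single sign change of the discrete gradient => unimodal
    d <- diff(prof)
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)
  }
})

test_that("the latent-Poisson mixture is overdispersed relative to Poisson", {
  # marginal initial counts x under the generative chain n ~ Pois(c m),
  # x ~ Pois(gamma n) have variance > mean whenever c m >= 1 and gamma >= 1
  set.seed(31)
  for (pars in list(c(cm = 1, g = 1), c(cm = 10, g = 1.5),
                    c(cm = 200, g = 1))) {
    n <- rpois(1e4, pars["cm"])
    x <- rpois(1e4, pars["g"] * n)
    expect_gt(var(x), mean(x))
  }
})
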