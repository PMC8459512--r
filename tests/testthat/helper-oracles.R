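# Brute-force probability-space oracle for the marginal likelihood of one
# guide-sample cell: enumerates every latent cell count and sums the prior
# and Poisson factors directly. Independent of the package's log-space /
# bundled code paths.
brute_loglik <- function(y, x = NULL, m = NULL, cells, gamma = 1,
                         gamma_prime = 1, epsilon, phi) {
  tot <- 0
  for (n in 0:cells) {
    pr <- if (is.null(m)) 1 / (cells + 1) else dpois(n, cells * m)
    px <- if (is.null(x)) 1 else dpois(x, gamma * n)
    py <- dpois(y, gamma_prime * n * (1 - epsilon * phi))
    tot <- tot + pr * px * py
  }
  log(tot)
}

# Small simulated screen shared across test files (built once per run).
# 40 nonessential + 10 moderately + 10 strongly essential genes, 4 guides
# each, 3 replicates, fully efficient guides, ~300 reads and 250 infected
# cells per guide.
small_screen <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ng <- 60L; gpg <- 4L
    genes <- sprintf("gene%02d", seq_len(ng))
    gog <- rep(genes, each = gpg)
    phi <- stats::setNames(c(rep(0, 40), rep(0.5, 10), rep(0.99, 10)), genes)
    m <- sample_master(synthetic_master_template(2000L, seed = 11L),
                       ng * gpg, seed = 12L)
    sim <- simulate_screen(sim_spec(m, gog, phi = phi, n_replicates = 3L),
                           seed = 13L)
    ds <- screen_dataset(y = sim$y, x = sim$x, gene_of_guide = gog,
                         cells = 250 * ng * gpg)
    set.seed(14)
    lib <- guide_library(rownames(sim$y), gog, gc = runif(ng * gpg, 0.2, 0.8))
    cache <<- list(dataset = ds, library = lib, genes = genes, phi = phi,
                   controls = genes[1:20], sim = sim, master = m)
    cache
  }
})

# Memoized model fit of the small screen.
small_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- small_screen()
    cache <<- fit_essentiality(sc$dataset, sc$library,
                               negative_controls = sc$controls)
    cache
  }
})

# Memoized differential test on a small two-panel design.
differential_on_small <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ng <- 30L; gpg <- 4L
    genes <- sprintf("d%02d", seq_len(ng))
    gog <- rep(genes, each = gpg)
    m <- rep(1 / (ng * gpg), ng * gpg)
    phi_c <- stats::setNames(rep(0, ng), genes)
    phi_t <- stats::setNames(c(rep(0.6, 10), rep(0, 20)), genes)
    sim <- simulate_screen(sim_spec(m, gog, phi = phi_c, phi_test = phi_t,
                                    n_replicates = 3L), seed = 15L)
    ds <- screen_dataset(y = sim$y, x = sim$x, gene_of_guide = gog,
                         cells = 250 * ng * gpg, panels = sim$panels)
    set.seed(16)
    lib <- guide_library(rownames(sim$y), gog, gc = runif(ng * gpg, 0.2, 0.8))
    fit <- suppressWarnings(
      fit_essentiality(ds, lib, negative_controls = genes[11:30]))
    cache <<- differential_essentiality(fit)
    cache
  }
})
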