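#' Logistic guide efficiency
#'
#' Guide efficiency is the logistic transform of a linear score `omega . F_g`
#' over guide features (one-hot GC-bin indicators by default). The output is
#' clamped to the open interval so downstream Poisson means never hit an
#' exact 0 or 1 through the efficiency term.
#'
#' @param omega Numeric weight vector, one entry per feature.
#' @param features Feature matrix (guides x features) or a single feature
#'   vector.
#' @return Numeric vector of efficiencies in (0, 1).
#' @export
guide_efficiency <- function(omega, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(omega)) {
    stop("feature dimension (", ncol(features),
         ") does not match length of omega (", length(omega), ")")
  }
  eta <- as.numeric(features %*% omega)
  eps <- stats::plogis(eta)
  pmin(pmax(eps, 1e-12), 1 - 1e-12)
}

#' Expected surviving cells after selection
#'
#' The post-selection expected abundance of a guide's cell population is the
#' deterministic map `d = n (1 - epsilon * phi)`: knockout of a fully
#' essential gene (`phi = 1`) by a fully efficient guide (`epsilon = 1`)
#' leaves no descendants, `phi = 0` leaves the population untouched, and
#' negative `phi` models a growth advantage on knockout.
#'
#' @param n Initial number of infected cells (nonnegative).
#' @param epsilon Guide efficiency in `[0, 1]`.
#' @param phi Gene essentiality, `phi <= 1`.
#' @return Expected surviving abundance (real, not rounded).
#' @export
expected_survivors <- function(n, epsilon, phi) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon must lie in [0, 1]")
  if (any(phi > 1)) stop("phi > 1 would give a negative expected abundance")
  n * (1 - epsilon * phi)
}

#' Options controlling the latent-cell summation
#'
#' The likelihood of a guide-sample cell sums over the unobserved number of
#' infected cells `n`. `exact` mode enumerates every value of the support.
#' `bundled` mode partitions the support into consecutive blocks of
#' `bundle_width` cells aligned at 0, evaluates the read-count factors at
#' the block midpoint, and weights each block by its prior mass under an
#' exponential tilt that matches the local log-slope of the read-count
#' factors at the midpoint (the tilted mass has a closed form for both the
#' Poisson and the uniform prior). The tilt makes the block approximation
#' exact whenever the read-count log-factors are linear across the block,
#' which is what keeps the error per guide-sample far below the naive
#' evaluate-at-midpoint rule; at `bundle_width = 1` the scheme reduces
#' algebraically to the exact summation.
#'
#' `prior_tail` optionally trims the summation to the region where either
#' the prior or the initial-count likelihood has mass: with
#' `prior_tail = 1e-8` the grid spans the `[1e-8, 1 - 1e-8]` quantile range
#' of the anchoring Poisson laws, widened by a safety margin (a large
#' speed-up when `c * m` is in the hundreds). `prior_tail = 0` keeps the
#' full `0..c` support.
#'
#' @param summation `"bundled"` or `"exact"`.
#' @param bundle_width Positive integer block width (default 10).
#' @param prior_tail Tail mass trimmed from each end of the summation grid
#'   (default 0 = full support).
#' @return A `likelihood_options` list.
#' @export
likelihood_options <- function(summation = c("bundled", "exact"),
                               bundle_width = 10L, prior_tail = 0) {
  summation <- match.arg(summation)
  bundle_width <- as.integer(bundle_width)
  if (bundle_width < 1L) stop("bundle_width must be >= 1")
  if (prior_tail < 0 || prior_tail >= 0.5) stop("prior_tail must be in [0, 0.5)")
  if (summation == "exact") bundle_width <- 1L
  structure(list(summation = summation, bundle_width = bundle_width,
                 prior_tail = prior_tail),
            class = "likelihood_options")
}

# Poisson log-pmf with the zero-mean convention Pois(k | 0) = 1{k = 0};
# vectorized over mu, never NaN.
pois_logpmf <- function(k, mu, lgamma_k1 = lgamma(k + 1)) {
  out <- numeric(length(mu))
  pos <- mu > 0
  out[pos] <- k * log(mu[pos]) - mu[pos] - lgamma_k1
  out[!pos] <- if (k == 0) 0 else -Inf
  out
}

# Latent-cell grid for one guide-sample: block boundaries and midpoints.
# Blocks are aligned to [0, w), [w, 2w), ... regardless of trimming so the
# bundled value does not depend on the trim. When trimming, the grid covers
# the prior's central mass and the region supported by the initial counts
# (anchor = x / gamma), widened by a relative margin because the final-count
# factor can pull the integrand's peak beyond both anchors while the
# essentiality parameter is being profiled.
latent_grid <- function(cm, cells, opts, uniform_prior = FALSE,
                        anchor = NULL) {
  w <- opts$bundle_width
  lo <- 0
  hi <- as.numeric(cells)
  if (opts$prior_tail > 0 && (!uniform_prior || !is.null(anchor))) {
    anchors <- c(if (!uniform_prior) cm, anchor)
    amin <- min(anchors); amax <- max(anchors)
    lo <- max(0, stats::qpois(opts$prior_tail, amin) - 0.25 * amin)
    hi <- min(hi, stats::qpois(opts$prior_tail, amax, lower.tail = FALSE) +
                0.4 * amax + 3)
  }
  first_block <- floor(lo / w)
  last_block <- floor(hi / w)
  block_lo <- pmax(first_block:last_block * w, 0)
  block_hi <- pmin(block_lo + w - 1, as.numeric(cells))
  mid <- (block_lo + block_hi) %/% 2
  list(lo = block_lo, hi = block_hi, mid = mid)
}

# log of the block prior mass under a local expansion of the read-count
# log-factors around the block midpoint,
#   log sum_{n in [lo, hi]} Prior(n) exp(s (n - mid) + q (n - mid)^2 / 2),
# where s and q are the slope and curvature of the log data factors at mid.
# For a Poisson(lambda) prior the tilted sum is a Poisson(lambda e^s) CDF
# difference times exp(lambda (e^s - 1) - s mid), and the (always negative)
# curvature term is applied as a Gaussian-style correction using the tilted
# truncated-Poisson second moment about the midpoint. For the uniform prior
# the tilted sum is a geometric sum (no curvature correction; the uniform
# prior is the small-cell-count path where blocks are narrow relative to
# the support). Exactly log Prior(mid) when lo == hi == mid. The slope is
# clamped to |s| <= 3: blocks needing a stronger tilt lie far from the
# integrand's peak and are negligible.
block_logmass <- function(lo, hi, mid, s, lambda, cells, uniform = FALSE,
                          q = 0) {
  s <- pmin(pmax(s, -3), 3)
  if (uniform) {
    len <- hi - lo + 1
    gsum <- ifelse(abs(s) < 1e-12, len, expm1(s * len) / expm1(s))
    return(-log(cells + 1) + s * (lo - mid) + log(gsum))
  }
  lt <- lambda * exp(s)
  # upper-tail CDF differences: accurate where blocks carry real mass
  p0 <- stats::ppois(lo - 1, lt, lower.tail = FALSE) -
    stats::ppois(hi, lt, lower.tail = FALSE)
  base <- lambda * expm1(s) - s * mid + log(pmax(p0, 0))
  if (all(q == 0)) return(base)
  # restricted tilted-Poisson moments: E[n 1_B] = lt P(lo-1 <= n <= hi-1),
  # E[n (n-1) 1_B] = lt^2 P(lo-2 <= n <= hi-2)
  m1 <- lt * (stats::ppois(lo - 2, lt, lower.tail = FALSE) -
                stats::ppois(hi - 1, lt, lower.tail = FALSE))
  m2 <- lt^2 * (stats::ppois(lo - 3, lt, lower.tail = FALSE) -
                  stats::ppois(hi - 2, lt, lower.tail = FALSE))
  ok <- p0 > 0
  e2 <- (m2 + m1 - 2 * mid * m1 + mid^2 * p0) / pmax(p0, 1e-300)
  corr <- ifelse(ok, q / 2 * e2, 0)
  base + pmin(corr, 0)
}

#' Log-likelihood of one guide in one sample
#'
#' Computes `log sum_n Prior(n) Pois(x | gamma n) Pois(y | gamma' n (1 - eps
#' phi))`, the contribution of a single guide-sample cell to the screen
#' likelihood, marginalizing the unobserved number of infected cells `n`
#' over `0..cells`. The prior on `n` is Poisson with mean `cells * m` when a
#' master-library fraction `m` is available, and uniform on `{0, ..., cells}`
#' otherwise. When the initial read count `x` is missing its Poisson factor
#' is dropped (the missing-data variant of the model). All summation is done
#' with log-sum-exp; impossible data return `-Inf`, never an error.
#'
#' @param y Final read count (nonnegative integer).
#' @param x Initial read count, or `NULL` if not sequenced.
#' @param m Master-library fraction of the guide, or `NULL` if unknown.
#' @param cells Number of cells infected in the sample (`c_s`).
#' @param gamma,gamma_prime Initial and final sample scaling factors.
#' @param epsilon Guide efficiency in (0, 1].
#' @param phi Gene essentiality (`phi <= 1`).
#' @param opts A [likelihood_options()] object.
#' @return Log-likelihood contribution (a log probability mass, `<= 0` up
#'   to the truncation of the prior at `cells`).
#' @export
guide_sample_loglik <- function(y, x = NULL, m = NULL, cells,
                                gamma = 1, gamma_prime = 1,
                                epsilon, phi,
                                opts = likelihood_options()) {
  stopifnot(y >= 0, cells >= 1)
  if (phi > 1) stop("phi must be <= 1")
  uniform_prior <- is.null(m)
  cm <- if (uniform_prior) NA_real_ else cells * m
  grid <- latent_grid(cm = cm, cells = cells, opts = opts,
                      uniform_prior = uniform_prior,
                      anchor = if (!is.null(x)) x / max(gamma, 1e-12) else NULL)
  surv <- 1 - epsilon * phi
  n <- grid$mid
  if (opts$bundle_width == 1L) {
    lw <- if (uniform_prior) rep(-log(cells + 1), length(n)) else
      stats::dpois(n, cm, log = TRUE)
  } else {
    # slope/curvature of log Pois(x | g n) + log Pois(y | g' s n) at n = mid
    xy <- y + if (is.null(x)) 0 else x
    slope <- ifelse(n > 0, xy / n, 3) - gamma_prime * surv -
      if (is.null(x)) 0 else gamma
    curv <- ifelse(n > 0, -xy / n^2, 0)
    lw <- block_logmass(grid$lo, grid$hi, n, slope,
                        lambda = cm, cells = cells, uniform = uniform_prior,
                        q = curv)
  }
  terms <- lw
  if (!is.null(x)) terms <- terms + pois_logpmf(x, gamma * n)
  terms <- terms + pois_logpmf(y, gamma_prime * n * surv)
  logsumexp(terms)
}

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Log-likelihood component of one gene
#'
#' Sums [guide_sample_loglik()] over the gene's guides and all (or a subset
#' of) samples; guides and samples are modelled as independent.
#'
#' @param dataset A [screen_dataset()].
#' @param gene Gene identifier.
#' @param state A [model_state()] with `phi`, `omega`, `gamma` and
#'   `gamma_prime`.
#' @param opts A [likelihood_options()] object.
#' @param samples Optional character/integer subset of samples (default all).
#' @param phi Optional override of the gene's essentiality (used by the
#'   likelihood-ratio machinery); defaults to `state$phi[gene]`.
#' @return Scalar log-likelihood of the gene's count data.
#' @export
gene_loglik <- function(dataset, gene, state, opts = likelihood_options(),
                        samples = NULL, phi = NULL) {
  gidx <- which(dataset$gene_of_guide == gene)
  if (!length(gidx)) stop("unknown gene: ", gene)
  sidx <- resolve_samples(dataset, samples)
  if (is.null(phi)) phi <- state$phi[[gene]]
  ll <- 0
  for (g in gidx) {
    for (s in sidx) {
      ll <- ll + guide_sample_loglik(
        y = dataset$y[g, s],
        x = if (is.null(dataset$x)) NULL else dataset$x[g, s],
        m = if (is.null(dataset$master)) NULL else dataset$master[g],
        cells = dataset$cells[s],
        gamma = state$gamma[s], gamma_prime = state$gamma_prime[s],
        epsilon = state$epsilon[g], phi = phi, opts = opts)
    }
  }
  ll
}

resolve_samples <- function(dataset, samples) {
  if (is.null(samples)) return(seq_along(dataset$sample_ids))
  if (is.character(samples)) {
    idx <- match(samples, dataset$sample_ids)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(samples)
  }
}
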