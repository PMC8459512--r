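#' Fitting configuration
#'
#' @param phi_bounds Closed search interval for per-gene essentiality; the
#'   upper bound must be 1 (larger values would give negative expected
#'   survivor counts). The lower bound of -5 allows up to a six-fold growth
#'   advantage on knockout, far beyond plausible signal, while keeping the
#'   1-D optimizer's bracket finite.
#' @param omega_bounds Search interval for each efficiency weight; the
#'   logistic transform maps `[-10, 10]` to efficiencies in
#'   `[4.5e-5, 0.99995]`.
#' @param brent_tol Tolerance of the bounded 1-D (Brent-type) maximizations.
#' @param max_outer_iters Maximum number of coordinate-ascent sweeps.
#' @param convergence_tol Maximum absolute change in any `phi` or `omega`
#'   entry below which the outer loop stops.
#' @param loglik_tol Additional stopping rule: the loop also stops when a
#'   full sweep improves the total log-likelihood by less than this (the
#'   1-D optimizer's x-tolerance makes parameters jitter at a scale the
#'   likelihood is flat over, so a pure parameter-change criterion can
#'   cycle long after the fit has effectively converged).
#' @param update_omega Update the efficiency weights? If `FALSE`, `omega`
#'   stays at its initialization (all guides treated as ~100% effective).
#' @param opts A [likelihood_options()] object used for all likelihood
#'   evaluations during fitting. The default bundles the latent-cell
#'   summation into blocks of 10 and trims the Poisson prior to its central
#'   `1 - 2e-8` mass.
#' @return A `fit_config` list.
#' @export
fit_config <- function(phi_bounds = c(-5, 1), omega_bounds = c(-10, 10),
                       brent_tol = 1e-4, max_outer_iters = 50L,
                       convergence_tol = 1e-3, loglik_tol = 0.01,
                       update_omega = TRUE,
                       opts = likelihood_options(prior_tail = 1e-8)) {
  if (phi_bounds[2] != 1) stop("upper phi bound must be 1")
  if (brent_tol <= 0 || convergence_tol <= 0) stop("tolerances must be > 0")
  structure(list(phi_bounds = phi_bounds, omega_bounds = omega_bounds,
                 brent_tol = brent_tol,
                 max_outer_iters = as.integer(max_outer_iters),
                 convergence_tol = convergence_tol, loglik_tol = loglik_tol,
                 update_omega = update_omega, opts = opts),
            class = "fit_config")
}

# ---- flattened likelihood context ------------------------------------------
#
# All guide-sample cells of the dataset are laid out as rows, grouped by
# gene. Everything that does not depend on (phi, omega) -- the latent-cell
# block grid and the initial-count Poisson factor -- is precomputed once
# into padded matrices:
#   MID/LO/HI (rows x K): block midpoints and boundaries (pad LO=0, HI=-1,
#                         so the padded block mass is exactly 0)
#   LX        (rows x K): log Pois(x | gamma mid), 0 when x is absent
#   XM        (rows x K): (x + y) / mid, the count part of the tilt slope
# A likelihood evaluation adds the tilted block prior mass and the
# final-count factor log Pois(y | gamma' mid (1 - eps phi)), then
# log-sum-exps each row.
build_context <- function(dataset, master, gamma, gamma_prime, gc_bin,
                          opts, uniform_prior = FALSE) {
  n_guides <- nrow(dataset$y)
  S <- ncol(dataset$y)
  genes <- unique(dataset$gene_of_guide)
  guide_order <- order(match(dataset$gene_of_guide, genes))
  rows_g <- rep(guide_order, each = S)
  rows_s <- rep.int(seq_len(S), n_guides)

  y <- as.numeric(dataset$y[cbind(rows_g, rows_s)])
  has_x <- !is.null(dataset$x)
  x <- if (has_x) as.numeric(dataset$x[cbind(rows_g, rows_s)]) else NULL
  if (uniform_prior && !has_x) {
    stop("uniform latent prior requires initial counts to anchor the grid")
  }
  gam <- gamma[rows_s]
  gp <- gamma_prime[rows_s]
  cells <- dataset$cells[rows_s]
  cm <- if (uniform_prior) rep(NA_real_, length(y)) else cells * master[rows_g]
  R <- length(y)

  grids <- vector("list", R)
  for (r in seq_len(R)) {
    grids[[r]] <- latent_grid(
      cm = cm[r], cells = cells[r], opts = opts,
      uniform_prior = uniform_prior,
      anchor = if (has_x) x[r] / max(gam[r], 1e-12) else NULL)
  }
  K <- max(vapply(grids, function(g) length(g$mid), integer(1)))
  MID <- matrix(1, nrow = R, ncol = K)
  LO <- matrix(0, nrow = R, ncol = K)
  HI <- matrix(-1, nrow = R, ncol = K)
  LX <- matrix(0, nrow = R, ncol = K)
  LW0 <- if (opts$bundle_width == 1L) matrix(-Inf, R, K) else NULL
  for (r in seq_len(R)) {
    k <- length(grids[[r]]$mid)
    sk <- seq_len(k)
    MID[r, sk] <- grids[[r]]$mid
    LO[r, sk] <- grids[[r]]$lo
    HI[r, sk] <- grids[[r]]$hi
    if (has_x) LX[r, sk] <- pois_logpmf(x[r], gam[r] * grids[[r]]$mid)
    if (!is.null(LW0)) {
      LW0[r, sk] <- if (uniform_prior) -log(cells[r] + 1) else
        stats::dpois(grids[[r]]$mid, cm[r], log = TRUE)
    }
  }
  if (!is.null(LW0) && K > 1) {
    # padded cells must stay silent in exact mode too
    pad <- HI < LO
    LX[pad] <- -Inf
  }
  xy <- y + if (has_x) x else 0
  XM <- xy / MID
  QM <- -xy / MID^2

  gene_of_row <- match(dataset$gene_of_guide[rows_g], genes)
  gene_rows <- split(seq_len(R), gene_of_row)
  names(gene_rows) <- genes[as.integer(names(gene_rows))]
  list(MID = MID, LO = LO, HI = HI, LX = LX, XM = XM, QM = QM, LW0 = LW0,
       y = y, gp = gp, lgy = lgamma(y + 1), lam = cm, cells = cells,
       gam_eff = if (has_x) gam else rep(0, R),
       uniform = uniform_prior, exact = opts$bundle_width == 1L,
       bin = gc_bin[rows_g], gene_of_row = gene_of_row,
       sample_of_row = rows_s, gene_rows = gene_rows[genes], genes = genes)
}

# Sum of per-row marginal log-likelihoods; eps and phi are per-row vectors
# (scalars recycle). Length-R vectors recycle down the columns of the
# rows x K matrices.
rows_loglik <- function(sl, eps, phi) {
  .rows_loglik_cpp(sl$MID, sl$LO, sl$HI, sl$LX, sl$XM, sl$QM, sl$LW0,
                   sl$y, sl$gp, sl$lgy,
                   if (sl$uniform) numeric(length(sl$y)) else sl$lam,
                   sl$cells, sl$gam_eff,
                   as.numeric(eps), as.numeric(phi),
                   sl$uniform, sl$exact)
}

ctx_slice <- function(ctx, rows) {
  list(MID = ctx$MID[rows, , drop = FALSE], LO = ctx$LO[rows, , drop = FALSE],
       HI = ctx$HI[rows, , drop = FALSE], LX = ctx$LX[rows, , drop = FALSE],
       XM = ctx$XM[rows, , drop = FALSE], QM = ctx$QM[rows, , drop = FALSE],
       LW0 = if (is.null(ctx$LW0)) NULL else ctx$LW0[rows, , drop = FALSE],
       y = ctx$y[rows], gp = ctx$gp[rows], lgy = ctx$lgy[rows],
       lam = ctx$lam[rows], cells = ctx$cells[rows],
       gam_eff = ctx$gam_eff[rows],
       uniform = ctx$uniform, exact = ctx$exact,
       bin = ctx$bin[rows], gene_of_row = ctx$gene_of_row[rows],
       sample_of_row = ctx$sample_of_row[rows])
}

slice_loglik <- function(sl, eps_bin, phi) {
  rows_loglik(sl, eps_bin[sl$bin], phi)
}

# Maximize a slice's log-likelihood over a scalar phi; never returns a point
# worse than the incumbent phi0.
maximize_phi <- function(sl, eps_bin, phi0, bounds, tol) {
  opt <- stats::optimize(function(p) slice_loglik(sl, eps_bin, p),
                         interval = bounds, maximum = TRUE, tol = tol)
  ll0 <- slice_loglik(sl, eps_bin, phi0)
  if (opt$objective >= ll0) {
    list(phi = opt$maximum, loglik = opt$objective)
  } else {
    list(phi = phi0, loglik = ll0)
  }
}

#' Fit the essentiality model by coordinate ascent
#'
#' Maximum-likelihood estimation of per-gene essentiality `phi` and
#' per-GC-bin efficiency weights `omega`. With `omega` fixed the likelihood
#' decomposes by gene, and with `phi` fixed it decomposes by feature bin, so
#' the fit alternates bounded 1-D (Brent-type) maximizations over each
#' `phi_G` and each `omega_f` until no parameter moves by more than
#' `convergence_tol` (or a full sweep stops improving the log-likelihood
#' materially; see [fit_config()]). `omega` is initialized at +8 per bin
#' (efficiency
#' ~0.9997, i.e. all guides treated as effectively 100% efficient), `phi` at
#' 0. The total log-likelihood is monitored and must be nondecreasing across
#' sweeps.
#'
#' Sample scaling factors are estimated up front by median-of-ratios (see
#' [estimate_scaling_factors()]) and held fixed, as are the master
#' fractions (estimated from initial counts when absent).
#'
#' @param dataset A [screen_dataset()].
#' @param library A [guide_library()] covering every guide in `dataset`.
#' @param negative_controls Character vector of negative-control gene ids
#'   used as the normalization reference and as the empirical null for the
#'   essentiality test; `NULL` uses all genes for normalization and skips
#'   empirical p-values.
#' @param config A [fit_config()].
#' @return An `essfit_fit` object: list with `state` ([model_state()]),
#'   `results` (data.table: gene, phi_hat, loglik_full, loglik_null, llr,
#'   p_empirical, p_adjusted), `loglik_trace`, `converged`, plus internals
#'   reused by [differential_essentiality()].
#' @export
fit_essentiality <- function(dataset, library, negative_controls = NULL,
                             config = fit_config()) {
  lib_idx <- match(dataset$guide_ids, library$guide_id)
  if (anyNA(lib_idx)) {
    stop("guide(s) present in counts but absent from library: ",
         paste(dataset$guide_ids[is.na(lib_idx)][1:3], collapse = ", "))
  }
  gc_bin <- library$gc_bin[lib_idx]
  n_bins <- ncol(attr(library, "features"))

  reference <- if (is.null(negative_controls)) "all" else negative_controls
  sc <- estimate_scaling_factors(dataset, reference_genes = reference)
  gamma <- sc$gamma
  if (is.null(gamma)) gamma <- rep(1, ncol(dataset$y))  # x absent: unused
  if (any(sc$gamma_prime <= 0)) {
    stop("gamma' is zero for at least one sample; cannot fit")
  }
  ctx <- build_context(dataset, master = sc$master, gamma = gamma,
                       gamma_prime = sc$gamma_prime, gc_bin = gc_bin,
                       opts = config$opts)
  genes <- ctx$genes
  gene_slices <- lapply(ctx$gene_rows, function(rows) ctx_slice(ctx, rows))
  bin_rows <- split(seq_along(ctx$y), ctx$bin)
  occupied_bins <- as.integer(names(bin_rows))
  bin_slices <- lapply(bin_rows, function(rows) ctx_slice(ctx, rows))

  phi <- stats::setNames(rep(0, length(genes)), genes)
  omega <- rep(8, n_bins)
  eps_bin <- clamp_eps(stats::plogis(omega))
  loglik_gene <- stats::setNames(rep(NA_real_, length(genes)), genes)
  trace <- numeric(0)
  converged <- FALSE

  phi_change <- rep(Inf, length(genes))
  for (iter in seq_len(config$max_outer_iters)) {
    delta <- 0
    for (i in seq_along(genes)) {
      # a gene whose essentiality did not move in the previous sweep is at
      # its conditional optimum; re-optimizing it only burns likelihood
      # evaluations (skipping keeps the ascent monotone)
      if (iter > 2L && phi_change[i] < 10 * config$brent_tol) next
      res <- maximize_phi(gene_slices[[i]], eps_bin, phi[[i]],
                          config$phi_bounds, config$brent_tol)
      phi_change[i] <- abs(res$phi - phi[[i]])
      delta <- max(delta, phi_change[i])
      phi[[i]] <- res$phi
      loglik_gene[[i]] <- res$loglik
    }
    if (config$update_omega) {
      for (b in seq_along(occupied_bins)) {
        sl <- bin_slices[[b]]
        phi_rows <- phi[sl$gene_of_row]
        f <- function(w) {
          e <- clamp_eps(stats::plogis(w))
          rows_loglik(sl, e, phi_rows)
        }
        # omega precision 1e-3 bounds the efficiency error by ~2.5e-4
        opt <- stats::optimize(f, interval = config$omega_bounds,
                               maximum = TRUE,
                               tol = max(config$brent_tol, 1e-3))
        w_old <- omega[occupied_bins[b]]
        if (opt$objective >= f(w_old)) {
          delta <- max(delta, abs(opt$maximum - w_old))
          omega[occupied_bins[b]] <- opt$maximum
        }
      }
      eps_bin <- clamp_eps(stats::plogis(omega))
      # omega moved: refresh the cached per-gene maxima
      for (i in seq_along(genes)) {
        loglik_gene[[i]] <- slice_loglik(gene_slices[[i]], eps_bin, phi[[i]])
      }
    }
    total <- sum(loglik_gene)
    if (length(trace) && total < trace[length(trace)] - 1e-6 * (1 + abs(total))) {
      stop("coordinate ascent decreased the log-likelihood (",
           trace[length(trace)], " -> ", total, "); optimizer failure")
    }
    gain <- if (length(trace)) total - trace[length(trace)] else Inf
    trace <- c(trace, total)
    # the likelihood-gain threshold scales with the number of genes: a
    # sweep that improves the average gene by < 1e-4 log-units is noise
    if (delta < config$convergence_tol ||
        gain < max(config$loglik_tol, 1e-4 * length(genes))) {
      converged <- TRUE
      break
    }
  }
  # final full sweep over every gene: sweep-skipping can leave a gene's phi
  # at its optimum for an *earlier* omega; downstream likelihood ratios
  # need each phi_hat to be the conditional optimum at the final omega
  for (i in seq_along(genes)) {
    res <- maximize_phi(gene_slices[[i]], eps_bin, phi[[i]],
                        config$phi_bounds, config$brent_tol)
    phi[[i]] <- res$phi
    loglik_gene[[i]] <- res$loglik
  }
  if (!converged) {
    warning("coordinate ascent did not converge in ", config$max_outer_iters,
            " sweeps (last max parameter change ", signif(delta, 3), ")")
  }

  loglik_null <- vapply(gene_slices, function(sl)
    slice_loglik(sl, eps_bin, 0), numeric(1))
  raw_llr <- loglik_gene - loglik_null
  if (any(raw_llr < -10 * config$brent_tol)) {
    stop("negative essentiality LLR (", min(raw_llr),
         ") for a nested null; optimizer failure")
  }
  llr <- pmax(raw_llr, 0)

  results <- data.table::data.table(
    gene = genes, phi_hat = as.numeric(phi),
    loglik_full = as.numeric(loglik_gene),
    loglik_null = as.numeric(loglik_null), llr = as.numeric(llr))
  if (!is.null(negative_controls)) {
    null_llr <- results$llr[results$gene %in% negative_controls]
    results$p_empirical <- empirical_pvalues(results$llr, null_llr)
    results$p_adjusted <- adjust_pvalues(results$p_empirical)
  }

  features <- matrix(0, nrow = nrow(dataset$y), ncol = n_bins)
  features[cbind(seq_len(nrow(dataset$y)), gc_bin)] <- 1
  state <- model_state(phi = phi, omega = omega, features = features,
                       gamma = gamma, gamma_prime = sc$gamma_prime)
  structure(list(state = state, results = results, loglik_trace = trace,
                 converged = converged, master = sc$master,
                 negative_controls = negative_controls,
                 config = config, dataset = dataset,
                 ctx = ctx, gene_slices = gene_slices, eps_bin = eps_bin),
            class = "essfit_fit")
}

clamp_eps <- function(e) pmin(pmax(e, 1e-12), 1 - 1e-12)

#' @export
print.essfit_fit <- function(x, ...) {
  cat("essfit_fit:", nrow(x$results), "genes,",
      length(x$loglik_trace), "sweeps,",
      if (x$converged) "converged" else "NOT converged",
      "| log-likelihood", format(max(x$loglik_trace), digits = 10), "\n")
  invisible(x)
}

#' Absolute-essentiality log-likelihood ratio
#'
#' `T = ln L(phi_hat) - ln L(phi = 0)` for one gene, all other parameters
#' fixed at their fitted values. Nonnegative up to optimizer tolerance since
#' the null is nested.
#'
#' @param dataset A [screen_dataset()].
#' @param gene Gene id.
#' @param state A fitted [model_state()].
#' @param opts A [likelihood_options()].
#' @return The log-likelihood ratio statistic.
#' @export
absolute_llr <- function(dataset, gene, state, opts = likelihood_options()) {
  gene_loglik(dataset, gene, state, opts) -
    gene_loglik(dataset, gene, state, opts, phi = 0)
}

#' Likelihood-ratio test for differential essentiality
#'
#' For each gene, compares the likelihood maximized with a single
#' essentiality shared across the test and control sample panels (the fitted
#' `phi_hat`) against the likelihood with separate `phi_test` and
#' `phi_control`, re-estimated per panel:
#' `T' = ln L(phi_test) + ln L(phi_control) - ln L(phi_shared)`.
#' Sample scaling factors and guide efficiencies stay fixed at their
#' all-sample fitted values; only the two panel essentialities are
#' re-optimized. With `one_sided = TRUE`, `T'` is set to 0 unless
#' `phi_test > phi_control` (a test for *increased* essentiality in the test
#' panel).
#'
#' @param fit An [fit_essentiality()] result on a dataset with panel labels.
#' @param one_sided Apply the one-sided direction gate (default `FALSE`).
#' @param null_genes Gene ids forming the empirical null for `T'`
#'   (defaults to the fit's negative controls). `NULL` skips p-values.
#' @param p_method Empirical p-value convention, see [empirical_pvalues()].
#' @return data.table: gene, phi_shared, phi_test, phi_control, llr
#'   (`T'`), p_empirical, p_adjusted.
#' @export
differential_essentiality <- function(fit, one_sided = FALSE,
                                      null_genes = fit$negative_controls,
                                      p_method = c("add_one", "plugin")) {
  p_method <- match.arg(p_method)
  dataset <- fit$dataset
  test_s <- panel_samples(dataset, "test")
  ctrl_s <- panel_samples(dataset, "control")
  config <- fit$config
  eps_bin <- fit$eps_bin
  genes <- fit$ctx$genes
  phi_t <- phi_c <- tprime <- numeric(length(genes))
  for (i in seq_along(genes)) {
    sl <- fit$gene_slices[[i]]
    phi0 <- fit$results$phi_hat[i]
    sl_t <- subslice(sl, sl$sample_of_row %in% test_s)
    sl_c <- subslice(sl, sl$sample_of_row %in% ctrl_s)
    rt <- maximize_phi(sl_t, eps_bin, phi0, config$phi_bounds, config$brent_tol)
    rc <- maximize_phi(sl_c, eps_bin, phi0, config$phi_bounds, config$brent_tol)
    shared <- slice_loglik(sl_t, eps_bin, phi0) +
      slice_loglik(sl_c, eps_bin, phi0)
    phi_t[i] <- rt$phi
    phi_c[i] <- rc$phi
    tp <- rt$loglik + rc$loglik - shared
    if (tp < -10 * config$brent_tol) {
      stop("negative differential LLR (", tp, ") for gene ", genes[i],
           "; optimizer failure")
    }
    tp <- max(tp, 0)
    if (one_sided && phi_t[i] <= phi_c[i]) tp <- 0
    tprime[i] <- tp
  }
  out <- data.table::data.table(
    gene = genes, phi_shared = fit$results$phi_hat,
    phi_test = phi_t, phi_control = phi_c, llr = tprime)
  if (!is.null(null_genes)) {
    null_llr <- out$llr[out$gene %in% null_genes]
    out$p_empirical <- empirical_pvalues(out$llr, null_llr, method = p_method)
    out$p_adjusted <- adjust_pvalues(out$p_empirical,
                                     n = sum(!out$gene %in% null_genes))
  }
  out
}

subslice <- function(sl, keep) {
  list(MID = sl$MID[keep, , drop = FALSE], LO = sl$LO[keep, , drop = FALSE],
       HI = sl$HI[keep, , drop = FALSE], LX = sl$LX[keep, , drop = FALSE],
       XM = sl$XM[keep, , drop = FALSE], QM = sl$QM[keep, , drop = FALSE],
       LW0 = if (is.null(sl$LW0)) NULL else sl$LW0[keep, , drop = FALSE],
       y = sl$y[keep], gp = sl$gp[keep], lgy = sl$lgy[keep],
       lam = sl$lam[keep], cells = sl$cells[keep],
       gam_eff = sl$gam_eff[keep],
       uniform = sl$uniform, exact = sl$exact,
       bin = sl$bin[keep], gene_of_row = sl$gene_of_row[keep],
       sample_of_row = sl$sample_of_row[keep])
}

#' Empirical p-values from a null set of statistics
#'
#' @param statistics Observed test statistics.
#' @param null_statistics Statistics of designated null (negative-control)
#'   genes.
#' @param method `"add_one"` (default): `p = (1 + #\{null >= T\}) / (1 + N)`,
#'   the permutation-test convention that avoids `p = 0`. `"plugin"`:
#'   `p = #\{null >= T\} / N`, which can reach 0 when `T` exceeds every null
#'   value — required when p-values must be able to fall below a
#'   multiple-testing threshold finer than `1 / N`.
#' @return Vector of p-values in `[0, 1]`, monotone nonincreasing in the
#'   statistic. Ties count against significance (null values equal to `T`
#'   are included in the exceedance count).
#' @export
empirical_pvalues <- function(statistics, null_statistics,
                              method = c("add_one", "plugin")) {
  method <- match.arg(method)
  n_null <- length(null_statistics)
  if (n_null == 0L) stop("empty null set")
  if (n_null < 20L) warning("only ", n_null, " null statistics; ",
                            "empirical p-values will be coarse")
  exceed <- vapply(statistics, function(t) sum(null_statistics >= t),
                   numeric(1))
  if (method == "add_one") (1 + exceed) / (1 + n_null) else exceed / n_null
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param method Only `"bonferroni"`.
#' @param n Number of tests (default `length(p)`).
#' @return `min(1, p * n)` elementwise.
#' @export
adjust_pvalues <- function(p, method = "bonferroni", n = length(p)) {
  method <- match.arg(method, "bonferroni")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, p * n)
}
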