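#' Simulation specification
#'
#' Configuration of the empirical-gamma screen simulator. Counts are
#' generated independently per guide through a chain of gamma draws: a
#' per-guide, per-replicate infection abundance
#' `mu ~ Gamma(shape = sigma_m / m, scale = m^2 / sigma_m)` (mean `m`, the
#' guide's master fraction), then initial reads
#' `x = round(X_s * Gamma(shape = sigma_x / mu, scale = mu^2 / sigma_x))`
#' and final reads
#' `y = round(Y_s * Gamma(shape = sigma_y / (s mu), scale = (s mu)^2 / sigma_y))`
#' with `s = 1 - epsilon * phi` the survival factor. All three gamma
#' families are shape-scale parameterized so the means are `m`, `mu` and
#' `s * mu` respectively; smaller `sigma` means more dispersion
#' (`CV^2 = mean / sigma`).
#'
#' Default dispersions, used when a template screen is not supplied, are set
#' so that at the mean master fraction the sequencing CV of each read draw
#' is 10% (roughly three-fold-Poisson variance at a coverage of ~300 reads
#' per guide, typical of pooled screens) and the per-replicate infection CV
#' is 15% — the level that, combined with a log-normal master library of
#' sdlog 0.5, reproduces the ~0.9 between-replicate log-count correlation
#' ordinarily seen in screen data.
#'
#' @param master_fractions Per-guide master-library fractions (summing ~1).
#' @param gene_of_guide Gene targeted by each guide.
#' @param phi Per-gene essentiality, named vector or single value; used for
#'   all samples unless `phi_test` is given.
#' @param phi_test Optional per-gene essentiality for the test panel; when
#'   supplied the simulator emits `2 * n_replicates` samples labelled
#'   test/control, with `phi` applying to the control panel.
#' @param epsilon Per-guide efficiency in `[0, 1]` (default 1).
#' @param sigma_m,sigma_x,sigma_y Gamma dispersion parameters (see above).
#' @param depth_initial,depth_final Target total reads per sample.
#' @param n_replicates Replicates per panel (default 3).
#' @param guide_ids Optional guide identifiers.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(master_fractions, gene_of_guide, phi, phi_test = NULL,
                     epsilon = 1, sigma_m = NULL, sigma_x = NULL,
                     sigma_y = NULL, depth_initial = NULL, depth_final = NULL,
                     n_replicates = 3L, guide_ids = NULL) {
  m <- as.numeric(master_fractions)
  gene_of_guide <- as.character(gene_of_guide)
  if (length(gene_of_guide) != length(m)) {
    stop("gene_of_guide must have one entry per guide")
  }
  if (is.null(guide_ids)) guide_ids <- paste0("guide", seq_along(m))
  genes <- unique(gene_of_guide)
  phi <- expand_by_gene(phi, genes, "phi")
  if (!is.null(phi_test)) phi_test <- expand_by_gene(phi_test, genes, "phi_test")
  if (any(phi > 1) || (!is.null(phi_test) && any(phi_test > 1))) {
    stop("phi must be <= 1")
  }
  epsilon <- rep_len(as.numeric(epsilon), length(m))
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon must lie in [0, 1]")
  mbar <- mean(m[m > 0])
  if (is.null(sigma_m)) sigma_m <- mbar / 0.15^2
  if (is.null(sigma_x)) sigma_x <- mbar / 0.1^2
  if (is.null(sigma_y)) sigma_y <- mbar / 0.1^2
  if (sigma_m <= 0 || sigma_x <= 0 || sigma_y <= 0) {
    stop("dispersions must be > 0")
  }
  if (is.null(depth_initial)) depth_initial <- 300 * length(m)
  if (is.null(depth_final)) depth_final <- 300 * length(m)
  if (any(depth_initial <= 0) || any(depth_final <= 0)) {
    stop("sequencing depths must be > 0")
  }
  structure(list(master = m, gene_of_guide = gene_of_guide,
                 guide_ids = as.character(guide_ids), genes = genes,
                 phi = phi, phi_test = phi_test, epsilon = epsilon,
                 sigma_m = sigma_m, sigma_x = sigma_x, sigma_y = sigma_y,
                 depth_initial = depth_initial, depth_final = depth_final,
                 n_replicates = as.integer(n_replicates)),
            class = "sim_spec")
}

expand_by_gene <- function(v, genes, what) {
  if (length(v) == 1L && is.null(names(v))) {
    return(stats::setNames(rep(as.numeric(v), length(genes)), genes))
  }
  if (is.null(names(v))) {
    if (length(v) != length(genes)) {
      stop(what, " must be named, scalar, or one value per gene")
    }
    return(stats::setNames(as.numeric(v), genes))
  }
  miss <- setdiff(genes, names(v))
  if (length(miss)) stop(what, " missing for gene(s): ",
                         paste(miss[1:3], collapse = ", "))
  as.numeric(v[genes])
}

#' Simulate a screen
#'
#' Draws guide-level initial and final read counts according to a
#' [sim_spec()]. Each guide is simulated independently; the infection
#' abundance `mu` is drawn afresh for every guide in every replicate (each
#' replicate is a separate infection into a new pool of cells). Guides with
#' a zero master fraction get zero counts with a warning. Counts are
#' half-to-even rounded to integers. Bit-identical output for identical
#' `spec` and `seed`.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed controlling all randomness.
#' @return List: `x` and `y` (guides x samples integer matrices), `panels`
#'   (per-sample labels; all `"none"` for a single-panel design),
#'   `sample_ids`, `truth` (data.table of per-guide master fraction,
#'   efficiency, per-sample essentiality used and the latent `mu` draws).
#' @export
simulate_screen <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  differential <- !is.null(spec$phi_test)
  S <- if (differential) 2L * spec$n_replicates else spec$n_replicates
  panels <- if (differential) {
    rep(c("test", "control"), each = spec$n_replicates)
  } else rep("none", S)
  sample_ids <- if (differential) {
    paste0(panels, rep(seq_len(spec$n_replicates), 2L))
  } else paste0("rep", seq_len(S))

  G <- length(spec$master)
  X <- rep_len(spec$depth_initial, S)
  Y <- rep_len(spec$depth_final, S)
  gene_idx <- match(spec$gene_of_guide, spec$genes)
  phi_mat <- matrix(spec$phi[gene_idx], nrow = G, ncol = S)
  if (differential) {
    phi_mat[, panels == "test"] <- spec$phi_test[gene_idx]
  }

  m <- spec$master
  if (any(m == 0)) {
    warning(sum(m == 0), " guide(s) with zero master fraction; ",
            "their counts are 0")
  }
  pos <- m > 0
  x <- matrix(0L, G, S)
  y <- matrix(0L, G, S)
  mu_mat <- matrix(0, G, S)
  for (s in seq_len(S)) {
    mu <- numeric(G)
    mu[pos] <- stats::rgamma(sum(pos), shape = spec$sigma_m / m[pos],
                             scale = m[pos]^2 / spec$sigma_m)
    mu_mat[, s] <- mu
    xs <- numeric(G)
    xs[pos] <- X[s] * stats::rgamma(sum(pos), shape = spec$sigma_x / mu[pos],
                                    scale = mu[pos]^2 / spec$sigma_x)
    x[, s] <- as.integer(round(xs))
    surv_mu <- (1 - spec$epsilon * phi_mat[, s]) * mu
    live <- surv_mu > 0
    ys <- numeric(G)
    ys[live] <- Y[s] * stats::rgamma(sum(live),
                                     shape = spec$sigma_y / surv_mu[live],
                                     scale = surv_mu[live]^2 / spec$sigma_y)
    y[, s] <- as.integer(round(ys))
  }
  rownames(x) <- rownames(y) <- spec$guide_ids
  colnames(x) <- colnames(y) <- sample_ids

  truth <- data.table::data.table(
    guide_id = spec$guide_ids, gene = spec$gene_of_guide,
    master = m, epsilon = spec$epsilon,
    phi = spec$phi[gene_idx])
  if (differential) {
    truth$phi_test <- spec$phi_test[gene_idx]
    truth$phi_control <- spec$phi[gene_idx]
  }
  list(x = x, y = y, panels = panels, sample_ids = sample_ids,
       truth = truth, mu = mu_mat, spec = spec, seed = seed)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample master-library fractions from a template
#'
#' Draws per-guide abundances (with replacement by default) from the
#' empirical read-fraction distribution of a template master library and
#' renormalizes them to sum to 1.
#'
#' @param template_master_counts Per-guide read counts (or fractions) of the
#'   template master library.
#' @param n_guides Number of guides to draw.
#' @param seed Integer seed.
#' @param replace Sample with replacement (default `TRUE`; sampling without
#'   replacement requires at least `n_guides` template entries).
#' @return Numeric vector of `n_guides` fractions summing to 1.
#' @export
sample_master <- function(template_master_counts, n_guides, seed = 1L,
                          replace = TRUE) {
  counts <- as.numeric(template_master_counts)
  if (!length(counts)) stop("empty master-library template")
  if (!replace && length(counts) < n_guides) {
    stop("template has fewer than n_guides entries; use replace = TRUE")
  }
  fr <- counts / sum(counts)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  draw <- sample(fr, n_guides, replace = replace)
  draw / sum(draw)
}

#' Synthetic master-library template
#'
#' A stand-in template master library for simulations run without a real
#' screen to mimic: log-normally distributed guide abundances (sdlog 0.5, a
#' typical skew for pooled libraries) scaled to integer counts.
#'
#' @param n_guides Number of template guides.
#' @param sdlog Log-scale standard deviation of abundances.
#' @param mean_count Mean template read count per guide.
#' @param seed Integer seed.
#' @return Integer vector of template master counts.
#' @export
synthetic_master_template <- function(n_guides = 10000L, sdlog = 0.5,
                                      mean_count = 500, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  ab <- stats::rlnorm(n_guides, meanlog = 0, sdlog = sdlog)
  pmax(1L, as.integer(round(mean_count * ab / mean(ab))))
}
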