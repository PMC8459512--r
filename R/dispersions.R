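#' Summary statistics of a replicated screen
#'
#' Five statistics describing the replicate-to-replicate variation of a
#' screen, used to match simulated data to a template: median across-guide
#' (1) CV of initial counts over replicates, (2) CV of final counts, median
#' over replicate pairs of the Pearson correlation of (3) log initial and
#' (4) log final counts, and (5) median across-guide variance of the
#' final/initial log-ratio over replicates (computed on nonessential guides,
#' where the ratio is not confounded by depletion).
#'
#' @param x,y Guides x replicates count matrices.
#' @param nonessential_guides Indices (or logical mask) of guides from
#'   nonessential genes used for the log-ratio statistic; default all.
#' @return Named numeric vector of the five statistics.
#' @export
screen_summary_stats <- function(x, y, nonessential_guides = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) < 2L) stop("need >= 2 replicates to measure variation")
  if (is.null(nonessential_guides)) nonessential_guides <- seq_len(nrow(x))
  cv <- function(mat) {
    mn <- rowMeans(mat)
    keep <- mn > 0
    stats::median(apply(mat[keep, , drop = FALSE], 1, stats::sd) / mn[keep])
  }
  paircor <- function(mat) {
    lmat <- log1p(mat)
    prs <- utils::combn(ncol(mat), 2)
    stats::median(apply(prs, 2, function(p) stats::cor(lmat[, p[1]],
                                                       lmat[, p[2]])))
  }
  lr <- log((y[nonessential_guides, , drop = FALSE] + 0.5) /
              (x[nonessential_guides, , drop = FALSE] + 0.5))
  c(cv_x = cv(x), cv_y = cv(y), cor_x = paircor(x), cor_y = paircor(y),
    lr_var = stats::median(apply(lr, 1, stats::var)))
}

#' Fit simulator dispersions to a template screen
#'
#' Recovers the three gamma dispersion parameters `(sigma_m, sigma_x,
#' sigma_y)` that make simulated screens reproduce a template's
#' replicate-to-replicate variation. A moment-based initial estimate (from
#' the decomposition of the CV and log-ratio statistics into infection and
#' sequencing components) is refined by a Nelder-Mead search over the log
#' dispersions minimizing the squared distance between the log summary
#' statistics ([screen_summary_stats()]) of simulated and template data,
#' with common random numbers across objective evaluations.
#'
#' @param template_x,template_y Guides x replicates count matrices of the
#'   template (assumed dominated by nonessential guides).
#' @param template_master Per-guide master fractions of the template.
#' @param nonessential_guides Guides used for the log-ratio statistic.
#' @param maxit Nelder-Mead iterations (default 60).
#' @param seed Seed for the common random numbers of the objective.
#' @return Named vector `c(sigma_m, sigma_x, sigma_y)`.
#' @export
fit_template_dispersions <- function(template_x, template_y, template_master,
                                     nonessential_guides = NULL,
                                     maxit = 60L, seed = 7L) {
  template_x <- as.matrix(template_x)
  template_y <- as.matrix(template_y)
  if (ncol(template_x) < 2L) {
    stop("template has a single replicate; variation is not estimable")
  }
  m <- as.numeric(template_master)
  target <- screen_summary_stats(template_x, template_y, nonessential_guides)
  mbar <- mean(m[m > 0])

  # moment decomposition: cv_x^2 ~ a + b, cv_y^2 ~ a + c, lr_var ~ b + c
  # with a = mbar/sigma_m, b = mbar/sigma_x, c = mbar/sigma_y
  b0 <- max((target["cv_x"]^2 - target["cv_y"]^2 + target["lr_var"]) / 2, 1e-6)
  c0 <- max(target["lr_var"] - b0, 1e-6)
  a0 <- max(target["cv_x"]^2 - b0, 1e-6)
  start <- log(c(sigma_m = mbar / a0, sigma_x = mbar / b0,
                 sigma_y = mbar / c0))

  depths_x <- colSums(template_x)
  depths_y <- colSums(template_y)
  genes <- paste0("g", seq_along(m))
  objective <- function(ls) {
    sg <- exp(ls)
    spec <- sim_spec(master_fractions = m, gene_of_guide = genes, phi = 0,
                     sigma_m = sg[1], sigma_x = sg[2], sigma_y = sg[3],
                     depth_initial = depths_x, depth_final = depths_y,
                     n_replicates = ncol(template_x))
    sim <- simulate_screen(spec, seed = seed)
    got <- screen_summary_stats(sim$x, sim$y, nonessential_guides)
    sum((log(pmax(got, 1e-8)) - log(pmax(target, 1e-8)))^2)
  }
  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  stats::setNames(exp(opt$par), c("sigma_m", "sigma_x", "sigma_y"))
}
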