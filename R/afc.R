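#' Average-fold-change essentiality scores
#'
#' The baseline depletion estimator: each count gets a 0.5 pseudocount,
#' samples are normalized to a common total of 10 million reads (a factor
#' `lambda_s = 1e7 / sum_g x_sg` for the initial counts and a matching
#' `lambda'_s` for the final counts), and each gene scores
#' `AFC_G = 1 - geomean(lambda'_s tau (0.5 + y) / (lambda_s (0.5 + x)))`
#' over its guides and all samples, where the correction `tau` makes the
#' geometric-mean normalized ratio of negative-control guides exactly 1.
#' An AFC of 0 therefore means no growth impact, 1 complete depletion, and
#' negative values a growth advantage — the same scale as the model's
#' essentiality parameter. Geometric means are computed in log space.
#'
#' @param x,y Initial and final counts, guides x samples.
#' @param gene_of_guide Gene targeted by each guide.
#' @param negative_controls Character vector of negative-control gene ids.
#' @return Named numeric vector of per-gene AFC scores.
#' @export
afc_scores <- function(x, y, gene_of_guide, negative_controls) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  gene_of_guide <- as.character(gene_of_guide)
  if (!length(negative_controls)) stop("empty negative-control set")
  neg <- gene_of_guide %in% negative_controls
  if (!any(neg)) stop("no guides belong to the negative-control genes")
  lambda <- 1e7 / colSums(x)
  lambda_prime <- 1e7 / colSums(y)
  lograt <- sweep(log(0.5 + y), 2, log(lambda_prime), "+") -
    sweep(log(0.5 + x), 2, log(lambda), "+")
  log_tau <- -mean(lograt[neg, ])
  per_gene <- tapply(rowMeans(lograt), gene_of_guide, mean)
  afc <- 1 - exp(as.numeric(per_gene) + log_tau)
  stats::setNames(afc, names(per_gene))
}

#' z-scores of AFC relative to negative controls
#'
#' Standardizes AFC scores by the mean and sample (n-1) standard deviation
#' of the negative-control genes' scores.
#'
#' @param afc Named per-gene AFC vector (as from [afc_scores()]).
#' @param negative_controls Negative-control gene ids (>= 2 required).
#' @return Named per-gene z-score vector.
#' @export
afc_zscores <- function(afc, negative_controls) {
  null_afc <- afc[names(afc) %in% negative_controls]
  if (length(null_afc) < 2L) stop("need >= 2 negative-control genes")
  s <- stats::sd(null_afc)
  if (s == 0) stop("negative-control AFC scores have zero standard deviation")
  (afc - mean(null_afc)) / s
}
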