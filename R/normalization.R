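#' Estimate master-library fractions from initial counts
#'
#' When the master library was not sequenced, the relative abundance of each
#' guide in the pool is approximated by its read fraction in the initial
#' sequencing, averaged across samples.
#'
#' @param x Initial read counts, guides x samples.
#' @return Per-guide fractions summing to 1.
#' @export
estimate_master_fractions <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one sample of initial counts")
  totals <- colSums(x)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1]
    nm <- colnames(x)[bad]
    stop("sample ", if (is.null(nm)) bad else nm,
         " has zero total initial reads")
  }
  rowMeans(sweep(x, 2, totals, "/"))
}

#' Median-of-ratios sample scaling factors
#'
#' Sets the per-sample scaling factors by the median, over reference guides,
#' of the ratio of each guide's read count to its expected number of
#' infected cells `c_s * m_g` — the median-of-ratios normalization
#' popularized by differential-expression tools, anchored here at the
#' master-library prior. `gamma_s` uses the initial counts, `gamma'_s` the
#' final counts; `gamma'` additionally absorbs sample-wide growth effects.
#'
#' @param dataset A [screen_dataset()]. If it has no `master` fractions they
#'   are estimated from the initial counts via [estimate_master_fractions()]
#'   (initial counts must then be present).
#' @param reference_genes Character vector of reference (negative-control)
#'   gene ids, or `"all"` to use every gene.
#' @return List with `gamma` (NULL when initial counts are absent),
#'   `gamma_prime`, and the `master` fractions used.
#' @export
estimate_scaling_factors <- function(dataset, reference_genes = "all") {
  master <- dataset$master
  if (is.null(master)) {
    if (is.null(dataset$x)) {
      stop("cannot anchor scaling: no master fractions and no initial counts")
    }
    master <- estimate_master_fractions(dataset$x)
  }
  if (identical(reference_genes, "all")) {
    ref <- seq_along(dataset$gene_of_guide)
  } else {
    ref <- which(dataset$gene_of_guide %in% reference_genes)
    if (!length(ref)) {
      stop("no guides left after intersecting reference genes with library")
    }
  }
  drop <- master[ref] == 0
  if (any(drop)) {
    warning(sum(drop), " reference guide(s) with zero master fraction dropped")
    ref <- ref[!drop]
    if (!length(ref)) stop("all reference guides have zero master fraction")
  }
  denom <- outer(master[ref], dataset$cells)
  gamma_prime <- apply(dataset$y[ref, , drop = FALSE] / denom, 2, stats::median)
  if (any(gamma_prime == 0)) {
    warning("all-zero reference final counts in sample(s) ",
            paste(dataset$sample_ids[gamma_prime == 0], collapse = ", "),
            "; gamma' = 0 will make the fit fail loudly")
  }
  gamma <- NULL
  if (!is.null(dataset$x)) {
    gamma <- apply(dataset$x[ref, , drop = FALSE] / denom, 2, stats::median)
    if (any(gamma == 0)) {
      warning("all-zero reference initial counts in sample(s) ",
              paste(dataset$sample_ids[gamma == 0], collapse = ", "))
    }
  }
  list(gamma = gamma, gamma_prime = gamma_prime, master = master)
}
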