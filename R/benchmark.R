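#' Construct a simulated benchmark screen
#'
#' Builds the standard simulation layouts used to evaluate essentiality
#' callers, optionally scaled down for desk-size runs.
#'
#' The **absolute** design has 5250 genes at scale 1: 3150 nonessential
#' (60%), 300 at each of five intermediate essentiality levels and 600 at
#' 0.99, with 300 nonessential genes annotated as negative controls. The
#' **differential** design has 300 genes essential only in the test panel
#' (`phi_test = level`, `phi_control = 0`), 300 uniformly strong (0.99), 300
#' uniformly moderate (0.5) and 3150 uniformly nonessential genes; 300 genes
#' from each of the three uniform classes are designated as null genes for
#' the differential test, and 300 nonessential genes double as the
#' normalization controls. Both designs use 4 guides per gene, 3 replicates
#' per panel and an average of 300 reads per guide; master fractions are
#' sampled from a log-normal template library and guide efficiencies are 1.
#'
#' `scale` multiplies every class size (rounded); proportions are preserved.
#'
#' @param design `"absolute"` or `"differential"`.
#' @param level For the differential design, the test-panel essentiality of
#'   the differential genes (default 0.2). Ignored for `"absolute"`.
#' @param levels Intermediate essentiality levels of the absolute design.
#' @param scale Size multiplier in (0, 1].
#' @param seed Integer seed (drives master sampling, GC content and counts).
#' @param guides_per_gene,n_replicates,reads_per_guide,cells_per_guide
#'   Design constants; `cells_per_guide` sets the modelled infected-cell
#'   count `c_s = cells_per_guide * n_guides` (coverage ~250x by default).
#' @param include_master Attach the true master fractions to the returned
#'   dataset (default `FALSE`: methods see read counts only, and master
#'   fractions are re-estimated from the initial counts).
#' @return List: `dataset` (a [screen_dataset()]), `library` (a
#'   [guide_library()]), `truth` (per-gene data.table with class labels,
#'   true essentiality and control annotations), `sim` (raw simulator
#'   output).
#' @export
build_benchmark <- function(design = c("absolute", "differential"),
                            level = 0.2,
                            levels = c(0.1, 0.25, 0.5, 0.75, 0.9),
                            scale = 1, seed = 1L,
                            guides_per_gene = 4L, n_replicates = 3L,
                            reads_per_guide = 300, cells_per_guide = 250,
                            include_master = FALSE) {
  design <- match.arg(design)
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  if (any(levels > 1) || level > 1) stop("essentiality levels must be <= 1")
  n <- function(k) max(1L, as.integer(round(k * scale)))

  if (design == "absolute") {
    class_names <- c("null", paste0("phi", levels), "strong")
    class_sizes <- c(n(3150), rep(n(300), length(levels)), n(600))
    class_phi <- c(0, levels, 0.99)
    truth <- data.table::data.table(
      gene = character(0), class = character(0), phi = numeric(0))
    phi_gene <- numeric(0)
    for (i in seq_along(class_names)) {
      ids <- sprintf("%s_g%04d", class_names[i], seq_len(class_sizes[i]))
      truth <- rbind(truth, data.table::data.table(
        gene = ids, class = class_names[i], phi = class_phi[i]))
      phi_gene <- c(phi_gene, stats::setNames(rep(class_phi[i],
                                                  class_sizes[i]), ids))
    }
    truth$is_control <- FALSE
    truth$is_control[truth$class == "null"][seq_len(n(300))] <- TRUE
    phi_test <- NULL
    phi_control <- phi_gene
  } else {
    class_names <- c("differential", "strong", "moderate", "null")
    class_sizes <- c(n(300), n(300), n(300), n(3150))
    class_phi_c <- c(0, 0.99, 0.5, 0)
    class_phi_t <- c(level, 0.99, 0.5, 0)
    truth <- data.table::data.table(
      gene = character(0), class = character(0),
      phi_test = numeric(0), phi_control = numeric(0))
    phi_control <- phi_test <- numeric(0)
    for (i in seq_along(class_names)) {
      ids <- sprintf("%s_g%04d", class_names[i], seq_len(class_sizes[i]))
      truth <- rbind(truth, data.table::data.table(
        gene = ids, class = class_names[i],
        phi_test = class_phi_t[i], phi_control = class_phi_c[i]))
      phi_control <- c(phi_control,
                       stats::setNames(rep(class_phi_c[i], class_sizes[i]), ids))
      phi_test <- c(phi_test,
                    stats::setNames(rep(class_phi_t[i], class_sizes[i]), ids))
    }
    # null set for the differential test: equally many genes from each
    # uniformly essential / nonessential class
    truth$is_null_control <- FALSE
    for (cl in c("strong", "moderate", "null")) {
      truth$is_null_control[truth$class == cl][seq_len(n(300))] <- TRUE
    }
    # normalization controls must be genuinely nonessential
    truth$is_control <- FALSE
    truth$is_control[truth$class == "null"][seq_len(n(300))] <- TRUE
  }

  n_genes <- nrow(truth)
  n_guides <- n_genes * guides_per_gene
  gene_of_guide <- rep(truth$gene, each = guides_per_gene)
  guide_ids <- paste0(gene_of_guide, "_sg", seq_len(guides_per_gene))

  template <- synthetic_master_template(seed = seed)
  master <- sample_master(template, n_guides, seed = seed + 1L)

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed + 3L)
  gc <- stats::runif(n_guides, 0.2, 0.8)
  library <- guide_library(guide_ids, gene_of_guide, gc = gc)
  # true guide efficiencies follow GC content: most guides are effective,
  # with efficiency falling off toward both GC extremes (the relationship
  # the efficiency model is built to capture)
  eps_profile <- c(0.60, 0.75, 0.85, 0.90, 0.95, 0.95, 0.90, 0.85, 0.75, 0.60)
  epsilon <- eps_profile[library$gc_bin]

  spec <- sim_spec(master_fractions = master, gene_of_guide = gene_of_guide,
                   phi = phi_control, phi_test = phi_test, epsilon = epsilon,
                   depth_initial = reads_per_guide * n_guides,
                   depth_final = reads_per_guide * n_guides,
                   n_replicates = n_replicates, guide_ids = guide_ids)
  sim <- simulate_screen(spec, seed = seed + 2L)

  dataset <- screen_dataset(
    y = sim$y, x = sim$x, gene_of_guide = gene_of_guide,
    master = if (include_master) master else NULL,
    cells = cells_per_guide * n_guides,
    guide_ids = guide_ids, sample_ids = sim$sample_ids,
    panels = if (design == "differential") sim$panels else NULL)

  list(dataset = dataset, library = library, truth = truth, sim = sim,
       design = design, scale = scale, seed = seed)
}

#' Area under the ROC curve via the rank-sum identity
#'
#' @param scores_pos,scores_neg Statistics of the positive and negative
#'   class; ties receive midranks.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (!n1 || !n0) stop("both classes must be non-empty")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Absolute-essentiality benchmark
#'
#' Simulates the absolute design at the requested scale, fits the
#' hierarchical Poisson model and the AFC baseline, and reports per
#' essentiality level the median estimates of both methods and their AUC in
#' separating that level's genes from (non-control) nonessential genes —
#' the model thresholded on its log-likelihood ratio, the baseline on its
#' z-score.
#'
#' @param scale Size multiplier in (0, 1].
#' @param levels Intermediate essentiality levels.
#' @param seed Integer seed.
#' @param config A [fit_config()].
#' @return List: `per_level` (data.table: phi, n_genes, median_phi_model,
#'   median_afc, auc_model, auc_afc), `genes` (per-gene table joining truth,
#'   model results and AFC), `fit`, `benchmark`.
#' @export
run_absolute_benchmark <- function(scale = 0.3,
                                   levels = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                   seed = 1L, config = fit_config()) {
  bm <- build_benchmark("absolute", levels = levels, scale = scale,
                        seed = seed)
  controls <- bm$truth$gene[bm$truth$is_control]
  fit <- fit_essentiality(bm$dataset, bm$library,
                          negative_controls = controls, config = config)
  afc <- afc_scores(bm$dataset$x, bm$dataset$y, bm$dataset$gene_of_guide,
                    negative_controls = controls)
  z <- afc_zscores(afc, controls)

  genes <- data.table::copy(bm$truth)
  idx <- match(genes$gene, fit$results$gene)
  genes$phi_hat <- fit$results$phi_hat[idx]
  genes$llr <- fit$results$llr[idx]
  genes$afc <- as.numeric(afc[genes$gene])
  genes$afc_z <- as.numeric(z[genes$gene])

  neg_pool <- genes[genes$class == "null" & !genes$is_control, ]
  per_level <- data.table::rbindlist(lapply(
    sort(unique(genes$phi)), function(lv) {
      sub <- genes[genes$phi == lv, ]
      data.table::data.table(
        phi = lv, n_genes = nrow(sub),
        median_phi_model = stats::median(sub$phi_hat),
        median_afc = stats::median(sub$afc),
        auc_model = if (lv > 0) rank_auc(sub$llr, neg_pool$llr) else NA_real_,
        auc_afc = if (lv > 0) rank_auc(sub$afc_z, neg_pool$afc_z) else NA_real_)
    }))
  list(per_level = per_level, genes = genes, fit = fit, benchmark = bm)
}

#' Differential-essentiality benchmark
#'
#' Simulates the differential design, fits the model on all samples, runs
#' the differential likelihood-ratio test per gene, computes empirical
#' p-values of `T'` against the designated null genes (equal-sized samples
#' of the uniformly strong, moderate and nonessential classes — all three
#' are genuinely null for the differential hypothesis) and reports the
#' fraction of true differential genes detected at a Bonferroni-corrected
#' empirical p < 0.05 (corrected over the genes outside the null set), plus
#' the AUC of `T'` for differential genes against every non-differential
#' gene.
#'
#' Detection uses the plug-in empirical p-value convention (see
#' [empirical_pvalues()]): with a finite null set, the Bonferroni threshold
#' `0.05 / n_tests` lies below the smallest attainable add-one p-value, so
#' only the plug-in convention — under which a statistic exceeding every
#' null value earns p = 0 — yields a usable corrected test.
#'
#' @param scale Size multiplier in (0, 1].
#' @param level Test-panel essentiality of the differential genes.
#' @param seed Integer seed.
#' @param config A [fit_config()].
#' @param one_sided Use the one-sided test variant.
#' @return List: `detection_fraction`, `auc`, `raw_positive_rate` (share of
#'   true differential genes with pre-Bonferroni p < 0.05),
#'   `null_positive_rate` (same share among non-control uniform genes),
#'   `genes` (per-gene table), `fit`, `benchmark`.
#' @export
run_differential_benchmark <- function(scale = 0.3, level = 0.2, seed = 1L,
                                       config = fit_config(),
                                       one_sided = FALSE) {
  bm <- build_benchmark("differential", level = level, scale = scale,
                        seed = seed)
  norm_controls <- bm$truth$gene[bm$truth$is_control]
  null_genes <- bm$truth$gene[bm$truth$is_null_control]
  fit <- fit_essentiality(bm$dataset, bm$library,
                          negative_controls = norm_controls, config = config)
  diff <- differential_essentiality(fit, one_sided = one_sided,
                                    null_genes = null_genes,
                                    p_method = "plugin")
  genes <- data.table::copy(bm$truth)
  idx <- match(genes$gene, diff$gene)
  genes$phi_hat_test <- diff$phi_test[idx]
  genes$phi_hat_control <- diff$phi_control[idx]
  genes$llr_diff <- diff$llr[idx]
  genes$p_empirical <- diff$p_empirical[idx]
  genes$p_adjusted <- diff$p_adjusted[idx]

  is_diff <- genes$class == "differential"
  other <- genes[!is_diff, ]
  detection <- mean(genes$p_adjusted[is_diff] < 0.05)
  list(detection_fraction = detection,
       auc = rank_auc(genes$llr_diff[is_diff], other$llr_diff),
       raw_positive_rate = mean(genes$p_empirical[is_diff] < 0.05),
       null_positive_rate = mean(genes$p_empirical[!is_diff &
                                                     genes$class != "null"] <
                                   0.05),
       genes = genes, fit = fit, benchmark = bm)
}
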