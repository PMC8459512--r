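#' Assemble a screen dataset
#'
#' Container for the observed data of a pooled knockout screen: final (and
#' optionally initial) guide-level read counts, the guide-to-gene map,
#' master-library fractions when the master pool was sequenced, per-sample
#' infected-cell counts, and optional test/control panel labels.
#'
#' @param y Final read counts, integer matrix guides x samples (required).
#' @param x Initial read counts, same shape, or `NULL` if the initial pool
#'   was not sequenced.
#' @param gene_of_guide Character vector, gene targeted by each guide (row).
#' @param master Per-guide master-library fractions (nonnegative, summing to
#'   at most 1), or `NULL` if no master library is available.
#' @param cells Per-sample number of infected cells `c_s`; a single value is
#'   recycled. Default 1000.
#' @param guide_ids,sample_ids Identifiers; taken from dimnames when `NULL`.
#' @param panels Optional per-sample labels in `{"test", "control", "none"}`
#'   for differential designs.
#' @return A `screen_dataset` list.
#' @export
screen_dataset <- function(y, x = NULL, gene_of_guide, master = NULL,
                           cells = 1000, guide_ids = NULL, sample_ids = NULL,
                           panels = NULL) {
  y <- as.matrix(y)
  if (is.null(guide_ids)) guide_ids <- rownames(y)
  if (is.null(guide_ids)) guide_ids <- paste0("guide", seq_len(nrow(y)))
  if (is.null(sample_ids)) sample_ids <- colnames(y)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(y)))
  check_count_matrix(y, "y")
  if (!is.null(x)) {
    x <- as.matrix(x)
    check_count_matrix(x, "x")
    if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  }
  gene_of_guide <- as.character(gene_of_guide)
  if (length(gene_of_guide) != nrow(y)) {
    stop("gene_of_guide must have one entry per guide (row of y)")
  }
  if (anyDuplicated(guide_ids)) stop("duplicated guide ids")
  if (!is.null(master)) {
    master <- as.numeric(master)
    if (length(master) != nrow(y)) stop("master must have one entry per guide")
    if (any(master < 0)) stop("master fractions must be nonnegative")
    if (sum(master) > 1 + 1e-6) {
      stop("master fractions sum to ", signif(sum(master), 4),
           " > 1; they are fractions of the master library")
    }
  }
  cells <- rep_len(as.numeric(cells), ncol(y))
  if (any(cells < 1)) stop("cells (c_s) must be >= 1 for every sample")
  if (!is.null(panels)) {
    panels <- as.character(panels)
    if (length(panels) != ncol(y)) stop("panels must have one entry per sample")
    bad <- setdiff(unique(panels), c("test", "control", "none"))
    if (length(bad)) stop("unknown panel label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(y = unname(y), x = if (is.null(x)) NULL else unname(x),
                 gene_of_guide = gene_of_guide, master = master,
                 cells = cells, guide_ids = as.character(guide_ids),
                 sample_ids = as.character(sample_ids), panels = panels),
            class = "screen_dataset")
}

check_count_matrix <- function(mat, name) {
  if (anyNA(mat)) stop("missing values in ", name, " counts")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("negative count in ", name, " at row ", bad[1], ", column ", bad[2])
  }
  if (any(mat != round(mat))) stop(name, " counts must be integers")
  invisible(TRUE)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:", nrow(x$y), "guides x", ncol(x$y), "samples;",
      length(unique(x$gene_of_guide)), "genes\n")
  cat("  initial counts:", if (is.null(x$x)) "absent" else "present",
      "| master fractions:", if (is.null(x$master)) "absent" else "present",
      "\n")
  if (!is.null(x$panels)) {
    cat("  panels:", paste(sprintf("%s=%d", names(table(x$panels)),
                                   table(x$panels)), collapse = ", "), "\n")
  }
  invisible(x)
}

panel_samples <- function(dataset, panel) {
  if (is.null(dataset$panels)) stop("dataset has no panel labels")
  idx <- which(dataset$panels == panel)
  if (!length(idx)) stop("no samples labelled '", panel, "'")
  idx
}

#' Model parameter state
#'
#' Bundles the model parameters: per-gene essentiality `phi` (each `<= 1`),
#' the efficiency weight vector `omega` (one entry per GC bin), the derived
#' per-guide efficiencies, and the per-sample scaling factors linking cell
#' numbers to expected read counts at the initial (`gamma`) and final
#' (`gamma_prime`) sequencing.
#'
#' @param phi Named numeric vector of per-gene essentiality values.
#' @param omega Numeric weight vector for the efficiency features.
#' @param features Guide feature matrix (guides x features); efficiencies are
#'   recomputed from `omega` and `features`, never stored independently.
#' @param gamma,gamma_prime Per-sample positive scaling factors.
#' @return A `model_state` list with elements `phi`, `omega`, `epsilon`,
#'   `gamma`, `gamma_prime`.
#' @export
model_state <- function(phi, omega, features, gamma, gamma_prime) {
  if (any(phi > 1)) stop("phi must be <= 1 for every gene")
  if (any(gamma <= 0) || any(gamma_prime <= 0)) {
    stop("gamma and gamma_prime must be strictly positive")
  }
  structure(list(phi = phi, omega = omega,
                 epsilon = guide_efficiency(omega, features),
                 features = features,
                 gamma = gamma, gamma_prime = gamma_prime),
            class = "model_state")
}
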