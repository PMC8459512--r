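#' Build a guide library table
#'
#' A guide library maps each sgRNA to the gene it targets and carries the
#' guide's GC fraction, either supplied directly or computed from the guide
#' sequence. GC fractions feed the decile-indicator feature vectors used by
#' the efficiency model (see [gc_decile_features()]).
#'
#' @param guide_id Character vector of unique guide identifiers.
#' @param gene Character vector, same length, gene targeted by each guide.
#' @param gc Numeric vector of GC fractions in `[0, 1]`, or `NULL` when
#'   `sequence` is given.
#' @param sequence Character vector of guide sequences (A/C/G/T,
#'   case-insensitive); GC fraction is computed as (#G + #C) / length.
#' @param n_bins Number of GC bins for the efficiency features (default 10,
#'   i.e. deciles).
#' @return A `guide_library` object: a data.frame with columns `guide_id`,
#'   `gene`, `gc`, `gc_bin`, plus attributes `features` (guides x bins
#'   one-hot indicator matrix) and `gc_breaks`.
#' @export
guide_library <- function(guide_id, gene, gc = NULL, sequence = NULL,
                          n_bins = 10L) {
  guide_id <- as.character(guide_id)
  gene <- as.character(gene)
  if (length(guide_id) == 0L) stop("empty guide library")
  if (anyDuplicated(guide_id)) {
    stop("duplicated guide ids: ",
         paste(unique(guide_id[duplicated(guide_id)])[1:3], collapse = ", "))
  }
  if (length(gene) != length(guide_id)) {
    stop("'gene' must have one entry per guide")
  }
  if (is.null(gc)) {
    if (is.null(sequence)) stop("supply either 'gc' or 'sequence'")
    gc <- gc_fraction(sequence)
  }
  gc <- as.numeric(gc)
  if (length(gc) != length(guide_id)) {
    stop("'gc' must have one entry per guide")
  }
  if (anyNA(gc) || any(gc < 0 | gc > 1)) {
    stop("GC fractions must lie in [0, 1]")
  }
  feats <- gc_decile_features(gc, n_bins = n_bins)
  lib <- data.frame(guide_id = guide_id, gene = gene, gc = gc,
                    gc_bin = feats$bin, stringsAsFactors = FALSE)
  attr(lib, "features") <- feats$features
  attr(lib, "gc_breaks") <- feats$breaks
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' GC fraction of guide sequences
#'
#' @param sequence Character vector of A/C/G/T sequences (case-insensitive).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) == 0L)) stop("empty guide sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)
  vapply(chars, function(ch) {
    bad <- setdiff(unique(ch), c("A", "C", "G", "T"))
    if (length(bad)) {
      stop("non-ACGT character in guide sequence: ", paste(bad, collapse = ""))
    }
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
}

#' One-hot GC decile features
#'
#' Bins guides by empirical quantiles of their GC content and encodes the bin
#' membership as a one-hot indicator vector per guide. Guide efficiency is
#' modelled as a logistic function of these indicators, so each bin
#' effectively receives its own pooled efficiency estimate.
#'
#' Bin boundaries are the empirical `1/n_bins` quantiles of the supplied GC
#' fractions (type-7 quantiles); guides on a boundary fall in the lower bin.
#' Degenerate inputs with fewer distinct values than bins collapse gracefully
#' into fewer occupied bins; all-identical GC values put every guide in one
#' bin with a warning.
#'
#' @param gc_fractions Numeric vector of GC fractions in `[0, 1]`.
#' @param n_bins Number of bins (default 10).
#' @return List with `features` (length(gc) x n_bins indicator matrix),
#'   `bin` (integer bin index per guide, 1-based) and `breaks` (internal
#'   quantile boundaries).
#' @export
gc_decile_features <- function(gc_fractions, n_bins = 10L) {
  gc_fractions <- as.numeric(gc_fractions)
  n_bins <- as.integer(n_bins)
  if (length(gc_fractions) == 0L) stop("empty GC vector")
  if (anyNA(gc_fractions) || any(gc_fractions < 0 | gc_fractions > 1)) {
    stop("GC fractions must lie in [0, 1]")
  }
  if (n_bins < 1L) stop("n_bins must be >= 1")
  qs <- stats::quantile(gc_fractions, probs = seq_len(n_bins - 1L) / n_bins,
                        names = FALSE, type = 7)
  if (length(unique(gc_fractions)) == 1L && n_bins > 1L) {
    warning("all GC fractions identical; all guides share one GC bin")
  }
  # breaks may repeat when many guides tie; findInterval handles that by
  # leaving the corresponding upper bins empty
  bin <- findInterval(gc_fractions, vec = unique(qs), left.open = TRUE) + 1L
  # map back onto the full 1..n_bins index space so omega stays length n_bins
  ubreaks <- unique(qs)
  if (length(ubreaks) < length(qs)) {
    # positions of the retained breaks among the originals
    keep <- match(ubreaks, qs)
    bin <- c(keep, length(qs) + 1L)[bin]
  }
  F <- matrix(0, nrow = length(gc_fractions), ncol = n_bins)
  F[cbind(seq_along(gc_fractions), bin)] <- 1
  colnames(F) <- paste0("gc_bin", seq_len(n_bins))
  list(features = F, bin = bin, breaks = qs)
}

#' Read a guide library from a TSV file
#'
#' Expects columns `guide_id`, `gene` and one of `gc_fraction` or `sequence`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param n_bins Number of GC bins (default 10).
#' @return A [guide_library()] object.
#' @export
read_guide_library <- function(path, n_bins = 10L) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("guide_id", "gene")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("guide library ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if ("gc_fraction" %in% names(tab)) {
    guide_library(tab$guide_id, tab$gene, gc = tab$gc_fraction,
                  n_bins = n_bins)
  } else if ("sequence" %in% names(tab)) {
    guide_library(tab$guide_id, tab$gene, sequence = tab$sequence,
                  n_bins = n_bins)
  } else {
    stop("guide library ", path, " needs a 'gc_fraction' or 'sequence' column")
  }
}
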