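#' Read a guide count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of guide ids, and
#' integer cells; tab-separated, no quoting.
#'
#' @param path File path.
#' @return Integer matrix guides x samples with dimnames.
#' @export
read_counts <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (ncol(tab) < 2L) stop(path, ": need a guide-id column and >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicated guide id '", ids[duplicated(ids)][1], "'")
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(path, ": missing count at guide '", ids[bad[1]], "', sample '",
         colnames(mat)[bad[2]], "'")
  }
  if (!is.numeric(mat) || any(mat != round(mat))) {
    stop(path, ": counts must be integers")
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(path, ": negative count at guide '", ids[bad[1]], "', sample '",
         colnames(mat)[bad[2]], "'")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  mat
}

#' Write a guide count matrix as TSV
#'
#' @param mat Integer matrix guides x samples with dimnames.
#' @param path Output path.
#' @param id_column Name of the guide-id column (default `"guide_id"`).
#' @export
write_counts <- function(mat, path, id_column = "guide_id") {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("count matrix needs guide ids as rownames and sample ids as colnames")
  }
  out <- data.table::data.table(id = rownames(mat))
  data.table::setnames(out, "id", id_column)
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id` (required), `cells_infected` (optional, default
#' 1000), `panel` (optional, one of test/control/none).
#'
#' @param path File path.
#' @param default_cells Default infected-cell count when the column is
#'   absent.
#' @return data.frame with sample_id, cells_infected, panel.
#' @export
read_sample_sheet <- function(path, default_cells = 1000) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!"sample_id" %in% names(tab)) stop(path, ": needs a sample_id column")
  if (!"cells_infected" %in% names(tab)) tab$cells_infected <- default_cells
  if (!"panel" %in% names(tab)) tab$panel <- "none"
  tab[, c("sample_id", "cells_infected", "panel")]
}

#' Read a simulation spec from YAML
#'
#' The YAML maps directly onto [sim_spec()] / [build_benchmark()]
#' arguments: either a `benchmark:` block (`design`, `level`, `scale`, ...)
#' or explicit `master_fractions`, `gene_of_guide`, `phi`, dispersions and
#' depths.
#'
#' @param path YAML file path.
#' @return Named list of arguments.
#' @export
read_sim_config <- function(path) {
  yaml::read_yaml(path)
}
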