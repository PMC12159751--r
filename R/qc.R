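#' Joint quality-control filtering of multiome cells
#'
#' Keeps cells passing the RNA rules (detected genes >= `min_features`,
#' mitochondrial fraction <= `max_mito_frac`) and the ATAC rules (total
#' counts within `[min_fragments, max_fragments]`). Inequalities are
#' strict on the removal side: a cell at exactly 200 features, 25%
#' mitochondrial reads, 1000 or 50000 fragments is retained. Mitochondrial
#' fraction is mitochondrial RNA counts over total RNA counts; detected
#' genes are genes with count > 0; ATAC counts stand in for fragments.
#'
#' @param ds A `multiome_dataset` whose gene table has `is_mito`.
#' @param min_features,max_mito_frac,min_fragments,max_fragments QC
#'   thresholds (defaults 200, 0.25, 1000, 50000).
#' @return List with `dataset` (the filtered `multiome_dataset`) and
#'   `report`, a `qc_report` carrying pass counts and per-cell reason codes
#'   (`low_features`, `high_mito`, `low_fragments`, `high_fragments`).
#' @export
qc_filter <- function(ds, min_features = 200, max_mito_frac = 0.25,
                      min_fragments = 1000, max_fragments = 50000) {
  stopifnot(inherits(ds, "multiome_dataset"))
  if (all(is.na(ds$genes$is_mito))) stop("gene table has no is_mito flags", call. = FALSE)

  detected <- Matrix::rowSums(ds$rna > 0)
  rna_total <- Matrix::rowSums(ds$rna)
  mito_total <- Matrix::rowSums(ds$rna[, ds$genes$is_mito %in% TRUE, drop = FALSE])
  mito_frac <- ifelse(rna_total > 0, mito_total / rna_total, 1)
  frag <- Matrix::rowSums(ds$atac)

  low_features <- detected < min_features
  high_mito <- mito_frac > max_mito_frac
  low_fragments <- frag < min_fragments
  high_fragments <- frag > max_fragments

  pass_rna <- !low_features & !high_mito
  pass_atac <- !low_fragments & !high_fragments
  pass <- pass_rna & pass_atac
  if (!any(pass)) {
    stop("qc_filter removed every cell; review thresholds against this dataset",
         call. = FALSE)
  }

  reasons <- character(nrow(ds$cells))
  flag <- function(reasons, bad, code) {
    ifelse(bad, ifelse(nzchar(reasons), paste(reasons, code, sep = ";"), code), reasons)
  }
  reasons <- flag(reasons, low_features, "low_features")
  reasons <- flag(reasons, high_mito, "high_mito")
  reasons <- flag(reasons, low_fragments, "low_fragments")
  reasons <- flag(reasons, high_fragments, "high_fragments")

  report <- structure(list(
    n_input_cells = nrow(ds$cells),
    n_pass_rna = sum(pass_rna),
    n_pass_atac = sum(pass_atac),
    n_pass_joint = sum(pass),
    flags = data.frame(cell_id = ds$cells$cell_id, pass = pass,
                       reason = reasons, stringsAsFactors = FALSE)
  ), class = "qc_report")

  list(dataset = subset_cells(ds, which(pass)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d cells in, %d pass RNA, %d pass ATAC, %d pass joint\n",
              x$n_input_cells, x$n_pass_rna, x$n_pass_atac, x$n_pass_joint))
  invisible(x)
}

#' Counts-per-million normalization
#'
#' Rescales each sample (row) to a total of 1e6.
#'
#' @param counts samples x features matrix of non-negative counts.
#' @return Real matrix of the same shape; every row sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1]
    nm <- rownames(counts)[bad]
    stop(sprintf("sample %s has zero total counts; CPM undefined",
                 if (is.null(nm)) bad else nm), call. = FALSE)
  }
  out <- counts / totals * 1e6
  if (methods::is(out, "Matrix")) out <- as.matrix(out)
  out
}
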