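#' Paired single-cell multiome dataset
#'
#' Bundles a cell x gene RNA count matrix and a cell x peak ATAC count
#' matrix with their cell, gene and peak annotation tables. Both assays
#' share one cell ordering; counts are non-negative integers.
#'
#' @param rna cells x genes count matrix (base or \pkg{Matrix} sparse).
#' @param atac cells x peaks count matrix.
#' @param cells data.frame with one row per cell. Must contain `cell_id`;
#'   recognised optional columns: `group`, `cluster`, `pseudotime`
#'   (non-negative, may be `NA` for cells off the trajectory), `state`
#'   (small-integer trajectory state, may be `NA`).
#' @param genes data.frame with one row per gene: `gene_id`, `chrom`,
#'   `tss` (0-based), `strand` ("+"/"-"), `biotype`, `is_mito`.
#' @param peaks data.frame with one row per peak: `peak_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `gc` in [0, 1].
#'
#' @return An object of class `multiome_dataset`: a list with elements
#'   `rna`, `atac`, `cells`, `genes`, `peaks` plus id accessors.
#' @export
multiome_dataset <- function(rna, atac, cells, genes, peaks) {
  rna <- as_count_matrix(rna, "rna")
  atac <- as_count_matrix(atac, "atac")
  stopifnot(is.data.frame(cells), is.data.frame(genes), is.data.frame(peaks))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(cells, "cell_id", "cell")
  need(genes, c("gene_id", "chrom", "tss", "strand", "biotype", "is_mito"), "gene")
  need(peaks, c("peak_id", "chrom", "start", "end", "gc"), "peak")

  for (col in c("group", "cluster", "pseudotime", "state")) {
    if (is.null(cells[[col]])) cells[[col]] <- NA
  }

  check_unique <- function(ids, what) {
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate %s ids: e.g. '%s'", what, ids[duplicated(ids)][1]),
           call. = FALSE)
    }
  }
  check_unique(cells$cell_id, "cell")
  check_unique(genes$gene_id, "gene")
  check_unique(peaks$peak_id, "peak")

  if (nrow(rna) != nrow(cells) || ncol(rna) != nrow(genes)) {
    stop(sprintf("rna matrix is %d x %d but there are %d cells and %d genes",
                 nrow(rna), ncol(rna), nrow(cells), nrow(genes)), call. = FALSE)
  }
  if (nrow(atac) != nrow(cells) || ncol(atac) != nrow(peaks)) {
    stop(sprintf("atac matrix is %d x %d but there are %d cells and %d peaks",
                 nrow(atac), ncol(atac), nrow(cells), nrow(peaks)), call. = FALSE)
  }
  if (any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  if (any(peaks$gc < 0 | peaks$gc > 1, na.rm = TRUE)) {
    stop("peak gc content must lie in [0, 1]", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (any(genes$tss < 0)) stop("gene tss must be >= 0", call. = FALSE)
  pt <- cells$pseudotime
  if (any(!is.na(pt) & (!is.finite(pt) | pt < 0))) {
    stop("pseudotime must be finite and non-negative where present", call. = FALSE)
  }

  dimnames(rna) <- list(cells$cell_id, genes$gene_id)
  dimnames(atac) <- list(cells$cell_id, peaks$peak_id)
  structure(list(rna = rna, atac = atac,
                 cells = cells, genes = genes, peaks = peaks),
            class = "multiome_dataset")
}

as_count_matrix <- function(m, what) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!(is.matrix(m) || methods::is(m, "Matrix"))) {
    stop(sprintf("%s counts must be a matrix", what), call. = FALSE)
  }
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop(sprintf("%s counts must be non-negative integers", what), call. = FALSE)
  }
  m
}

#' @export
print.multiome_dataset <- function(x, ...) {
  cat(sprintf("multiome_dataset: %d cells, %d genes, %d peaks\n",
              nrow(x$rna), ncol(x$rna), ncol(x$atac)))
  grp <- x$cells$group
  if (!all(is.na(grp))) {
    tab <- table(grp)
    cat("  groups: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  n_pt <- sum(!is.na(x$cells$pseudotime))
  cat(sprintf("  cells with pseudotime: %d\n", n_pt))
  invisible(x)
}

#' @export
dim.multiome_dataset <- function(x) {
  c(cells = nrow(x$rna), genes = ncol(x$rna), peaks = ncol(x$atac))
}

#' Subset a multiome dataset by cells
#'
#' @param ds A `multiome_dataset`.
#' @param cell_idx Logical or integer index, or character cell ids.
#' @return A `multiome_dataset` restricted to the selected cells.
#' @export
subset_cells <- function(ds, cell_idx) {
  stopifnot(inherits(ds, "multiome_dataset"))
  if (is.character(cell_idx)) cell_idx <- match(cell_idx, ds$cells$cell_id)
  if (anyNA(cell_idx)) stop("unknown cell id in subset", call. = FALSE)
  multiome_dataset(ds$rna[cell_idx, , drop = FALSE],
                   ds$atac[cell_idx, , drop = FALSE],
                   ds$cells[cell_idx, , drop = FALSE],
                   ds$genes, ds$peaks)
}

#' Transcription-factor motif set
#'
#' @param motif_ids Character vector of motif identifiers.
#' @param tf_names Character vector, one TF name per motif. When a motif's
#'   TF gene is present in the dataset the name doubles as the gene id for
#'   regulator matching.
#' @param pfms List of 4 x width position frequency matrices with rows
#'   A, C, G, T; every column must sum to a positive value.
#' @param peak_match Optional peaks x motifs logical (or 0/1) matrix of
#'   motif occurrence within peaks.
#' @return An object of class `motif_set`.
#' @export
motif_set <- function(motif_ids, tf_names, pfms, peak_match = NULL) {
  motif_ids <- as.character(motif_ids)
  tf_names <- as.character(tf_names)
  stopifnot(length(motif_ids) == length(tf_names),
            length(motif_ids) == length(pfms))
  for (i in seq_along(pfms)) {
    p <- pfms[[i]]
    if (!is.matrix(p) || nrow(p) != 4) {
      stop(sprintf("PFM %s must be a 4 x width matrix", motif_ids[i]), call. = FALSE)
    }
    if (ncol(p) > 0 && any(colSums(p) <= 0)) {
      stop(sprintf("PFM %s has a column summing to <= 0", motif_ids[i]), call. = FALSE)
    }
    rownames(pfms[[i]]) <- c("A", "C", "G", "T")
  }
  names(pfms) <- motif_ids
  if (!is.null(peak_match)) {
    if (ncol(peak_match) != length(motif_ids)) {
      stop("peak_match must have one column per motif", call. = FALSE)
    }
    colnames(peak_match) <- motif_ids
  }
  structure(list(motif_ids = motif_ids, tf_names = tf_names,
                 pfms = pfms, peak_match = peak_match),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  w <- vapply(x$pfms, ncol, integer(1))
  cat(sprintf("motif_set: %d motifs (width %s)\n", length(x$motif_ids),
              if (length(w)) paste(range(w), collapse = "-") else "NA"))
  if (!is.null(x$peak_match)) {
    cat(sprintf("  peak_match: %d peaks x %d motifs\n",
                nrow(x$peak_match), ncol(x$peak_match)))
  }
  invisible(x)
}
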