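#' Pseudotime-ordered pseudobulk aggregation
#'
#' Sorts trajectory cells by pseudotime (ties broken by cell id) and sums
#' both assays over consecutive blocks of `group_size` cells. A trailing
#' block smaller than `group_size / 2` is merged into the previous block,
#' otherwise it is kept as a smaller final sample. CPM matrices are
#' computed per pseudobulk sample.
#'
#' @param ds A `multiome_dataset`.
#' @param trajectory_cells Cell ids (or logical/integer index) of cells on
#'   the trajectory; defaults to all cells with non-missing pseudotime.
#' @param group_size Cells per pseudobulk sample (default 50).
#' @return A `pseudobulk_series`: list with `sample_index`, `member_cells`
#'   (list of cell-id vectors), `mean_pseudotime` (non-decreasing),
#'   `rna_agg`, `atac_agg` (samples x features counts) and `rna_cpm`,
#'   `atac_cpm`.
#' @export
make_pseudobulks <- function(ds, trajectory_cells = NULL, group_size = 50) {
  stopifnot(inherits(ds, "multiome_dataset"))
  if (is.null(trajectory_cells)) {
    idx <- which(!is.na(ds$cells$pseudotime))
  } else if (is.character(trajectory_cells)) {
    idx <- match(trajectory_cells, ds$cells$cell_id)
    if (anyNA(idx)) stop("unknown cell id among trajectory_cells", call. = FALSE)
  } else {
    idx <- which(seq_len(nrow(ds$cells)) %in% seq_len(nrow(ds$cells))[trajectory_cells])
  }
  pt <- ds$cells$pseudotime[idx]
  if (anyNA(pt)) stop("all trajectory cells must have pseudotime", call. = FALSE)
  if (length(idx) < 2 * group_size) {
    stop(sprintf("only %d trajectory cells; need >= %d for a correlatable series",
                 length(idx), 2 * group_size), call. = FALSE)
  }
  ord <- idx[order(pt, ds$cells$cell_id[idx], method = "radix")]

  n <- length(ord)
  n_full <- n %/% group_size
  rem <- n %% group_size
  block <- rep(seq_len(n_full), each = group_size)
  if (rem > 0) {
    tail_block <- if (rem < group_size / 2) n_full else n_full + 1L
    block <- c(block, rep(tail_block, rem))
  }
  n_samples <- max(block)

  members <- split(ds$cells$cell_id[ord], block)
  mean_pt <- as.numeric(tapply(ds$cells$pseudotime[ord], block, mean))

  agg <- function(m) {
    grp <- Matrix::sparseMatrix(i = block, j = seq_len(n), x = 1,
                                dims = c(n_samples, n))
    out <- as.matrix(grp %*% m[ord, , drop = FALSE])
    colnames(out) <- colnames(m)
    rownames(out) <- sprintf("pb%03d", seq_len(n_samples))
    out
  }
  rna_agg <- agg(ds$rna)
  atac_agg <- agg(ds$atac)

  structure(list(sample_index = rownames(rna_agg),
                 member_cells = unname(members),
                 mean_pseudotime = mean_pt,
                 rna_agg = rna_agg, atac_agg = atac_agg,
                 rna_cpm = cpm_normalize(rna_agg),
                 atac_cpm = cpm_normalize(atac_agg)),
            class = "pseudobulk_series")
}

#' @export
print.pseudobulk_series <- function(x, ...) {
  sizes <- lengths(x$member_cells)
  cat(sprintf("pseudobulk_series: %d samples (%d cells; block sizes %s)\n",
              length(x$sample_index), sum(sizes),
              paste(unique(sizes), collapse = ",")))
  cat(sprintf("  pseudotime %.3f .. %.3f\n",
              min(x$mean_pseudotime), max(x$mean_pseudotime)))
  invisible(x)
}

#' Lineage-fate composition along binned pseudotime
#'
#' Restricts to cells whose trajectory state belongs to `fate_states`
#' (e.g. myeloid states 1,3,4,5 or lymphoid states 1,3,4,6), cuts the
#' pooled pseudotime range into `n_bins` equal-width bins shared by all
#' groups, and reports within each (group, bin) the proportion of each
#' cluster label. Empty bins carry all-zero proportions and are flagged.
#'
#' @param ds A `multiome_dataset` with `state` and `cluster` labels.
#' @param fate_states Integer vector of trajectory states defining the fate.
#' @param n_bins Number of pseudotime bins (default 50).
#' @return A `fate_composition`: list with `bin_edges` (length
#'   `n_bins + 1`), `clusters`, and `proportions`, a named list per group
#'   of `n_bins x n_clusters` matrices, plus `empty`, a per-group logical
#'   matrix of empty bins, and `counts` (cells per group x bin).
#' @export
fate_composition <- function(ds, fate_states, n_bins = 50) {
  stopifnot(inherits(ds, "multiome_dataset"))
  st <- ds$cells$state
  keep <- !is.na(st) & st %in% fate_states & !is.na(ds$cells$pseudotime)
  if (!any(keep)) stop("no cells in the requested fate states", call. = FALSE)
  pt <- ds$cells$pseudotime[keep]
  grp <- as.character(ds$cells$group[keep])
  cl <- as.character(ds$cells$cluster[keep])
  if (anyNA(cl)) stop("fate cells must have cluster labels", call. = FALSE)

  edges <- seq(min(pt), max(pt), length.out = n_bins + 1)
  bin <- findInterval(pt, edges, rightmost.closed = TRUE, all.inside = TRUE)
  clusters <- sort(unique(cl))
  groups <- sort(unique(grp))

  props <- list(); counts <- matrix(0L, length(groups), n_bins,
                                    dimnames = list(groups, NULL))
  empty <- matrix(FALSE, length(groups), n_bins, dimnames = list(groups, NULL))
  for (g in groups) {
    tab <- table(factor(bin[grp == g], levels = seq_len(n_bins)),
                 factor(cl[grp == g], levels = clusters))
    tot <- rowSums(tab)
    p <- matrix(0, n_bins, length(clusters), dimnames = list(NULL, clusters))
    nz <- tot > 0
    p[nz, ] <- tab[nz, , drop = FALSE] / tot[nz]
    props[[g]] <- p
    counts[g, ] <- as.integer(tot)
    empty[g, ] <- !nz
  }
  structure(list(bin_edges = edges, clusters = clusters,
                 proportions = props, counts = counts, empty = empty),
            class = "fate_composition")
}

#' @export
print.fate_composition <- function(x, ...) {
  cat(sprintf("fate_composition: %d bins, %d clusters, groups: %s\n",
              length(x$bin_edges) - 1, length(x$clusters),
              paste(names(x$proportions), collapse = ", ")))
  invisible(x)
}
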