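#' One-vs-rest cluster marker genes
#'
#' Finds genes up-regulated in each cluster against all other cells,
#' following the standard single-cell marker recipe: expression is
#' library-size normalized to 1e4 counts per cell and log1p-transformed;
#' the fold change is the natural log of the ratio of normalized group
#' means with pseudocount 1; candidates must have
#' `log_fc > logfc_min` and an expressing fraction above `min_pct` in at
#' least one of the two populations before a two-sided Wilcoxon rank-sum
#' test is applied; BH adjustment is per cluster across its tested genes.
#'
#' @param ds A `multiome_dataset` with cluster labels on >= 2 clusters.
#' @param logfc_min Natural-log fold-change threshold (default 0.25).
#' @param min_pct Expressing-fraction threshold (default 0.25).
#' @return data.frame with columns `gene_id`, `cluster`, `log_fc`,
#'   `pct_in`, `pct_out`, `p_value`, `p_adjusted`, sorted by cluster then
#'   p-value. Clusters with fewer than 3 cells are skipped with a warning.
#' @export
find_markers <- function(ds, logfc_min = 0.25, min_pct = 0.25) {
  stopifnot(inherits(ds, "multiome_dataset"))
  cl <- as.character(ds$cells$cluster)
  if (all(is.na(cl))) stop("cluster labels are required", call. = FALSE)
  clusters <- sort(unique(cl[!is.na(cl)]))
  if (length(clusters) < 2) stop("need >= 2 clusters to find markers", call. = FALSE)

  totals <- Matrix::rowSums(ds$rna)
  if (any(totals == 0)) stop("cells with zero RNA counts; run qc_filter first", call. = FALSE)
  norm <- as.matrix(ds$rna / totals * 1e4)       # cells x genes, CPM/100
  expr <- log1p(norm)
  detected <- norm > 0

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    in_cl <- !is.na(cl) & cl == clusters[ci]
    if (sum(in_cl) < 3) {
      warning(sprintf("cluster '%s' has < 3 cells; skipped", clusters[ci]))
      next
    }
    out_cl <- !is.na(cl) & !in_cl
    mean_in <- colMeans(norm[in_cl, , drop = FALSE])
    mean_out <- colMeans(norm[out_cl, , drop = FALSE])
    pct_in <- colMeans(detected[in_cl, , drop = FALSE])
    pct_out <- colMeans(detected[out_cl, , drop = FALSE])
    log_fc <- log((mean_in + 1) / (mean_out + 1))
    keep <- which(log_fc > logfc_min & pmax(pct_in, pct_out) > min_pct)
    if (!length(keep)) next
    pv <- vapply(keep, function(g) {
      # ties force the normal approximation; the warning is uninformative here
      suppressWarnings(stats::wilcox.test(expr[in_cl, g], expr[out_cl, g])$p.value)
    }, numeric(1))
    res <- data.frame(gene_id = ds$genes$gene_id[keep],
                      cluster = clusters[ci],
                      log_fc = log_fc[keep],
                      pct_in = pct_in[keep], pct_out = pct_out[keep],
                      p_value = pv,
                      p_adjusted = stats::p.adjust(pv, method = "BH"),
                      stringsAsFactors = FALSE)
    out[[ci]] <- res[order(res$p_value), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), cluster = character(),
                      log_fc = numeric(), pct_in = numeric(), pct_out = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
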