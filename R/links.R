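#' Candidate peak-gene pairs by genomic distance
#'
#' Pairs every protein-coding or lincRNA marker gene with all same-
#' chromosome peaks whose midpoint lies between `min_dist` and `max_dist`
#' base pairs from the gene's TSS (inclusive at both ends). The reported
#' distance is signed and strand-aware: positive values lie downstream of
#' the TSS in the gene's reading direction.
#'
#' @param genes Gene table (as in a `multiome_dataset`).
#' @param peaks Peak table.
#' @param marker_genes Character vector of gene ids allowed to enter
#'   linking (typically the union of cluster markers).
#' @param min_dist,max_dist Distance window in bp (defaults 1000, 250000).
#' @return data.frame with `peak_id`, `gene_id`, `distance_bp`.
#' @export
candidate_pairs <- function(genes, peaks, marker_genes,
                            min_dist = 1000, max_dist = 250000) {
  g <- genes[genes$gene_id %in% marker_genes &
               genes$biotype %in% c("protein_coding", "lincRNA"), , drop = FALSE]
  mid <- (peaks$start + peaks$end) / 2
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    on_chr <- which(peaks$chrom == g$chrom[i])
    if (!length(on_chr)) next
    d_abs <- abs(mid[on_chr] - g$tss[i])
    hit <- on_chr[d_abs >= min_dist & d_abs <= max_dist]
    if (!length(hit)) next
    signed <- mid[hit] - g$tss[i]
    if (g$strand[i] == "-") signed <- -signed
    out[[i]] <- data.frame(peak_id = peaks$peak_id[hit],
                           gene_id = g$gene_id[i],
                           distance_bp = signed,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peak_id = character(), gene_id = character(),
                      distance_bp = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Pearson correlation with a two-sided p-value
#'
#' Standard Pearson r with the t-based two-sided p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `pcc` and `p_value`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  list(pcc = r, p_value = p)
}

pearson_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  pmin(p, 1)
}

#' High-confidence link rule
#'
#' A pair is a high-confidence link when `|pcc| >= pcc_min` (inclusive)
#' and `p_value < p_max` (strict).
#'
#' @param pcc,p_value Numeric vectors.
#' @param pcc_min,p_max Thresholds (defaults 0.3, 0.05).
#' @return Logical vector.
#' @export
is_high_confidence <- function(pcc, p_value, pcc_min = 0.3, p_max = 0.05) {
  !is.na(pcc) & !is.na(p_value) & abs(pcc) >= pcc_min & p_value < p_max
}

#' Correlate candidate peak-gene pairs over a pseudobulk series
#'
#' For each candidate pair, computes the Pearson correlation between the
#' peak's CPM accessibility and the gene's CPM expression across
#' pseudobulk samples, with the t-based two-sided p-value, and flags
#' high-confidence links at `|PCC| >= pcc_min` and `P < p_max`. Pairs
#' whose peak or gene profile is constant across samples are returned
#' with `NA` correlation and `drop_reason = "constant_profile"`.
#'
#' @param series A `pseudobulk_series` with >= 3 samples.
#' @param pairs data.frame from [candidate_pairs()].
#' @param pcc_min,p_max Link thresholds (defaults 0.3, 0.05).
#' @return data.frame of `peak_gene_link` rows: `peak_id`, `gene_id`,
#'   `distance_bp`, `pcc`, `p_value`, `high_confidence`, `drop_reason`.
#' @export
link_peaks_to_genes <- function(series, pairs, pcc_min = 0.3, p_max = 0.05) {
  stopifnot(inherits(series, "pseudobulk_series"))
  n <- nrow(series$rna_cpm)
  if (n < 3) stop("need >= 3 pseudobulk samples", call. = FALSE)
  pi <- match(pairs$peak_id, colnames(series$atac_cpm))
  gi <- match(pairs$gene_id, colnames(series$rna_cpm))
  if (anyNA(pi)) stop(sprintf("pair references unknown peak '%s'",
                              pairs$peak_id[which(is.na(pi))[1]]), call. = FALSE)
  if (anyNA(gi)) stop(sprintf("pair references unknown gene '%s'",
                              pairs$gene_id[which(is.na(gi))[1]]), call. = FALSE)

  zscale <- function(m) {
    mu <- colMeans(m)
    sd <- sqrt(colSums(sweep(m, 2, mu)^2) / (nrow(m) - 1))
    list(z = sweep(sweep(m, 2, mu), 2, ifelse(sd > 0, sd, 1), "/"), sd = sd)
  }
  zp <- zscale(series$atac_cpm)
  zg <- zscale(series$rna_cpm)

  r <- colSums(zp$z[, pi, drop = FALSE] * zg$z[, gi, drop = FALSE]) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  const <- zp$sd[pi] == 0 | zg$sd[gi] == 0
  r[const] <- NA
  p <- ifelse(is.na(r), NA, pearson_p(r, n))

  data.frame(peak_id = pairs$peak_id, gene_id = pairs$gene_id,
             distance_bp = pairs$distance_bp,
             pcc = unname(r), p_value = unname(p),
             high_confidence = is_high_confidence(r, p, pcc_min, p_max),
             drop_reason = ifelse(const, "constant_profile", ""),
             stringsAsFactors = FALSE)
}

# k-means++ seeding (squared-distance-proportional center choice)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j + 1], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Cluster high-confidence links into dynamic programs
#'
#' Takes each high-confidence link's gene expression profile across the
#' pseudobulk series, z-scores it per gene (mean 0, sd 1 across samples),
#' and partitions the links with k-means (k-means++ seeding, `nstart`
#' restarts, Euclidean distance). Clusters are renumbered 1..k by the
#' ascending pseudotime position of their mean profile's maximum, so
#' cluster 1 peaks earliest.
#'
#' @param links data.frame from [link_peaks_to_genes()].
#' @param series The `pseudobulk_series` the links were computed on.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed controlling the stochastic initialisation.
#' @param nstart Number of k-means restarts (default 10).
#' @return A `link_cluster_result`: `links` (high-confidence rows with a
#'   `kmeans_cluster` column), `profiles` (links x samples z-scored
#'   matrix), `centers` (k x samples mean z-profiles, renumbered).
#' @export
cluster_links <- function(links, series, k = 6, seed = 1, nstart = 10) {
  hc <- links[links$high_confidence %in% TRUE, , drop = FALSE]
  if (nrow(hc) < k) {
    stop(sprintf("only %d high-confidence links for k = %d; use a smaller k",
                 nrow(hc), k), call. = FALSE)
  }
  gi <- match(hc$gene_id, colnames(series$rna_cpm))
  prof <- t(series$rna_cpm[, gi, drop = FALSE])   # links x samples
  mu <- rowMeans(prof)
  sd <- apply(prof, 1, stats::sd)
  prof <- (prof - mu) / ifelse(sd > 0, sd, 1)
  rownames(prof) <- paste(hc$peak_id, hc$gene_id, sep = "|")

  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- kmeanspp_centers(prof, k)
    centers <- centers + stats::runif(length(centers), -1e-9, 1e-9)  # avoid duplicate-center error
    fit <- suppressWarnings(stats::kmeans(prof, centers = centers,
                                          iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  peak_pos <- apply(best$centers, 1, which.max)
  new_order <- order(peak_pos, seq_len(k))
  relabel <- integer(k); relabel[new_order] <- seq_len(k)
  hc$kmeans_cluster <- relabel[best$cluster]
  centers <- best$centers[new_order, , drop = FALSE]
  rownames(centers) <- seq_len(k)

  structure(list(links = hc, profiles = prof, centers = centers, k = k),
            class = "link_cluster_result")
}

#' @export
print.link_cluster_result <- function(x, ...) {
  cat(sprintf("link_cluster_result: %d links in %d clusters (sizes %s)\n",
              nrow(x$links), x$k,
              paste(tabulate(x$links$kmeans_cluster, x$k), collapse = ",")))
  invisible(x)
}

#' Motif enrichment within link clusters
#'
#' For every (cluster, motif) pair, tests whether motif-bearing peaks are
#' over-represented among the cluster's linked peaks relative to all
#' linked peaks, with a one-sided hypergeometric test; fold enrichment is
#' the in-cluster motif fraction over the background motif fraction. BH
#' adjustment is across motifs within each cluster.
#'
#' @param result A `link_cluster_result`.
#' @param motifs A `motif_set` with `peak_match`.
#' @return data.frame: `cluster`, `motif_id`, `n_cluster_peaks`,
#'   `n_with_motif`, `fold_enrichment`, `p_value`, `p_adjusted`.
#' @export
cluster_motif_enrichment <- function(result, motifs) {
  stopifnot(inherits(result, "link_cluster_result"), inherits(motifs, "motif_set"))
  if (is.null(motifs$peak_match)) stop("motif_set has no peak_match matrix", call. = FALSE)
  links <- result$links
  all_peaks <- unique(links$peak_id)
  pm <- motifs$peak_match[match(all_peaks, rownames(motifs$peak_match)), , drop = FALSE]
  if (anyNA(pm[, 1])) stop("linked peak missing from peak_match rows", call. = FALSE)
  pm <- pm != 0
  N <- length(all_peaks)
  bg_hits <- colSums(pm)

  out <- list()
  for (cl in sort(unique(links$kmeans_cluster))) {
    cl_peaks <- unique(links$peak_id[links$kmeans_cluster == cl])
    n <- length(cl_peaks)
    if (!n) next
    in_cl <- all_peaks %in% cl_peaks
    rows <- lapply(seq_along(motifs$motif_ids), function(m) {
      K <- bg_hits[m]
      if (K == 0) return(NULL)  # motif absent from background: untestable
      x <- sum(pm[in_cl, m])
      p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      fe <- (x / n) / (K / N)
      data.frame(cluster = cl, motif_id = motifs$motif_ids[m],
                 n_cluster_peaks = n, n_with_motif = x,
                 fold_enrichment = fe, p_value = p, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cluster = integer(), motif_id = character(),
                      n_cluster_peaks = integer(), n_with_motif = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
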