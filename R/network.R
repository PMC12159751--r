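#' Accessibility-derived gene activity scores
#'
#' Scores each gene in each pseudobulk sample by summing CPM accessibility
#' of peaks near its TSS, weighted by exponential distance decay:
#' `score(i, g) = log1p( sum_p exp(-|TSS_g - mid_p| / decay) * atac_cpm[i, p] )`
#' over peaks within `window` bp of the TSS on the same chromosome. Genes
#' with no peak in the window score 0.
#'
#' @param series A `pseudobulk_series` (or any object with `atac_cpm`).
#' @param genes,peaks Annotation tables from the `multiome_dataset`.
#' @param window Maximum TSS-peak distance in bp (default 1e5).
#' @param decay Exponential decay constant in bp (default 5000).
#' @return samples x genes matrix of non-negative scores, with attributes
#'   `window` and `decay_constant`.
#' @export
gene_scores <- function(series, genes, peaks, window = 100000, decay = 5000) {
  atac_cpm <- series$atac_cpm
  mid <- (peaks$start + peaks$end) / 2
  ii <- list(); jj <- list(); ww <- list()
  for (g in seq_len(nrow(genes))) {
    on_chr <- which(peaks$chrom == genes$chrom[g])
    if (!length(on_chr)) next
    d <- abs(mid[on_chr] - genes$tss[g])
    hit <- d <= window
    if (!any(hit)) next
    ii[[length(ii) + 1L]] <- on_chr[hit]
    jj[[length(jj) + 1L]] <- rep.int(g, sum(hit))
    ww[[length(ww) + 1L]] <- exp(-d[hit] / decay)
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(nrow(peaks), nrow(genes)))
  scores <- log1p(as.matrix(atac_cpm %*% W))
  dimnames(scores) <- list(rownames(atac_cpm), genes$gene_id)
  attr(scores, "window") <- window
  attr(scores, "decay_constant") <- decay
  scores
}

#' Match TF motif accessibility to TF gene scores
#'
#' For every motif with a mapped TF gene, correlates its bias-corrected
#' deviation z-scores with the TF's own gene activity scores across the
#' pseudobulk series (Pearson, two-sided t-based p, BH across motifs).
#' A motif is called a positive regulator when `r >= r_min` and adjusted
#' p < `fdr_max`: its motif opens exactly where its own gene becomes
#' active along pseudotime.
#'
#' @param dev A `deviation_result` computed on the same samples.
#' @param scores samples x genes matrix from [gene_scores()].
#' @param tf_gene_map Named character vector: motif id -> TF gene id.
#'   Motifs without an entry (or whose gene is absent) are skipped with a
#'   warning.
#' @param r_min Correlation threshold for a positive call (default 0.5).
#' @param fdr_max BH-adjusted p threshold (default 0.05).
#' @return data.frame: `motif_id`, `tf_gene_id`, `correlation`, `p_value`,
#'   `p_adjusted`, `is_positive_regulator`, sorted by descending
#'   correlation.
#' @export
match_regulators <- function(dev, scores, tf_gene_map, r_min = 0.5, fdr_max = 0.05) {
  stopifnot(inherits(dev, "deviation_result"))
  if (ncol(dev$z_dev) < 5) stop("need >= 5 samples to match regulators", call. = FALSE)
  motif_ids <- rownames(dev$z_dev)
  rows <- list()
  for (m in motif_ids) {
    gene <- if (m %in% names(tf_gene_map)) tf_gene_map[[m]] else NA_character_
    if (is.na(gene) || !(gene %in% colnames(scores))) {
      warning(sprintf("motif %s has no mapped TF gene in the score matrix; skipped", m))
      next
    }
    z <- dev$z_dev[m, ]
    s <- scores[, gene]
    ok <- !is.na(z) & !is.na(s)
    if (sum(ok) < 5 || stats::sd(z[ok]) == 0 || stats::sd(s[ok]) == 0) next
    pr <- pearson_with_p(z[ok], s[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      motif_id = m, tf_gene_id = gene,
      correlation = pr$pcc, p_value = pr$p_value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no motif could be matched to a TF gene", call. = FALSE)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$is_positive_regulator <- res$correlation >= r_min & res$p_adjusted < fdr_max
  res <- res[order(-res$correlation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Promoter windows around gene TSSs
#'
#' 0-based half-open windows covering `up` bp upstream and `down` bp
#' downstream of the TSS in the gene's reading direction, clipped at 0.
#' Every unclipped window spans `up + down` bp on either strand.
#'
#' @param genes Gene table with `tss` and `strand`.
#' @param up,down Upstream / downstream extents in bp (defaults 2000, 500).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(genes, up = 2000, down = 500) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down + 1)
  end <- ifelse(plus, genes$tss + down, genes$tss + up + 1)
  start <- pmax(start, 0)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

# PFM -> PWM: log2 of pseudocounted frequency over uniform background
pfm_to_pwm <- function(pfm, pseudocount = 0.8, bg = 0.25) {
  if (ncol(pfm) == 0) stop("zero-width PFM", call. = FALSE)
  freq <- sweep(pfm + pseudocount * bg, 2, colSums(pfm) + pseudocount, "/")
  log2(freq / bg)
}

revcomp_pwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

score_windows <- function(codes, pwm) {
  w <- ncol(pwm)
  n_win <- length(codes) - w + 1L
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  bad <- logical(n_win)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_win - 1L)]
    na <- is.na(cj)
    bad <- bad | na
    cj[na] <- 1L
    sc <- sc + pwm[cbind(cj, j)]
  }
  sc[bad] <- NA_real_
  sc
}

#' Scan a promoter sequence with a motif PWM
#'
#' Converts the PFM to a log2-odds PWM (pseudocount 0.8, uniform
#' background), slides it over both strands, and reports windows passing
#' both thresholds: relative score ("homology") above `rel_min`, where
#' `relative = (score - min) / (max - min)` over the PWM's attainable
#' score range, and raw log-odds sum ("binding score") above `score_min`.
#' Windows containing N are skipped.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pfm 4 x width position frequency matrix (rows A, C, G, T).
#' @param rel_min Relative-score threshold (default 0.85, strict).
#' @param score_min Log-odds threshold (default 8, strict).
#' @param all_windows If `TRUE`, return every scored window unfiltered.
#' @return data.frame: `match_start` (0-based), `strand`, `log_odds`,
#'   `relative_score`.
#' @export
scan_pwm <- function(sequence, pfm, rel_min = 0.85, score_min = 8,
                     all_windows = FALSE) {
  pwm <- pfm_to_pwm(pfm)
  codes <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  if (ncol(pwm) > length(codes)) {
    stop("PWM wider than the sequence", call. = FALSE)
  }
  smin <- sum(apply(pwm, 2, min))
  smax <- sum(apply(pwm, 2, max))
  rng <- max(smax - smin, .Machine$double.eps)

  fwd <- score_windows(codes, pwm)
  rev <- score_windows(codes, revcomp_pwm(pwm))
  res <- data.frame(
    match_start = c(seq_along(fwd), seq_along(rev)) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    log_odds = c(fwd, rev), stringsAsFactors = FALSE)
  res$relative_score <- (res$log_odds - smin) / rng
  res <- res[!is.na(res$log_odds), , drop = FALSE]
  if (!all_windows) res <- filter_pwm_hits(res, rel_min, score_min)
  rownames(res) <- NULL
  res
}

#' Edge-calling rule for PWM matches
#'
#' A scanned window becomes a network edge only when its relative score
#' exceeds `rel_min` AND its log-odds score exceeds `score_min` (both
#' strict, matching "homology >85%, binding score >8").
#'
#' @param hits data.frame with `relative_score` and `log_odds`.
#' @param rel_min,score_min Thresholds (defaults 0.85, 8).
#' @return The passing subset of `hits`.
#' @export
filter_pwm_hits <- function(hits, rel_min = 0.85, score_min = 8) {
  hits[hits$relative_score > rel_min & hits$log_odds > score_min, , drop = FALSE]
}

#' TF-target promoter-binding network
#'
#' Scans the promoter window of every target gene with every TF motif and
#' emits one edge per passing match. Promoter sequences are read from a
#' FASTA whose record names are gene ids; each record must cover the
#' gene's promoter window (sequences are taken as the window itself).
#'
#' @param motifs A `motif_set`.
#' @param genes Gene table.
#' @param promoter_fasta Path to a FASTA of promoter-window sequences
#'   named by gene id, or a named character vector of sequences.
#' @param target_gene_set Character vector of target gene ids (e.g. a
#'   pathway gene list).
#' @param rel_min,score_min Edge thresholds (defaults 0.85, 8).
#' @return data.frame of `network_edge` rows: `tf_name`, `motif_id`,
#'   `target_gene_id`, `match_start`, `strand`, `relative_score`,
#'   `log_odds`.
#' @export
build_network <- function(motifs, genes, promoter_fasta, target_gene_set,
                          rel_min = 0.85, score_min = 8) {
  stopifnot(inherits(motifs, "motif_set"))
  seqs <- if (is.character(promoter_fasta) && length(promoter_fasta) == 1 &&
                file.exists(promoter_fasta)) {
    ss <- Biostrings::readDNAStringSet(promoter_fasta)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    promoter_fasta
  }
  out <- list()
  for (g in target_gene_set) {
    if (!(g %in% names(seqs))) {
      warning(sprintf("no promoter sequence for gene %s; skipped", g))
      next
    }
    for (m in seq_along(motifs$motif_ids)) {
      hits <- scan_pwm(seqs[[g]], motifs$pfms[[m]], rel_min, score_min)
      if (!nrow(hits)) next
      hits$tf_name <- motifs$tf_names[m]
      hits$motif_id <- motifs$motif_ids[m]
      hits$target_gene_id <- g
      out[[length(out) + 1L]] <- hits
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(match_start = integer(), strand = character(),
                      log_odds = numeric(), relative_score = numeric(),
                      tf_name = character(), motif_id = character(),
                      target_gene_id = character(), stringsAsFactors = FALSE)
  }
  res <- res[, c("tf_name", "motif_id", "target_gene_id", "match_start",
                 "strand", "relative_score", "log_odds")]
  rownames(res) <- NULL
  res
}
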