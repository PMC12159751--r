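#' Expected accessibility fraction per peak
#'
#' The fraction of all reads expected to land in each peak under the
#' depth-only null: total counts of the peak across samples over the
#' grand total. Sums to 1.
#'
#' @param atac samples x peaks count matrix.
#' @return Numeric vector, one expectation per peak.
#' @export
expected_fraction <- function(atac) {
  tot <- Matrix::colSums(atac)
  grand <- sum(tot)
  if (grand <= 0) stop("all-zero accessibility matrix", call. = FALSE)
  as.numeric(tot / grand)
}

#' Raw accessibility deviation of a peak set
#'
#' For each sample, the relative excess of observed reads in the peak set
#' over the depth-based expectation:
#' `(observed - expected) / expected`, where
#' `expected_i = depth_i * sum(e_p)` over member peaks. Samples with zero
#' expectation get `NA` with a warning.
#'
#' @param atac samples x peaks count matrix.
#' @param motif_peaks Integer or logical index of member peaks (>= 1 peak).
#' @param expectation Optional per-peak expected fractions; defaults to
#'   [expected_fraction()] of `atac`. Supplying a fixed expectation makes
#'   the deviation exactly invariant to rescaling any single sample.
#' @return Numeric vector of per-sample raw deviations.
#' @export
raw_deviation <- function(atac, motif_peaks, expectation = NULL) {
  if (is.logical(motif_peaks)) motif_peaks <- which(motif_peaks)
  if (!length(motif_peaks)) stop("motif has no peaks", call. = FALSE)
  e <- if (is.null(expectation)) expected_fraction(atac) else expectation
  depth <- Matrix::rowSums(atac)
  o <- Matrix::rowSums(atac[, motif_peaks, drop = FALSE])
  x <- depth * sum(e[motif_peaks])
  dev <- rep(NA_real_, length(o))
  ok <- x > 0
  if (!all(ok)) warning("sample(s) with zero expected counts; deviation NA")
  dev[ok] <- (o[ok] - x[ok]) / x[ok]
  dev
}

# Raw deviations for many peak sets at once. sets: peaks x nset column
# count matrix (multiplicity allowed). Returns samples x nset.
raw_deviation_matrix <- function(atac, sets, e, depth) {
  o <- as.matrix(atac %*% sets)
  exp_frac <- as.numeric(Matrix::crossprod(sets, e))
  x <- outer(depth, exp_frac)
  dev <- (o - x) / x
  dev[x == 0] <- NA_real_
  dev
}

#' GC/accessibility-matched background peaks
#'
#' For each peak, draws `n_bg` background peaks (with replacement, never
#' the peak itself) from its nearest neighbours in standardized
#' (GC content, log1p mean accessibility) space. Neighbours are the
#' nearest 5% of peaks; draws are weighted by a Gaussian kernel on the
#' neighbour distances. If all peaks are identical in both covariates,
#' backgrounds are sampled uniformly with a warning.
#'
#' @param peaks Peak table with a `gc` column.
#' @param atac samples x peaks count matrix (mean accessibility covariate).
#' @param n_bg Background draws per peak (default 50).
#' @param seed Integer seed.
#' @return Integer matrix peaks x `n_bg` of background peak indices.
#' @export
background_peaks <- function(peaks, atac, n_bg = 50, seed = 1) {
  n <- nrow(peaks)
  if (n < n_bg + 1) stop(sprintf("need >= %d peaks for %d backgrounds", n_bg + 1, n_bg),
                         call. = FALSE)
  feat <- cbind(peaks$gc, log1p(Matrix::colMeans(atac)))
  sds <- apply(feat, 2, stats::sd)
  degenerate <- all(sds == 0)
  if (degenerate) {
    warning("all peaks identical in (gc, accessibility); uniform background sampling")
  } else {
    feat <- sweep(feat, 2, colMeans(feat))
    feat <- sweep(feat, 2, ifelse(sds > 0, sds, 1), "/")
  }
  k <- max(2L, as.integer(ceiling(0.05 * (n - 1))))

  set.seed(seed)
  bg <- matrix(0L, n, n_bg)
  chunk <- 512L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    if (degenerate) {
      for (i in idx) bg[i, ] <- sample.int(n - 1L, n_bg, replace = TRUE) |>
          (\(s) ifelse(s >= i, s + 1L, s))()
      next
    }
    d2 <- outer(rowSums(feat[idx, , drop = FALSE]^2), rowSums(feat^2), "+") -
      2 * feat[idx, , drop = FALSE] %*% t(feat)
    for (j in seq_along(idx)) {
      i <- idx[j]
      di <- d2[j, ]
      di[i] <- Inf                       # never draw the peak itself
      nn <- order(di)[seq_len(k)]
      dn <- sqrt(pmax(di[nn], 0))
      sigma <- stats::median(dn[dn > 0])
      w <- if (is.na(sigma) || sigma == 0) rep(1, k) else exp(-dn^2 / (2 * sigma^2))
      bg[i, ] <- sample(nn, n_bg, replace = TRUE, prob = w)
    }
  }
  bg
}

#' Bias-corrected motif deviation z-scores
#'
#' chromVAR-style scoring: for each motif, the raw deviation of its peak
#' set is compared against deviations of background peak sets built by
#' replacing every member peak with one of its GC/accessibility-matched
#' background draws. For background iteration b and sample i,
#' `z_i = (raw_i - mean_b(raw_i^bg)) / sd_b(raw_i^bg)`. Variability is
#' the standard deviation of z across samples.
#'
#' @param atac samples x peaks count matrix (pseudobulks or cells).
#' @param motifs A `motif_set` with `peak_match`, or a peaks x motifs
#'   logical/0-1 matrix.
#' @param backgrounds Integer matrix from [background_peaks()].
#' @return A `deviation_result`: `raw_dev` and `z_dev` (motifs x samples),
#'   `variability` (per motif), `backgrounds`, `n_background`, and the
#'   `atac` matrix used (kept for synergy resampling).
#' @export
bias_corrected_z <- function(atac, motifs, backgrounds) {
  pm <- if (inherits(motifs, "motif_set")) motifs$peak_match else motifs
  if (is.null(pm)) stop("motif_set has no peak_match matrix", call. = FALSE)
  pm <- as.matrix(pm) != 0
  n_bg <- ncol(backgrounds)
  stopifnot(nrow(backgrounds) == nrow(pm))

  e <- expected_fraction(atac)
  depth <- Matrix::rowSums(atac)
  hits <- which(pm, arr.ind = TRUE)
  sets <- Matrix::sparseMatrix(i = hits[, 1], j = hits[, 2], x = 1,
                               dims = dim(pm))
  raw <- raw_deviation_matrix(atac, sets, e, depth)   # samples x motifs

  s1 <- 0; s2 <- 0
  for (b in seq_len(n_bg)) {
    bsets <- Matrix::sparseMatrix(i = backgrounds[hits[, 1], b], j = hits[, 2],
                                  x = 1, dims = dim(pm))
    rb <- raw_deviation_matrix(atac, bsets, e, depth)
    s1 <- s1 + rb
    s2 <- s2 + rb^2
  }
  mu <- s1 / n_bg
  v <- (s2 - n_bg * mu^2) / (n_bg - 1)
  sdv <- sqrt(pmax(v, 0))
  z <- (raw - mu) / sdv
  z[sdv == 0] <- NA_real_

  z_dev <- t(z); raw_dev <- t(raw)
  ids <- colnames(pm)
  if (!is.null(ids)) rownames(z_dev) <- rownames(raw_dev) <- ids
  colnames(z_dev) <- colnames(raw_dev) <- rownames(atac)
  variability <- apply(z_dev, 1, stats::sd, na.rm = TRUE)

  structure(list(raw_dev = raw_dev, z_dev = z_dev, variability = variability,
                 backgrounds = backgrounds, n_background = n_bg, atac = atac),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("deviation_result: %d motifs x %d samples (%d background sets)\n",
              nrow(x$z_dev), ncol(x$z_dev), x$n_background))
  invisible(x)
}

#' Pairwise motif synergy and correlation
#'
#' Correlation is the Pearson r between two motifs' deviation z-score
#' profiles across samples. Synergy asks whether the peaks shared by two
#' motifs are more variable than expected: the variability of the
#' intersection peak set is z-scored against variabilities of `n_sub`
#' random same-size subsets of the union. Pairs sharing fewer than 5
#' peaks get `NA` synergy.
#'
#' @param dev A `deviation_result` from [bias_corrected_z()].
#' @param motifs The `motif_set` (with `peak_match`) scored in `dev`.
#' @param n_sub Number of random subsets per pair (default 100).
#' @param seed Integer seed.
#' @return A `synergy_matrix`: list with `correlation` (symmetric, unit
#'   diagonal) and `synergy` (z-scores, `NA` diagonal).
#' @export
synergy_and_correlation <- function(dev, motifs, n_sub = 100, seed = 1) {
  stopifnot(inherits(dev, "deviation_result"))
  pm <- as.matrix(if (inherits(motifs, "motif_set")) motifs$peak_match else motifs) != 0
  m <- ncol(pm)
  if (m < 2) stop("need >= 2 motifs", call. = FALSE)

  cors <- stats::cor(t(dev$z_dev), use = "pairwise.complete.obs")
  cors[cbind(seq_len(m), seq_len(m))] <- 1

  # assemble intersection + subset columns for every eligible pair
  set.seed(seed)
  cols <- list(); meta <- list()
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    inter <- which(pm[, a] & pm[, b])
    if (length(inter) < 5) next
    uni <- which(pm[, a] | pm[, b])
    subs <- replicate(n_sub, sample(uni, length(inter)), simplify = FALSE)
    cols[[length(cols) + 1L]] <- c(list(inter), subs)
    meta[[length(meta) + 1L]] <- c(a, b)
  }
  syn <- matrix(NA_real_, m, m, dimnames = dimnames(cors))
  if (length(cols)) {
    flat <- unlist(cols, recursive = FALSE)
    sets <- Matrix::sparseMatrix(
      i = unlist(flat),
      j = rep(seq_along(flat), lengths(flat)),
      x = 1, dims = c(nrow(pm), length(flat)))
    vab <- set_variability(dev$atac, sets, dev$backgrounds)
    off <- 0
    for (q in seq_along(cols)) {
      nq <- length(cols[[q]])
      v <- vab[off + seq_len(nq)]; off <- off + nq
      mu <- mean(v[-1], na.rm = TRUE); sdv <- stats::sd(v[-1], na.rm = TRUE)
      # degenerate reference (e.g. identical peak sets): the intersection
      # sits exactly at the distributional center
      zz <- if (is.na(sdv) || sdv == 0) {
        if (isTRUE(abs(v[1] - mu) < 1e-9)) 0 else NA_real_
      } else (v[1] - mu) / sdv
      a <- meta[[q]][1]; b <- meta[[q]][2]
      syn[a, b] <- syn[b, a] <- zz
    }
  }
  structure(list(correlation = cors, synergy = syn), class = "synergy_matrix")
}

# variability (sd of bias-corrected z across samples) for arbitrary
# peak-set columns, sharing one background matrix
set_variability <- function(atac, sets, backgrounds) {
  e <- expected_fraction(atac)
  depth <- Matrix::rowSums(atac)
  ts <- methods::as(sets, "TsparseMatrix")
  hits <- cbind(ts@i + 1L, ts@j + 1L)
  raw <- raw_deviation_matrix(atac, sets, e, depth)
  n_bg <- ncol(backgrounds)
  s1 <- 0; s2 <- 0
  for (b in seq_len(n_bg)) {
    bsets <- Matrix::sparseMatrix(i = backgrounds[hits[, 1], b], j = hits[, 2],
                                  x = 1, dims = dim(sets))
    rb <- raw_deviation_matrix(atac, bsets, e, depth)
    s1 <- s1 + rb
    s2 <- s2 + rb^2
  }
  mu <- s1 / n_bg
  sdv <- sqrt(pmax((s2 - n_bg * mu^2) / (n_bg - 1), 0))
  z <- (raw - mu) / sdv
  z[sdv == 0] <- NA_real_
  apply(z, 2, stats::sd, na.rm = TRUE)
}

#' Group-wise differential motif accessibility
#'
#' Contrasts bias-corrected deviation z-scores between two groups of
#' samples (e.g. control vs disease cells): per motif, the group means,
#' their difference (case minus control), a two-sided Wilcoxon rank-sum
#' p-value across samples, and BH adjustment across motifs. Suitable for
#' a volcano display of delta vs adjusted p.
#'
#' @param dev A `deviation_result`.
#' @param groups Factor or character vector, one label per sample
#'   (column of `z_dev`), exactly 2 levels, each with >= 3 samples.
#' @param case Which level is the case group; defaults to the second
#'   level sorted alphabetically.
#' @return data.frame: `motif_id`, `mean_dev_ctrl`, `mean_dev_case`,
#'   `delta`, `p_value`, `p_adjusted`. All-NA motifs are skipped.
#' @export
differential_deviation <- function(dev, groups, case = NULL) {
  stopifnot(inherits(dev, "deviation_result"))
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(dev$z_dev))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly 2 group labels are required", call. = FALSE)
  if (is.null(case)) case <- lev[2]
  ctrl <- setdiff(lev, case)
  if (sum(groups == case) < 3 || sum(groups == ctrl) < 3) {
    stop("both groups need >= 3 samples", call. = FALSE)
  }
  ids <- rownames(dev$z_dev)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dev$z_dev)))
  rows <- lapply(seq_len(nrow(dev$z_dev)), function(m) {
    zc <- dev$z_dev[m, groups == ctrl]
    zt <- dev$z_dev[m, groups == case]
    zc <- zc[!is.na(zc)]; zt <- zt[!is.na(zt)]
    if (!length(zc) || !length(zt)) return(NULL)
    p <- suppressWarnings(stats::wilcox.test(zt, zc)$p.value)
    data.frame(motif_id = ids[m], mean_dev_ctrl = mean(zc),
               mean_dev_case = mean(zt), delta = mean(zt) - mean(zc),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no motif with usable deviations in both groups", call. = FALSE)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}
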