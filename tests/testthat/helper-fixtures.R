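# Shared fixtures. Large simulations are cached across test files so the
# planted-truth checks reuse one draw per seed.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# full-size study conditions: 2000 cells, 500 genes, 5000 peaks,
# 200 planted links, 20 motifs with 3 planted regulators, link_effect 0.9
default_sim <- function(seed) {
  cache_get(paste0("sim_", seed), function() {
    simulate_multiome(synthetic_spec(seed = seed))
  })
}

# qc -> markers -> pseudobulks -> links, shared by link and regulator checks
default_pipeline <- function(seed) {
  cache_get(paste0("pipe_", seed), function() {
    sim <- default_sim(seed)
    qc <- qc_filter(sim$dataset)
    markers <- find_markers(qc$dataset)
    pb <- make_pseudobulks(qc$dataset)
    pairs <- candidate_pairs(qc$dataset$genes, qc$dataset$peaks,
                             unique(markers$gene_id))
    links <- link_peaks_to_genes(pb, pairs)
    list(sim = sim, qc = qc, markers = markers, pb = pb,
         pairs = pairs, links = links)
  })
}

small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_cells = 400, n_genes = 60, n_peaks = 600, n_motifs = 6,
                 n_planted_links = 20, n_planted_regulators = 2, seed = seed, ...)
}

small_sim <- function(seed = 1) {
  cache_get(paste0("small_", seed), function() simulate_multiome(small_spec(seed)))
}

# mid-size draw for properties that need decent pseudobulk series
mid_spec <- function(seed = 7, ...) {
  synthetic_spec(n_cells = 1000, n_genes = 300, n_peaks = 2000, n_motifs = 8,
                 n_planted_links = 100, n_planted_regulators = 2, seed = seed, ...)
}

# hand-built dataset: explicit counts, one mito gene, controllable cells
toy_dataset <- function(rna, atac, pseudotime = NULL, cluster = NULL,
                        group = NULL, state = NULL, n_mito = 1,
                        peak_chrom = "chr1", peak_start = NULL) {
  n <- nrow(rna); G <- ncol(rna); P <- ncol(atac)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
  if (!is.null(group)) cells$group <- group
  if (!is.null(cluster)) cells$cluster <- cluster
  if (!is.null(pseudotime)) cells$pseudotime <- pseudotime
  if (!is.null(state)) cells$state <- state
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(G)), chrom = "chr1",
                      tss = seq_len(G) * 1000L, strand = "+",
                      biotype = "protein_coding",
                      is_mito = seq_len(G) > G - n_mito,
                      stringsAsFactors = FALSE)
  if (is.null(peak_start)) peak_start <- seq_len(P) * 2000L
  peaks <- data.frame(peak_id = sprintf("p%03d", seq_len(P)), chrom = peak_chrom,
                      start = peak_start, end = peak_start + 500L,
                      gc = seq(0.3, 0.7, length.out = P),
                      stringsAsFactors = FALSE)
  multiome_dataset(rna, atac, cells, genes, peaks)
}

# eight cells probing every QC boundary exactly (defaults 200 / 25% /
# 1000 / 50000); expected pass pattern: B, C, F, G
qc_boundary_dataset <- function() {
  G <- 301L  # 300 ordinary genes + 1 mitochondrial
  rna <- matrix(0L, 8, G)
  rna[1, 1:199] <- 1L                      # A: 199 detected -> low_features
  rna[2, 1:200] <- 1L                      # B: 200 detected -> kept
  rna[3, 1:300] <- 1L; rna[3, G] <- 100L   # C: mito 100/400 = 25.0% -> kept
  rna[4, 1:300] <- 1L; rna[4, G] <- 101L   # D: 101/401 = 25.2% -> high_mito
  for (i in 5:8) rna[i, 1:300] <- 1L
  atac <- matrix(0L, 8, 3)
  atac[, 1] <- 2000L
  atac[5, ] <- c(999L, 0L, 0L)             # E: low_fragments
  atac[6, ] <- c(1000L, 0L, 0L)            # F: kept
  atac[7, ] <- c(25000L, 25000L, 0L)       # G: 50000 -> kept
  atac[8, ] <- c(25000L, 25001L, 0L)       # H: 50001 -> high_fragments
  toy_dataset(rna, atac)
}

# exact hypergeometric upper tail by direct summation
hyper_tail_oracle <- function(x, K, N, n) {
  j <- x:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# definitional Pearson r and t-based two-sided p
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
  list(pcc = r, p_value = 2 * stats::pt(tval, n - 2, lower.tail = FALSE))
}

# independent PWM scoring: rebuild the log-odds matrix from its formula and
# score one window on one strand from first principles
pwm_window_oracle <- function(sequence, pfm, offset, strand) {
  w <- ncol(pfm)
  pwm <- log2(((pfm + 0.8 * 0.25) / rep(colSums(pfm) + 0.8, each = 4)) / 0.25)
  win <- substr(sequence, offset + 1, offset + w)
  if (strand == "-") {
    win <- chartr("ACGT", "TGCA", paste(rev(strsplit(win, "")[[1]]), collapse = ""))
  }
  b <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(b)) return(NA_real_)
  sum(pwm[cbind(b, seq_len(w))])
}

link_keys <- function(df) paste(df$peak_id, df$gene_id)
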