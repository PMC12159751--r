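test_that("gene scores apply exponential distance decay inside the window", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      tss = c(10000L, 10000L, 500000L), strand = "+",
                      biotype = "protein_coding", is_mito = FALSE,
                      stringsAsFactors = FALSE)
  # peak 1 midpoint at gA TSS; peak 2 at one decay constant away
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                      start = c(9750L, 14750L), end = c(10250L, 15250L),
                      gc = 0.5, stringsAsFactors = FALSE)
  cpm <- matrix(c(100, 200, 50, 80), 2, 2,
                dimnames = list(c("s1", "s2"), c("p1", "p2")))
  gs <- gene_scores(list(atac_cpm = cpm), genes, peaks,
                    window = 100000, decay = 5000)
  expect_equal(gs["s1", "gA"], log1p(1 * 100 + exp(-1) * 50), tolerance = 1e-12)
  expect_equal(gs["s2", "gA"], log1p(1 * 200 + exp(-1) * 80), tolerance = 1e-12)
  # gC has no peak within the window
  expect_equal(unname(gs[, "gC"]), c(0, 0))
  # widening the window never decreases a score
  gs_wide <- gene_scores(list(atac_cpm = cpm), genes, peaks,
                         window = 1e6, decay = 5000)
  expect_true(all(gs_wide >= gs - 1e-12))
})

test_that("promoter windows span 2000 up / 500 down on either strand", {
  genes <- data.frame(gene_id = c("gP", "gM", "gEdge"), chrom = "chr1",
                      tss = c(10000L, 10000L, 100L), strand = c("+", "-", "+"),
                      biotype = "protein_coding", is_mito = FALSE,
                      stringsAsFactors = FALSE)
  pw <- promoter_windows(genes)
  expect_identical(pw$start[1], 8000L)
  expect_identical(pw$end[1], 10500L)
  expect_identical(pw$start[2], 9501L)
  expect_identical(pw$end[2], 12001L)
  expect_identical(pw$end[1] - pw$start[1], 2500L)
  expect_identical(pw$end[2] - pw$start[2], 2500L)
  # clipped at chromosome start
  expect_identical(pw$start[3], 0L)
  expect_identical(pw$end[3], 600L)
})

consensus_pfm <- function(seq_str, depth = 100) {
  b <- match(strsplit(seq_str, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(2, 4, length(b))
  for (j in seq_along(b)) m[b[j], j] <- depth - 6
  rownames(m) <- c("A", "C", "G", "T")
  m
}

test_that("PWM scanning agrees with exhaustive window enumeration", {
  pfm <- consensus_pfm("ACGT")
  seq10 <- "GGACGTACGA"
  hits <- scan_pwm(seq10, pfm, all_windows = TRUE)
  expect_identical(nrow(hits), 14L)   # 7 offsets x 2 strands
  for (i in seq_len(nrow(hits))) {
    ora <- pwm_window_oracle(seq10, pfm, hits$match_start[i], hits$strand[i])
    expect_equal(hits$log_odds[i], ora, tolerance = 1e-9)
  }
  # consensus window scores the attainable maximum
  best <- hits[hits$strand == "+", ]
  expect_equal(max(best$relative_score), 1.0, tolerance = 1e-12)
  expect_identical(best$match_start[which.max(best$relative_score)], 2L)
})

test_that("random sequencePWM pairs match the enumeration oracle exactly", {
  set.seed(17)
  for (rep in 1:50) {
    w <- sample(4:9, 1)
    pfm <- matrix(rpois(4 * w, 20) + 1, 4, w,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    s <- paste(sample(c("A", "C", "G", "T"), w + sample(3:12, 1), TRUE),
               collapse = "")
    hits <- scan_pwm(s, pfm, all_windows = TRUE)
    for (i in seq_len(nrow(hits))) {
      expect_equal(hits$log_odds[i],
                   pwm_window_oracle(s, pfm, hits$match_start[i], hits$strand[i]),
                   tolerance = 1e-9)
    }
  }
})

test_that("a motif match is found identically on the reverse strand", {
  pfm <- consensus_pfm("ACGTACGA")
  fwd <- scan_pwm("TTACGTACGATT", pfm, all_windows = TRUE)
  rc <- scan_pwm("AATCGTACGTAA", pfm, all_windows = TRUE)  # revcomp sequence
  expect_equal(max(fwd$log_odds[fwd$strand == "+"]),
               max(rc$log_odds[rc$strand == "-"]), tolerance = 1e-12)
  # windows containing N are skipped
  nn <- scan_pwm("NNACGTACGANN", pfm, all_windows = TRUE)
  expect_identical(nrow(nn), 2L)
  expect_error(scan_pwm("ACG", pfm), "wider")
})

test_that("network edges require both thresholds and map planted sites", {
  pfm <- consensus_pfm("ACGTACGA")
  pad <- function(k) strrep("N", k)
  # three planted consensus sites at known offsets in two promoters
  seqs <- c(gT1 = paste0(pad(10), "ACGTACGA", pad(10), "ACGTACGA", pad(4)),
            gT2 = paste0(pad(25), "ACGTACGA", pad(7)),
            gT3 = pad(40))
  genes <- data.frame(gene_id = names(seqs), chrom = "chr1", tss = 5000L,
                      strand = "+", biotype = "protein_coding", is_mito = FALSE,
                      stringsAsFactors = FALSE)
  motifs <- motif_set("M1", "TF1", list(pfm))
  net <- build_network(motifs, genes, seqs, target_gene_set = names(seqs))
  expect_identical(nrow(net), 3L)
  expect_setequal(net$match_start[net$target_gene_id == "gT1"], c(10L, 28L))
  expect_identical(net$match_start[net$target_gene_id == "gT2"], 25L)
  expect_true(all(net$relative_score > 0.85 & net$log_odds > 8))
  expect_identical(nrow(build_network(motifs, genes, seqs, character())), 0L)
  expect_warning(build_network(motifs, genes, seqs, c("gT2", "missing")),
                 "missing")
})

test_that("edge thresholds are strict at 0.85 homology and log-odds 8", {
  hits <- data.frame(relative_score = c(0.851, 0.849, 0.851, 0.900),
                     log_odds = c(8.01, 9.00, 7.99, 8.50))
  kept <- filter_pwm_hits(hits)
  expect_identical(rownames(kept), c("1", "4"))
})

test_that("regulator matching calls affine relationships and controls nulls", {
  set.seed(23)
  n_s <- 30
  z <- matrix(rnorm(101 * n_s), 101, n_s,
              dimnames = list(sprintf("M%03d", 1:101), NULL))
  scores <- matrix(rnorm(n_s * 101), n_s, 101,
                   dimnames = list(NULL, sprintf("tf%03d", 1:101)))
  scores[, 1] <- 3 * z[1, ] + 2          # motif 1: exact affine match
  dev <- structure(list(z_dev = z), class = "deviation_result")
  map <- stats::setNames(sprintf("tf%03d", 1:101), sprintf("M%03d", 1:101))
  res <- match_regulators(dev, scores, map)
  expect_equal(res$correlation[res$motif_id == "M001"], 1, tolerance = 1e-12)
  expect_true(res$is_positive_regulator[res$motif_id == "M001"])
  # 100 independent noise motifs: positive-call rate within the FDR target
  nulls <- res[res$motif_id != "M001", ]
  expect_lte(mean(nulls$is_positive_regulator), 0.05)
  # equivariant under joint permutation of the sample order
  perm <- sample(n_s)
  dev_p <- structure(list(z_dev = z[, perm]), class = "deviation_result")
  res_p <- match_regulators(dev_p, scores[perm, ], map)
  m <- match(res$motif_id, res_p$motif_id)
  expect_equal(res$correlation, res_p$correlation[m], tolerance = 1e-12)
  # unmapped motifs are skipped with a warning
  expect_warning(match_regulators(dev, scores, map[-5]), "M005")
})

test_that("planted regulators are recovered from the synthetic fixture", {
  sim <- small_sim(1)
  pb <- make_pseudobulks(sim$dataset, group_size = 25)
  bg <- background_peaks(sim$dataset$peaks, pb$atac_agg, seed = 3)
  dev <- bias_corrected_z(pb$atac_agg, sim$motifs, bg)
  gs <- gene_scores(pb, sim$dataset$genes, sim$dataset$peaks)
  res <- match_regulators(dev, gs, sim$truth$tf_gene_map)
  k <- length(sim$truth$planted_regulators)
  expect_setequal(res$motif_id[seq_len(k)], sim$truth$planted_regulators)
  expect_true(all(res$is_positive_regulator[seq_len(k)]))
})
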