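test_that("expected fractions are total-count shares summing to one", {
  atac <- rbind(c(4, 10), c(6, 20))
  expect_equal(expected_fraction(atac), c(0.25, 0.75))
  u <- matrix(7, 3, 5)
  expect_equal(expected_fraction(u), rep(0.2, 5))
  set.seed(3)
  m <- matrix(rpois(24, 9), 4, 6)
  expect_equal(sum(expected_fraction(m)), 1, tolerance = 1e-12)
  expect_error(expected_fraction(matrix(0, 2, 2)), "all-zero")
})

test_that("raw deviation matches hand computation and its invariances", {
  atac <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(raw_deviation(atac, 1), c(-0.5, 0.5))
  # the all-peaks set deviates by exactly zero
  expect_equal(raw_deviation(atac, 1:3), c(0, 0))
  # doubling all counts changes nothing
  expect_equal(raw_deviation(atac * 2, 1), raw_deviation(atac, 1))
  # scaling one sample's counts changes nothing once the expectation is held
  # fixed (the expectation itself is depth-weighted, so it is supplied here)
  atac2 <- atac; atac2[2, ] <- atac2[2, ] * 5
  e <- expected_fraction(atac)
  expect_equal(raw_deviation(atac2, 1, expectation = e),
               raw_deviation(atac, 1, expectation = e))
})

test_that("background draws exclude self, reproduce under a seed, and match GC", {
  sim <- small_sim(1)
  pb <- make_pseudobulks(sim$dataset, group_size = 25)
  bg <- background_peaks(sim$dataset$peaks, pb$atac_agg, n_bg = 20, seed = 4)
  expect_identical(dim(bg), c(600L, 20L))
  expect_true(all(bg != row(bg)[, 1]))
  bg2 <- background_peaks(sim$dataset$peaks, pb$atac_agg, n_bg = 20, seed = 4)
  expect_identical(bg, bg2)
  # matched-moment check: background GC tracks the foreground peak's GC
  gc <- sim$dataset$peaks$gc
  bg_gc <- matrix(gc[bg], nrow(bg))
  expect_lt(stats::median(abs(rowMeans(bg_gc) - gc)), 0.05)
  # degenerate covariates fall back to uniform sampling with a warning
  ident <- sim$dataset$peaks; ident$gc <- 0.5
  flat <- matrix(5L, 4, nrow(ident))
  expect_warning(bgu <- background_peaks(ident, flat, n_bg = 5, seed = 1),
                 "uniform")
  expect_true(all(bgu != row(bgu)[, 1]))
})

test_that("bias-corrected z matches a brute-force enumeration on a toy", {
  atac <- matrix(c(5, 1, 9, 2,
                   3, 7, 2, 8,
                   6, 2, 4, 3,
                   1, 9, 2, 7,
                   4, 4, 5, 5), nrow = 4, ncol = 5)
  pm <- cbind(m1 = c(TRUE, TRUE, FALSE, FALSE, FALSE),
              m2 = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  bg <- rbind(c(3, 4, 5), c(4, 5, 1), c(2, 5, 1), c(5, 2, 3), c(1, 2, 4))
  dev <- bias_corrected_z(atac, pm, bg)

  e <- colSums(atac) / sum(atac)
  depth <- rowSums(atac)
  for (m in 1:2) {
    members <- which(pm[, m])
    rd <- function(set) {
      o <- rowSums(atac[, set, drop = FALSE])
      x <- depth * sum(e[set])
      (o - x) / x
    }
    raw <- rd(members)
    bgdevs <- sapply(1:3, function(b) rd(bg[members, b]))
    z <- (raw - rowMeans(bgdevs)) / apply(bgdevs, 1, sd)
    expect_equal(unname(dev$raw_dev[m, ]), unname(raw), tolerance = 1e-9)
    expect_equal(unname(dev$z_dev[m, ]), unname(z), tolerance = 1e-9)
    expect_equal(unname(dev$variability[m]), sd(z), tolerance = 1e-9)
  }
})

test_that("background-duplicate peaks are counted with multiplicity", {
  atac <- matrix(c(2, 1, 4, 3, 1, 5, 2, 2), 2, 4)
  pm <- cbind(m1 = c(TRUE, TRUE, FALSE, FALSE))
  bg <- rbind(c(3, 3), c(3, 4), c(1, 2), c(2, 1))  # both members -> peak 3 in draw 1
  dev <- bias_corrected_z(atac, pm, bg)
  e <- colSums(atac) / sum(atac)
  depth <- rowSums(atac)
  raw <- (rowSums(atac[, 1:2]) - depth * sum(e[1:2])) / (depth * sum(e[1:2]))
  # draw 1: {3, 3} counts peak 3 twice; draw 2: {3, 4}
  b1 <- (2 * atac[, 3] - depth * 2 * e[3]) / (depth * 2 * e[3])
  b2 <- (atac[, 3] + atac[, 4] - depth * (e[3] + e[4])) / (depth * (e[3] + e[4]))
  z <- (raw - (b1 + b2) / 2) / apply(cbind(b1, b2), 1, sd)
  expect_equal(unname(dev$z_dev[1, ]), unname(z), tolerance = 1e-9)
})

test_that("null motifs score near zero and planted regulators are hypervariable", {
  sim <- small_sim(1)
  pb <- make_pseudobulks(sim$dataset, group_size = 25)
  bg <- background_peaks(sim$dataset$peaks, pb$atac_agg, seed = 2)
  dev <- bias_corrected_z(pb$atac_agg, sim$motifs, bg)
  planted <- sim$truth$planted_regulators
  nulls <- setdiff(rownames(dev$z_dev), planted)
  # motifs drawn from background-like peaks: mean z near 0
  expect_lt(max(abs(rowMeans(dev$z_dev[nulls, ], na.rm = TRUE))), 0.5)
  # planted regulators exceed the null variability range
  expect_true(all(dev$variability[planted] >
                    stats::quantile(dev$variability[nulls], 0.9)))
})

test_that("synergy and correlation behave on identical, opposing and disjoint sets", {
  sim <- small_sim(1)
  pb <- make_pseudobulks(sim$dataset, group_size = 25)
  bg <- background_peaks(sim$dataset$peaks, pb$atac_agg, seed = 2)
  pm <- sim$motifs$peak_match
  # append a clone of motif 1 and a set disjoint from it
  clone <- pm[, 1]
  disjoint <- !logical(nrow(pm)); disjoint[pm[, 1]] <- FALSE
  disjoint <- which(disjoint)[1:50]
  pm2 <- cbind(pm, clone = clone, disj = FALSE)
  pm2[disjoint, "disj"] <- TRUE
  dev <- bias_corrected_z(pb$atac_agg, pm2, bg)
  sc <- synergy_and_correlation(dev, pm2, n_sub = 50, seed = 9)

  expect_equal(diag(sc$correlation), rep(1, ncol(pm2)), ignore_attr = TRUE)
  expect_equal(sc$correlation, t(sc$correlation), tolerance = 1e-12)
  expect_equal(sc$correlation["M001", "clone"], 1, tolerance = 1e-12)
  # identical peak sets: intersection equals every same-size subset of the
  # union, so the synergy z sits exactly at the distributional center
  expect_equal(sc$synergy["M001", "clone"], 0)
  expect_true(is.na(sc$synergy["M001", "disj"]))
  # opposing planted programs anticorrelate
  expect_lt(sc$correlation["M001", "M002"], 0)
  # PSD up to numerical tolerance
  ev <- eigen(sc$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("differential deviations are antisymmetric and detect planted shifts", {
  set.seed(11)
  n_s <- 60
  z <- matrix(rnorm(20 * n_s), 20, dimnames = list(sprintf("M%02d", 1:20), NULL))
  groups <- rep(c("Ctrl", "LIP"), each = n_s / 2)
  z["M01", groups == "LIP"] <- z["M01", groups == "LIP"] + 1  # planted shift
  dev <- structure(list(z_dev = z), class = "deviation_result")

  res <- differential_deviation(dev, groups, case = "LIP")
  expect_true(res$p_adjusted[res$motif_id == "M01"] < 0.05)
  expect_gt(res$delta[res$motif_id == "M01"], 0.5)
  # null motifs: few BH-significant calls
  expect_lte(sum(res$p_adjusted[res$motif_id != "M01"] < 0.05), 1)
  # swapping case and control negates delta exactly
  res_sw <- differential_deviation(dev, groups, case = "Ctrl")
  m <- match(res$motif_id, res_sw$motif_id)
  expect_equal(res$delta, -res_sw$delta[m], tolerance = 1e-12)
  expect_equal(res$p_value, res_sw$p_value[m], tolerance = 1e-12)
  expect_error(differential_deviation(dev, rep("a", n_s)), "2 group")
})
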