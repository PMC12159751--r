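#' Specification for a synthetic multiome dataset
#'
#' Defines the study conditions emulated by [simulate_multiome()]: a
#' bifurcating hematopoietic-like trajectory (myeloid vs lymphoid branch)
#' with group-dependent branch bias, negative-binomial expression
#' programs, Poisson peak accessibility, planted peak-gene links and
#' planted positive TF regulators.
#'
#' @param n_cells,n_genes,n_peaks,n_motifs Dataset dimensions.
#' @param n_planted_links Number of peak-gene pairs with a real
#'   regulatory coupling.
#' @param n_planted_regulators Number of motifs planted as positive TF
#'   regulators (must be <= n_motifs).
#' @param branch_bias Named per-group probability of the myeloid branch.
#' @param rna_depth_mean,atac_depth_mean Mean library sizes (log-normal
#'   per-cell depths, sdlog 0.3).
#' @param nb_dispersion Shared NB size parameter for RNA counts.
#' @param link_effect Strength in (0, 1] with which a planted peak's
#'   accessibility tracks its partner gene's program; 0 disables the
#'   coupling entirely.
#' @param seed Integer seed; the whole draw is a deterministic function
#'   of the spec including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 2000, n_genes = 500, n_peaks = 5000,
                           n_motifs = 20, n_planted_links = 200,
                           n_planted_regulators = 3,
                           branch_bias = c(Ctrl = 0.4, LIP = 0.8),
                           rna_depth_mean = 5000, atac_depth_mean = 10000,
                           nb_dispersion = 2, link_effect = 0.9, seed = 1) {
  spec <- list(n_cells = n_cells, n_genes = n_genes, n_peaks = n_peaks,
               n_motifs = n_motifs, n_planted_links = n_planted_links,
               n_planted_regulators = n_planted_regulators,
               branch_bias = branch_bias,
               rna_depth_mean = rna_depth_mean, atac_depth_mean = atac_depth_mean,
               nb_dispersion = nb_dispersion, link_effect = link_effect,
               seed = as.integer(seed))
  if (n_planted_links > n_genes || n_planted_links > n_peaks) {
    stop("more planted links than genes or peaks", call. = FALSE)
  }
  if (n_planted_regulators > n_motifs) {
    stop("more planted regulators than motifs", call. = FALSE)
  }
  if (any(branch_bias < 0 | branch_bias > 1)) {
    stop("branch_bias must lie in [0, 1]", call. = FALSE)
  }
  if (link_effect < 0 || link_effect > 1) stop("link_effect must be in [0, 1]", call. = FALSE)
  if (n_peaks < n_genes + n_planted_links + 2 * n_motifs + 150 * n_planted_regulators) {
    stop("n_peaks too small for the planted structure", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

# smooth program value in [0, 1] for cells at (t, branch)
eval_program <- function(par, t, branch) {
  f <- switch(par$type,
              flat = rep(1, length(t)),
              ramp_up = stats::plogis((t - par$center) / par$scale),
              ramp_down = 1 - stats::plogis((t - par$center) / par$scale),
              bump = exp(-(t - par$center)^2 / (2 * 0.12^2)))
  if (par$branch != "both") f <- f * ifelse(branch == par$branch, 1, 0.1)
  f
}

random_program <- function(branches = c("both", "myeloid", "lymphoid")) {
  list(type = sample(c("ramp_up", "ramp_down", "bump"), 1),
       center = stats::runif(1, 0.2, 0.8),
       scale = stats::runif(1, 0.05, 0.15),
       branch = sample(branches, 1, prob = c(2, 1, 1)[seq_along(branches)]))
}

random_pfm <- function(width = 8, depth = 100) {
  consensus <- sample.int(4, width, replace = TRUE)
  m <- matrix(0, 4, width)
  for (j in seq_len(width)) {
    p <- rep(0.06, 4); p[consensus[j]] <- 0.82
    m[, j] <- as.numeric(stats::rmultinom(1, depth, p))
  }
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Simulate a multiome dataset with planted ground truth
#'
#' Draws a bifurcating trajectory: each cell gets latent pseudotime
#' `t ~ U(0, 1)` and a branch (myeloid with group-dependent probability
#' `branch_bias`). Gene programs are smooth in (t, branch) (logistic
#' ramps or Gaussian bumps, optionally branch-restricted); RNA counts are
#' negative-binomial around per-cell log-normal depths. Planted-link
#' peaks' accessibility rates track their partner gene's program with
#' weight `link_effect`; every gene also gets a flat decoy peak inside
#' the linking window, and further flat peaks fill intergenic space.
#' Each planted-regulator motif's peak set is >= 80% peaks tracking the
#' TF's own gene program (the three planted regulators get an early
#' rising, a closing, and a transient mid-trajectory program); its TF
#' gene additionally carries tracking promoter-proximal peaks so that
#' accessibility-derived gene scores follow the program. Observed
#' pseudotime is a rank-preserving Gaussian perturbation of t; trajectory
#' states are assigned from (t, branch) so that myeloid {1,3,4,5} and
#' lymphoid {1,3,4,6} fate sets are realizable. Cluster labels follow a
#' five-population hematopoietic layout (LSK -> GMP -> NeuP /
#' LSK -> CLP -> proB).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a `multiome_dataset`), `motifs` (a
#'   `motif_set` with `peak_match`), and `truth`: `planted_links`
#'   (peak_id, gene_id), `planted_regulators` (motif ids), `tf_gene_map`,
#'   `true_pseudotime`, `true_branch`.
#' @export
simulate_multiome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; G <- spec$n_genes; P <- spec$n_peaks; M <- spec$n_motifs

  ## cells -------------------------------------------------------------
  groups <- names(spec$branch_bias)
  group <- rep(groups, length.out = n)[sample.int(n)]
  t_true <- stats::runif(n)
  branch <- ifelse(stats::runif(n) < spec$branch_bias[group], "myeloid", "lymphoid")
  cluster <- ifelse(t_true < 0.3, "LSK",
                    ifelse(branch == "myeloid",
                           ifelse(t_true < 0.7, "GMP", "NeuP"),
                           ifelse(t_true < 0.7, "CLP", "proB")))
  state <- ifelse(t_true < 0.25, 1L,
                  ifelse(t_true < 0.5, 3L,
                         ifelse(t_true < 0.75, 4L,
                                ifelse(branch == "myeloid", 5L, 6L))))
  pt_obs <- rank(t_true + stats::rnorm(n, 0, 0.02), ties.method = "first") / n
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      group = group, cluster = cluster,
                      pseudotime = pt_obs, state = state,
                      stringsAsFactors = FALSE)

  ## gene programs ------------------------------------------------------
  gene_ids <- sprintf("gene%04d", seq_len(G))
  planted_genes <- sort(sample.int(G, spec$n_planted_links))
  tf_genes <- sort(sample(setdiff(seq_len(G), planted_genes), M))
  reg_tf_genes <- tf_genes[seq_len(spec$n_planted_regulators)]

  programs <- vector("list", G)
  dynamic <- logical(G)
  for (g in seq_len(G)) {
    if (g %in% planted_genes || stats::runif(1) < 0.4) {
      programs[[g]] <- random_program()
      dynamic[g] <- TRUE
    } else {
      programs[[g]] <- list(type = "flat", center = 0, scale = 1, branch = "both")
    }
  }
  # planted regulators get fixed, well-separated program shapes so their
  # motif activities are mutually distinguishable (incl. one opposing pair)
  reg_shapes <- list(list(type = "ramp_up", center = 0.5, scale = 0.1, branch = "both"),
                     list(type = "ramp_down", center = 0.5, scale = 0.1, branch = "both"),
                     list(type = "bump", center = 0.5, scale = 0.1, branch = "both"))
  for (r in seq_along(reg_tf_genes)) {
    programs[[reg_tf_genes[r]]] <- reg_shapes[[(r - 1L) %% 3L + 1L]]
    dynamic[reg_tf_genes[r]] <- TRUE
  }

  Fmat <- matrix(0, n, G)
  for (g in seq_len(G)) Fmat[, g] <- eval_program(programs[[g]], t_true, branch)

  base_g <- stats::rlnorm(G, 0, 0.5)
  amp <- ifelse(dynamic, 1, 0)
  rate_g <- sweep(0.15 + sweep(Fmat, 2, amp, "*"), 2, base_g, "*")

  is_mito <- rep(FALSE, G)
  mito_pick <- setdiff(which(!dynamic), c(planted_genes, tf_genes))
  is_mito[mito_pick[seq_len(min(10, length(mito_pick)))]] <- TRUE
  biotype <- rep("protein_coding", G)
  lnc <- sample(setdiff(seq_len(G), c(planted_genes, tf_genes, which(is_mito))),
                max(1, round(0.05 * G)))
  biotype[lnc] <- "lincRNA"
  oth <- setdiff(seq_len(G), c(planted_genes, tf_genes, which(is_mito), lnc))
  if (length(oth) >= 2) biotype[sample(oth, 2)] <- "other"

  ## genome layout: one chromosome, genes every 600 kb ------------------
  spacing <- 600000
  tss <- 300000 + (seq_len(G) - 1L) * spacing
  genes <- data.frame(gene_id = gene_ids, chrom = "chrS", tss = tss,
                      strand = rep(c("+", "-"), length.out = G),
                      biotype = biotype, is_mito = is_mito,
                      stringsAsFactors = FALSE)

  ## RNA counts ---------------------------------------------------------
  depth_rna <- stats::rlnorm(n, log(spec$rna_depth_mean) - 0.045, 0.3)
  p_g <- rate_g / rowSums(rate_g)
  mu_rna <- p_g * depth_rna
  rna <- matrix(stats::rnbinom(n * G, mu = mu_rna, size = spec$nb_dispersion), n, G)

  ## peaks ---------------------------------------------------------------
  half_width <- 250
  peak_mid <- numeric(0); peak_partner <- integer(0); peak_kind <- character(0)
  add_peaks <- function(mid, partner, kind) {
    peak_mid <<- c(peak_mid, mid)
    peak_partner <<- c(peak_partner, partner)
    peak_kind <<- c(peak_kind, rep(kind, length(mid)))
  }
  # planted link peaks, 1-250 kb from the partner TSS
  d_link <- round(stats::runif(spec$n_planted_links, 1000, 250000))
  sgn <- sample(c(-1, 1), spec$n_planted_links, replace = TRUE)
  add_peaks(tss[planted_genes] + sgn * d_link, planted_genes, "link")
  # promoter-proximal peaks for every TF gene (inside the 1 kb exclusion
  # zone of the linking window; tracking for planted regulators)
  for (g in tf_genes) {
    kind <- if (g %in% reg_tf_genes) "tf_promoter" else "tf_promoter_null"
    add_peaks(tss[g] + c(-400, 300), c(g, g), kind)
  }
  # regulator-motif tracking peaks in intergenic deserts
  desert_slot <- function(k) {
    host <- sample.int(G, k, replace = TRUE)
    tss[host] + round(stats::runif(k, 251000, 349000))
  }
  n_track <- 120L
  for (r in seq_along(reg_tf_genes)) {
    add_peaks(desert_slot(n_track), rep(reg_tf_genes[r], n_track), "tracking")
  }
  # one flat decoy inside every gene's linking window
  d_dec <- round(stats::runif(G, 1000, 250000))
  add_peaks(tss + sample(c(-1, 1), G, replace = TRUE) * d_dec, seq_len(G), "decoy")
  # remaining flat peaks in deserts
  n_rest <- P - length(peak_mid)
  add_peaks(desert_slot(n_rest), rep(NA_integer_, n_rest), "flat")

  peaks <- data.frame(peak_id = sprintf("peak%05d", seq_along(peak_mid)),
                      chrom = "chrS",
                      start = as.integer(peak_mid - half_width),
                      end = as.integer(peak_mid + half_width),
                      gc = stats::rbeta(length(peak_mid), 5, 5),
                      stringsAsFactors = FALSE)

  ## ATAC rates and counts ----------------------------------------------
  base_p <- stats::rlnorm(P, 0, 0.5)
  rate_p <- matrix(rep(base_p, each = n), n, P)
  link_idx <- which(peak_kind == "link")
  w <- spec$link_effect
  if (length(link_idx) && w > 0) {
    rate_p[, link_idx] <- rate_p[, link_idx] *
      ((1 - w) + w * Fmat[, peak_partner[link_idx], drop = FALSE])
  }
  dyn_idx <- which(peak_kind %in% c("tracking", "tf_promoter"))
  rate_p[, dyn_idx] <- rate_p[, dyn_idx] *
    (0.1 + 0.9 * Fmat[, peak_partner[dyn_idx], drop = FALSE])

  depth_atac <- stats::rlnorm(n, log(spec$atac_depth_mean) - 0.045, 0.3)
  p_p <- rate_p / rowSums(rate_p)
  atac <- matrix(stats::rpois(n * P, p_p * depth_atac), n, P)

  ds <- multiome_dataset(rna, atac, cells, genes, peaks)

  ## motifs ---------------------------------------------------------------
  motif_ids <- sprintf("M%03d", seq_len(M))
  pfms <- lapply(seq_len(M), function(i) random_pfm())
  flat_pool <- which(peak_kind %in% c("decoy", "flat", "tf_promoter_null"))
  pm <- matrix(FALSE, P, M, dimnames = list(peaks$peak_id, motif_ids))
  set_size <- 150L
  for (m in seq_len(M)) {
    if (m <= spec$n_planted_regulators) {
      own <- which(peak_kind == "tracking" & peak_partner == reg_tf_genes[m])
      pm[c(own, sample(flat_pool, set_size - length(own))), m] <- TRUE
    } else {
      pm[sample(flat_pool, set_size), m] <- TRUE
    }
  }
  motifs <- motif_set(motif_ids, gene_ids[tf_genes], pfms, peak_match = pm)

  truth <- list(planted_links = data.frame(peak_id = peaks$peak_id[link_idx],
                                           gene_id = gene_ids[peak_partner[link_idx]],
                                           stringsAsFactors = FALSE),
                planted_regulators = motif_ids[seq_len(spec$n_planted_regulators)],
                tf_gene_map = stats::setNames(gene_ids[tf_genes], motif_ids),
                true_pseudotime = t_true, true_branch = branch)
  list(dataset = ds, motifs = motifs, truth = truth, spec = spec)
}

#' Write a synthetic fixture to disk
#'
#' Emits the full on-disk layout: the five [write_multiome()] files, the
#' motif PFMs (JASPAR text), the motif-peak membership matrix (MTX), the
#' ground truth (JSON), and a `manifest.json` recording the seed, file
#' list and matrix totals for integrity checking.
#'
#' @param sim Result of [simulate_multiome()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_multiome(sim$dataset, out_dir)
  jaspar <- file.path(out_dir, "motifs.jaspar")
  write_jaspar(sim$motifs, jaspar)
  match_mtx <- file.path(out_dir, "motif_peaks.mtx")
  Matrix::writeMM(as_sparse_mm(sim$motifs$peak_match * 1), match_mtx)
  truth_json <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, truth_json, auto_unbox = TRUE, digits = NA)

  files <- c(paths, motifs_jaspar = jaspar, motif_peaks_mtx = match_mtx,
             ground_truth_json = truth_json)
  manifest <- list(seed = sim$spec$seed,
                   n_cells = nrow(sim$dataset$rna),
                   n_genes = ncol(sim$dataset$rna),
                   n_peaks = ncol(sim$dataset$atac),
                   n_motifs = length(sim$motifs$motif_ids),
                   rna_total = sum(sim$dataset$rna),
                   atac_total = sum(sim$dataset$atac),
                   n_files = length(files),
                   files = as.list(stats::setNames(basename(files), names(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Reload a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `dataset`, `motifs` (with `peak_match`), `truth`,
#'   `manifest`.
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  ds <- read_multiome(file.path(dir, "rna.mtx"), file.path(dir, "atac.mtx"),
                      file.path(dir, "cells.tsv"), file.path(dir, "genes.tsv"),
                      file.path(dir, "peaks.bed"))
  motifs <- read_jaspar(file.path(dir, "motifs.jaspar"))
  pm <- as.matrix(Matrix::readMM(file.path(dir, "motif_peaks.mtx"))) != 0
  dimnames(pm) <- list(ds$peaks$peak_id, motifs$motif_ids)
  motifs$peak_match <- pm
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  list(dataset = ds, motifs = motifs, truth = truth, manifest = manifest)
}
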