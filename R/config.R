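#' Default analysis parameters
#'
#' Every threshold used by the pipeline, with its default. QC: cells need
#' >= 200 detected genes, <= 25% mitochondrial fraction, and ATAC totals
#' within [1000, 50000]. Markers: natural-log fold change > 0.25 and
#' expressing fraction > 0.25. Linking: 50-cell pseudobulks, peaks 1-250 kb
#' from the TSS, |PCC| >= 0.3 with P < 0.05, k-means k = 6. Fate stacks use
#' 50 pseudotime bins. Networks: promoter windows 2000 bp upstream / 500 bp
#' downstream, PWM matches kept at relative score > 0.85 and log-odds > 8.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    min_features       = 200,
    max_mito_frac      = 0.25,
    min_fragments      = 1000,
    max_fragments      = 50000,
    logfc_min          = 0.25,
    min_pct            = 0.25,
    pseudobulk_size    = 50,
    n_fate_bins        = 50,
    link_min_dist      = 1000,
    link_max_dist      = 250000,
    pcc_min            = 0.3,
    p_max              = 0.05,
    k_clusters         = 6,
    n_background       = 50,
    gene_score_window  = 100000,
    gene_score_decay   = 5000,
    regulator_r_min    = 0.5,
    regulator_fdr_max  = 0.05,
    promoter_up        = 2000,
    promoter_down      = 500,
    pwm_rel_min        = 0.85,
    pwm_score_min      = 8
  )
}

#' Load pipeline configuration
#'
#' Reads a `key: value` YAML file and overlays it on [default_config()].
#' Any key absent from the file keeps its default; unknown keys are an
#' error. The returned object is treated as immutable by the pipeline.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A named list of class `regdyn_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s\nvalid keys: %s",
                   paste(unknown, collapse = ", "),
                   paste(names(cfg), collapse = ", ")), call. = FALSE)
    }
    for (k in names(user)) {
      v <- user[[k]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        stop(sprintf("config key '%s' must be a single finite number, got '%s'",
                     k, paste(v, collapse = ",")), call. = FALSE)
      }
      cfg[[k]] <- v
    }
  }
  structure(cfg, class = "regdyn_config")
}

#' @export
print.regdyn_config <- function(x, ...) {
  cat("regdyn_config:\n")
  for (k in names(x)) cat(sprintf("  %-18s %g\n", k, x[[k]]))
  invisible(x)
}
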