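#' Read a multiome dataset from disk
#'
#' Expects the on-disk layout written by [write_multiome()]: two
#' matrix-market count matrices with cells as rows, tab-separated cell and
#' gene annotation tables with a header row, and a BED-style peak file
#' (`chrom start end name gc strand`, 0-based half-open).
#'
#' @param rna_mtx,atac_mtx Paths to MatrixMarket count matrices
#'   (cells x genes and cells x peaks).
#' @param cells_tsv,genes_tsv Paths to annotation TSVs.
#' @param peaks_bed Path to the peak BED file.
#' @return A validated [multiome_dataset()].
#' @export
read_multiome <- function(rna_mtx, atac_mtx, cells_tsv, genes_tsv, peaks_bed) {
  for (f in c(rna_mtx, atac_mtx, cells_tsv, genes_tsv, peaks_bed)) {
    if (!file.exists(f)) stop(sprintf("file not found: %s", f), call. = FALSE)
  }
  rna <- methods::as(Matrix::readMM(rna_mtx), "CsparseMatrix")
  atac <- methods::as(Matrix::readMM(atac_mtx), "CsparseMatrix")
  cells <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_tsv, stringsAsFactors = FALSE)
  peaks <- read_peaks_bed(peaks_bed)

  if (nrow(rna) != nrow(cells)) {
    stop(sprintf("%s declares %d cell rows but %s has %d cells",
                 rna_mtx, nrow(rna), cells_tsv, nrow(cells)), call. = FALSE)
  }
  if (ncol(rna) != nrow(genes)) {
    stop(sprintf("%s declares %d gene columns but %s has %d genes",
                 rna_mtx, ncol(rna), genes_tsv, nrow(genes)), call. = FALSE)
  }
  if (nrow(atac) != nrow(cells)) {
    stop(sprintf("%s declares %d cell rows but %s has %d cells",
                 atac_mtx, nrow(atac), cells_tsv, nrow(cells)), call. = FALSE)
  }
  if (ncol(atac) != nrow(peaks)) {
    stop(sprintf("%s declares %d peak columns but %s has %d peaks",
                 atac_mtx, ncol(atac), peaks_bed, nrow(peaks)), call. = FALSE)
  }
  if (!is.null(cells$pseudotime)) cells$pseudotime <- as.numeric(cells$pseudotime)
  if (!is.null(cells$state)) cells$state <- as.integer(cells$state)
  genes$is_mito <- as.logical(genes$is_mito)
  multiome_dataset(rna, atac, cells, genes, peaks)
}

#' Write a multiome dataset to disk
#'
#' @param ds A `multiome_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the five file paths.
#' @export
write_multiome <- function(ds, dir) {
  stopifnot(inherits(ds, "multiome_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rna_mtx = file.path(dir, "rna.mtx"),
             atac_mtx = file.path(dir, "atac.mtx"),
             cells_tsv = file.path(dir, "cells.tsv"),
             genes_tsv = file.path(dir, "genes.tsv"),
             peaks_bed = file.path(dir, "peaks.bed"))
  Matrix::writeMM(as_sparse_mm(ds$rna), paths["rna_mtx"])
  Matrix::writeMM(as_sparse_mm(ds$atac), paths["atac_mtx"])
  write_tsv(ds$cells, paths["cells_tsv"])
  write_tsv(ds$genes, paths["genes_tsv"])
  bed <- data.frame(chrom = ds$peaks$chrom, start = ds$peaks$start,
                    end = ds$peaks$end, name = ds$peaks$peak_id,
                    score = format(ds$peaks$gc, digits = 15),
                    strand = ".")
  utils::write.table(bed, paths["peaks_bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

as_sparse_mm <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

read_peaks_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 5) stop(sprintf("%s: expected >= 5 BED columns", path), call. = FALSE)
  data.frame(peak_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
             gc = as.numeric(bed[[5]]), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, format(x, digits = 15)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read motifs in JASPAR text format
#'
#' Parses the JASPAR 2016+ PFM flat-file format: a `>ID NAME` header line
#' followed by four rows of per-position counts, one per base, e.g.
#' `A [ 10 5 0 ]`. Bare count rows without the base letter and brackets
#' are accepted; base order must be A, C, G, T.
#'
#' @param pfm_path Path to the motif file.
#' @return A [motif_set()] (without `peak_match`). An empty file yields an
#'   empty set with a warning.
#' @export
read_jaspar <- function(pfm_path) {
  if (!file.exists(pfm_path)) stop(sprintf("file not found: %s", pfm_path), call. = FALSE)
  lines <- readLines(pfm_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("%s contains no motifs", pfm_path))
    return(motif_set(character(), character(), list()))
  }
  hdr <- grep("^>", lines)
  if (!length(hdr) || hdr[1] != 1) {
    stop(sprintf("%s: expected a '>' header on line 1", pfm_path), call. = FALSE)
  }
  ids <- character(0); tfs <- character(0); pfms <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1]]
    ids <- c(ids, h[1])
    tfs <- c(tfs, if (length(h) >= 2) h[2] else h[1])
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      stop(sprintf("%s: motif %s has %d base rows (need 4) near line %d",
                   pfm_path, h[1], length(body), hdr[i]), call. = FALSE)
    }
    rows <- lapply(seq_along(body), function(j) {
      txt <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[|\\]", "", body[j])
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[ \t]+")[[1]]))
      if (anyNA(vals) || !length(vals)) {
        stop(sprintf("%s: malformed base row on line %d", pfm_path, hdr[i] + j),
             call. = FALSE)
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      stop(sprintf("%s: motif %s has ragged base rows", pfm_path, h[1]), call. = FALSE)
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    pfms[[length(pfms) + 1L]] <- m
  }
  motif_set(ids, tfs, pfms)
}

#' Write motifs in JASPAR text format
#'
#' @param motifs A `motif_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(motifs, path) {
  stopifnot(inherits(motifs, "motif_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(motifs$motif_ids)) {
    writeLines(sprintf(">%s %s", motifs$motif_ids[i], motifs$tf_names[i]), con)
    p <- motifs$pfms[[i]]
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b, paste(format(p[b, ], trim = TRUE),
                                               collapse = " ")), con)
    }
  }
  invisible(path)
}
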