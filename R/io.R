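#' Write a genotype matrix with its KO-threshold sidecar
#'
#' Emits the strain x KO bitscore matrix as TSV (first column `strain_id`)
#' and the per-KO adaptive thresholds as a two-column sidecar TSV.
#'
#' @param genotypes a `genotype_matrix` (see [simulate_genotypes()]).
#' @param path path of the matrix TSV; the sidecar gets the suffix
#'   `.thresholds.tsv`.
#' @return paths written, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(strain_id = rownames(genotypes$bitscore),
                   genotypes$bitscore, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(path, ".thresholds.tsv")
  utils::write.table(
    data.frame(ko = names(genotypes$threshold),
               threshold = unname(genotypes$threshold)),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, side))
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param path matrix TSV path (sidecar expected at `<path>.thresholds.tsv`).
#' @return a `genotype_matrix` list with `bitscore`, `threshold`, `presence`
#'   (bitscore >= threshold).
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  bits <- as.matrix(df[, -1, drop = FALSE])
  rownames(bits) <- df$strain_id
  side <- utils::read.delim(paste0(path, ".thresholds.tsv"), sep = "\t")
  threshold <- stats::setNames(side$threshold, side$ko)[colnames(bits)]
  structure(list(bitscore = bits, threshold = threshold,
                 presence = sweep(bits, 2, threshold, `>=`)),
            class = "genotype_matrix")
}

#' Write a genome annotation as a flat TSV
#'
#' KO label sets are comma-joined in a `kos` column; [read_annotation()]
#' restores the list-column. Coordinates are 1-based inclusive.
#'
#' @param ann a `genome_annotation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  flat <- ann
  flat$kos <- vapply(ann$kos, paste, "", collapse = ",")
  utils::write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genome annotation written by [write_annotation()]
#' @param path TSV path.
#' @return a `genome_annotation` data.frame with `kos` list-column.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = c(kos = "character"))
  df$kos <- lapply(strsplit(df$kos, ",", fixed = TRUE),
                   function(k) k[nzchar(k)])
  df <- df[order(df$genome, df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genome_annotation", "data.frame")
  df
}
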