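#' Construct a strain-by-sample abundance table
#'
#' Container for per-sample strain relative abundances and (optionally)
#' horizontal genome coverage, together with the sample design metadata
#' (condition, passage, biological and technical replicate, or any other
#' pairing variables such as individual/site for in vivo data).
#'
#' @param samples data.frame of sample metadata. Must contain a `sample_id`
#'   column (unique) and a `condition` column; any further columns (e.g.
#'   `passage`, `bio_rep`, `tech_rep`, `individual`, `site`) are kept as-is.
#' @param rel_abundance numeric matrix, strains in rows, samples in columns
#'   (column names matching `samples$sample_id`). Entries are fractions; each
#'   column must sum to at most 1 + 1e-6.
#' @param h_coverage optional numeric matrix of horizontal genome coverage
#'   fractions, same dimnames as `rel_abundance`.
#' @param sum_tol slack allowed on the per-sample abundance sum above 1.
#'   Per-library input tables use the strict default; tables of
#'   technical-replicate medians (which are deliberately not renormalized)
#'   may exceed 1 slightly and are built with a relaxed tolerance.
#' @return An object of class `abundance_table`: a list with elements
#'   `samples`, `rel_abundance`, `h_coverage`.
#' @export
abundance_table <- function(samples, rel_abundance, h_coverage = NULL,
                            sum_tol = 1e-6) {
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "condition") %in% names(samples))) {
    stop("`samples` must have columns 'sample_id' and 'condition'")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in `samples`")
  rel_abundance <- as.matrix(rel_abundance)
  if (is.null(rownames(rel_abundance)) || is.null(colnames(rel_abundance))) {
    stop("`rel_abundance` needs strain rownames and sample colnames")
  }
  if (!identical(colnames(rel_abundance), samples$sample_id)) {
    stop("columns of `rel_abundance` must match samples$sample_id in order")
  }
  if (any(rel_abundance < 0)) stop("negative relative abundance")
  bad <- which(colSums(rel_abundance) > 1 + sum_tol)
  if (length(bad)) {
    stop("per-sample abundance sums exceed 1 in: ",
         paste(colnames(rel_abundance)[bad], collapse = ", "))
  }
  if (!is.null(h_coverage)) {
    h_coverage <- as.matrix(h_coverage)
    if (!identical(dimnames(h_coverage), dimnames(rel_abundance))) {
      stop("`h_coverage` dimnames must match `rel_abundance`")
    }
    if (any(h_coverage < 0) || any(h_coverage > 1)) {
      stop("horizontal coverage must lie in [0, 1]")
    }
  }
  structure(list(samples = samples, rel_abundance = rel_abundance,
                 h_coverage = h_coverage),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d strains x %d samples (%s coverage)\n",
              nrow(x$rel_abundance), ncol(x$rel_abundance),
              if (is.null(x$h_coverage)) "no" else "with"))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Strain ids of an abundance table
#' @param table an `abundance_table`
#' @return character vector of strain ids (row order preserved)
#' @export
strains <- function(table) rownames(table$rel_abundance)

#' Read a long-format abundance table
#'
#' Expects a tab-separated file with one row per (sample, strain) pair and at
#' least the columns `sample_id`, `condition`, `strain_id`, `rel_abundance`;
#' `h_coverage` and any design columns (`passage`, `bio_rep`, `tech_rep`, ...)
#' are carried into the sample metadata. Missing (sample, strain) combinations
#' are filled with 0.
#'
#' @param path path to the TSV file.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("sample_id", "condition", "strain_id", "rel_abundance")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(df$rel_abundance < 0 | df$rel_abundance > 1)
  if (length(bad)) {
    stop("rel_abundance outside [0, 1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("h_coverage" %in% names(df)) {
    bad <- which(df$h_coverage < 0 | df$h_coverage > 1)
    if (length(bad)) {
      stop("h_coverage outside [0, 1] at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  key <- paste(df$sample_id, df$strain_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sample, strain) row: ", gsub("\r", " / ", dup))
  }
  strain_ids <- unique(df$strain_id)
  meta_cols <- setdiff(names(df), c("strain_id", "rel_abundance", "h_coverage"))
  samples <- unique(df[meta_cols])
  rownames(samples) <- NULL
  if (anyDuplicated(samples$sample_id)) {
    stop("inconsistent metadata for a sample_id")
  }
  fill <- function(col) {
    m <- matrix(0, nrow = length(strain_ids), ncol = nrow(samples),
                dimnames = list(strain_ids, samples$sample_id))
    m[cbind(match(df$strain_id, strain_ids),
            match(df$sample_id, samples$sample_id))] <- df[[col]]
    m
  }
  abundance_table(samples, fill("rel_abundance"),
                  if ("h_coverage" %in% names(df)) fill("h_coverage") else NULL)
}

#' Write an abundance table in long format
#'
#' Inverse of [read_abundance_table()]: UTF-8, LF line endings, '.' decimal.
#'
#' @param table an `abundance_table`
#' @param path output TSV path
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  n_s <- nrow(table$rel_abundance); n_j <- ncol(table$rel_abundance)
  long <- data.frame(
    table$samples[rep(seq_len(n_j), each = n_s), , drop = FALSE],
    strain_id = rep(rownames(table$rel_abundance), times = n_j),
    rel_abundance = as.vector(table$rel_abundance),
    row.names = NULL, check.names = FALSE)
  if (!is.null(table$h_coverage)) long$h_coverage <- as.vector(table$h_coverage)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse technical replicates to their median
#'
#' Technical replicates (repeat libraries from the same culture tube) are
#' collapsed to their per-strain median abundance and coverage; biological
#' replicates (distinct tubes) stay separate. Grouping is over all sample
#' metadata columns except `sample_id` and `tech_rep`.
#'
#' @param table an `abundance_table` whose samples carry a `tech_rep` column.
#' @return an `abundance_table` with one sample per technical-replicate group.
#' @export
collapse_technical <- function(table) {
  meta <- table$samples
  if (!"tech_rep" %in% names(meta)) stop("samples have no 'tech_rep' column")
  group_cols <- setdiff(names(meta), c("sample_id", "tech_rep"))
  key <- do.call(paste, c(meta[group_cols], sep = "\r"))
  groups <- split(seq_len(nrow(meta)), key)
  # stable order: first occurrence of each group
  groups <- groups[order(vapply(groups, min, 1L))]
  med <- function(mat) {
    out <- vapply(groups, function(idx) {
      apply(mat[, idx, drop = FALSE], 1, stats::median)
    }, numeric(nrow(mat)))
    dimnames(out) <- list(rownames(mat), NULL)
    out
  }
  new_meta <- meta[vapply(groups, min, 1L), group_cols, drop = FALSE]
  new_meta <- cbind(sample_id = vapply(groups, function(idx) {
    paste(unlist(meta[idx[1], group_cols]), collapse = "_")
  }, ""), new_meta)
  rownames(new_meta) <- NULL
  ra <- med(table$rel_abundance)
  colnames(ra) <- new_meta$sample_id
  hc <- NULL
  if (!is.null(table$h_coverage)) {
    hc <- med(table$h_coverage)
    colnames(hc) <- new_meta$sample_id
  }
  # medians of replicate fractions need not sum to exactly 1; keep them as-is
  abundance_table(new_meta, ra, hc, sum_tol = 0.5)
}

#' Call strain detection per sample
#'
#' A strain is detected in a sample when its relative abundance strictly
#' exceeds `min_abund` AND its horizontal genome coverage strictly exceeds
#' `min_cov`. Defaults are the community-profiling cutoffs of 0.0001%
#' relative abundance (1e-6 as a fraction) and 1% horizontal coverage.
#'
#' @param table an `abundance_table` carrying horizontal coverage.
#' @param min_abund detection floor on relative abundance (fraction).
#' @param min_cov detection floor on horizontal coverage (fraction).
#' @return logical strain-by-sample presence matrix.
#' @export
detect <- function(table, min_abund = 1e-6, min_cov = 0.01) {
  if (min_abund < 0 || min_abund > 1 || min_cov < 0 || min_cov > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  if (is.null(table$h_coverage)) stop("detection requires horizontal coverage")
  table$rel_abundance > min_abund & table$h_coverage > min_cov
}

#' Per-sample strain richness
#'
#' @param presence logical presence matrix from [detect()].
#' @param groups optional factor/character vector (one per sample) over which
#'   median richness is additionally reported.
#' @return named integer vector of per-sample counts; when `groups` is given,
#'   a list with elements `per_sample` and `group_median`.
#' @export
richness <- function(presence, groups = NULL) {
  counts <- colSums(presence)
  if (is.null(groups)) return(counts)
  if (length(groups) != ncol(presence)) stop("`groups` length must equal #samples")
  list(per_sample = counts,
       group_median = vapply(split(counts, groups), stats::median, 1.0))
}

#' Prevalence filter for top prevalent strains
#'
#' Keeps strains observed above `min_abund` relative abundance in at least
#' `ceil(min_frac * n_samples)` samples (so the study design of 270 passaged
#' libraries at 10% / 0.01% keeps strains present in 27 or more samples).
#' Call on the table restricted to passaged samples.
#'
#' @param table an `abundance_table`.
#' @param min_abund abundance floor (fraction), strict inequality.
#' @param min_frac minimum fraction of samples, default 0.10.
#' @return character vector of retained strain ids, table order preserved.
#' @export
prevalence_filter <- function(table, min_abund = 1e-4, min_frac = 0.10) {
  n <- ncol(table$rel_abundance)
  if (n == 0) stop("empty abundance table")
  need <- ceiling(min_frac * n)
  hits <- rowSums(table$rel_abundance > min_abund)
  rownames(table$rel_abundance)[hits >= need]
}

#' Aggregate an abundance table at a taxonomic rank
#'
#' Sums strain relative abundances within each taxon per sample. Horizontal
#' coverage is dropped (undefined above strain level).
#'
#' @param table an `abundance_table`.
#' @param taxonomy data.frame with column `strain_id` plus rank columns
#'   (`phylum`, optionally `family`, `genus`).
#' @param rank which rank column to aggregate at.
#' @return an `abundance_table` with taxa as rows and no coverage.
#' @export
aggregate_taxon <- function(table, taxonomy, rank = "phylum") {
  if (!rank %in% names(taxonomy)) stop("taxonomy lacks rank column '", rank, "'")
  lab <- taxonomy[[rank]][match(rownames(table$rel_abundance),
                                taxonomy$strain_id)]
  if (anyNA(lab)) {
    stop("strains missing from taxonomy: ",
         paste(utils::head(rownames(table$rel_abundance)[is.na(lab)], 5),
               collapse = ", "))
  }
  agg <- rowsum(table$rel_abundance, group = lab, reorder = FALSE)
  abundance_table(table$samples, agg, NULL)
}
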