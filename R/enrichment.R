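#' Paired compartment log-ratio enrichment scores
#'
#' For each strain and each pairing-key combination (e.g. passage x
#' biological replicate), computes the natural-log ratio of relative
#' abundance in the numerator compartment over the denominator compartment.
#' Zeros are replaced, per sample, by half that sample's minimum nonzero
#' relative abundance (a sample-specific detection limit) before the log
#' transform. Strains absent from BOTH compartments of a pair get a missing
#' score: a ratio of two pseudo-counts carries no signal.
#'
#' Technical replicates must already be collapsed (see
#' [collapse_technical()]); each pairing key must identify exactly one sample
#' per compartment.
#'
#' @param table an `abundance_table`.
#' @param num_condition condition label of the numerator compartment (e.g.
#'   `"mucin-carrier"`).
#' @param den_condition condition label of the denominator compartment (e.g.
#'   `"mucin-supernatant"`).
#' @param pairing_keys metadata columns identifying a pair, default
#'   `c("passage", "bio_rep")`.
#' @param log_base base of the logarithm; the default natural log reports
#'   scores in nats. The mean/SD aggregate is invariant to this choice.
#' @return data.frame with columns `strain_id`, the pairing keys, and
#'   `score` (NA for double-zero pairs); attribute `pairing_keys` records the
#'   keys used.
#' @export
paired_log_ratios <- function(table, num_condition, den_condition,
                              pairing_keys = c("passage", "bio_rep"),
                              log_base = exp(1)) {
  meta <- table$samples
  missing_keys <- setdiff(pairing_keys, names(meta))
  if (length(missing_keys)) {
    stop("pairing key(s) absent from sample metadata: ",
         paste(missing_keys, collapse = ", "))
  }
  pick <- function(cond) meta[meta$condition == cond, , drop = FALSE]
  num_meta <- pick(num_condition); den_meta <- pick(den_condition)
  key_of <- function(m) do.call(paste, c(m[pairing_keys], sep = "\r"))
  num_key <- key_of(num_meta); den_key <- key_of(den_meta)
  if (anyDuplicated(num_key) || anyDuplicated(den_key)) {
    stop("a pairing key maps to more than one sample; collapse technical ",
         "replicates first")
  }
  keys <- union(num_key, den_key)
  unmatched <- c(setdiff(num_key, den_key), setdiff(den_key, num_key))
  if (length(unmatched)) {
    stop("pairing key(s) missing a compartment: ",
         paste(gsub("\r", "/", unmatched), collapse = ", "))
  }
  ra <- table$rel_abundance
  half_min <- apply(ra, 2, function(a) {
    nz <- a[a > 0]
    if (length(nz)) min(nz) / 2 else NA_real_
  })
  strain_ids <- rownames(ra)
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    s_num <- num_meta$sample_id[match(keys[i], num_key)]
    s_den <- den_meta$sample_id[match(keys[i], den_key)]
    a_num <- ra[, s_num]; a_den <- ra[, s_den]
    both_zero <- a_num == 0 & a_den == 0
    a_num[a_num == 0] <- half_min[s_num]
    a_den[a_den == 0] <- half_min[s_den]
    score <- log(a_num / a_den, base = log_base)
    score[both_zero] <- NA_real_
    km <- num_meta[match(keys[i], num_key), pairing_keys, drop = FALSE]
    out[[i]] <- data.frame(strain_id = strain_ids, km, score,
                           row.names = NULL, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "pairing_keys") <- pairing_keys
  res
}

#' Aggregate pair-level enrichment scores per strain
#'
#' The aggregate carrier-enrichment score of a strain is the mean over the
#' standard deviation (sample SD, n-1) of its non-missing pair scores in the
#' selected late passages — by default passages 3-6, which with three
#' biological replicates gives up to 12 scores per strain. Strains with fewer
#' than 2 usable scores, or zero SD, get a missing aggregate with a flag.
#'
#' @param scores pair-level data.frame from [paired_log_ratios()].
#' @param passages passages to include, default `3:6`; `NULL` keeps all pairs
#'   (used for designs without passages, e.g. in vivo individual x site).
#' @return data.frame with columns `strain_id`, `aggregate`, `n_pairs_used`,
#'   `flag` (`"ok"`, `"too_few"` or `"zero_sd"`).
#' @export
aggregate_enrichment <- function(scores, passages = 3:6) {
  if (!is.null(passages)) {
    if (!"passage" %in% names(scores)) {
      stop("scores carry no 'passage' column; use passages = NULL")
    }
    scores <- scores[scores$passage %in% passages, , drop = FALSE]
  }
  per <- split(scores$score, scores$strain_id)
  # preserve first-appearance strain order
  per <- per[unique(scores$strain_id)]
  agg <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) return(c(NA_real_, n, 1))
    s <- stats::sd(v)
    if (s == 0) return(c(NA_real_, n, 2))
    c(mean(v) / s, n, 0)
  }
  m <- t(vapply(per, agg, numeric(3)))
  flags <- c("ok", "too_few", "zero_sd")[m[, 3] + 1]
  if (any(flags == "zero_sd")) {
    warning("zero-SD strains flagged with missing aggregate: ",
            paste(utils::head(names(per)[flags == "zero_sd"], 5), collapse = ", "))
  }
  data.frame(strain_id = names(per), aggregate = m[, 1],
             n_pairs_used = as.integer(m[, 2]), flag = flags,
             row.names = NULL)
}

#' Mucosa/lumen enrichment for in vivo paired samples
#'
#' Same statistic as the in vitro carrier score, with pairing over
#' (individual, site): per-pair log ratio of mucosal to lumen abundance with
#' the per-sample half-minimum zero replacement, then mean-over-SD across all
#' pairs (the reference design of 13 individuals x 3 sites yields 39 scores
#' per species).
#'
#' @param table an `abundance_table` whose conditions include the two
#'   compartments and whose metadata carries the pairing columns.
#' @param num_condition,den_condition compartment labels, default
#'   `"mucosa"` / `"lumen"`.
#' @param pairing_keys default `c("individual", "site")`.
#' @return list with elements `pairs` (pair-level scores) and `aggregate`
#'   (per-species aggregate data.frame).
#' @export
invivo_enrichment <- function(table, num_condition = "mucosa",
                              den_condition = "lumen",
                              pairing_keys = c("individual", "site")) {
  pairs <- paired_log_ratios(table, num_condition, den_condition, pairing_keys)
  list(pairs = pairs, aggregate = aggregate_enrichment(pairs, passages = NULL))
}

#' Write enrichment outputs as TSV
#'
#' @param pairs pair-level scores from [paired_log_ratios()].
#' @param aggregate aggregate scores from [aggregate_enrichment()].
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_enrichment <- function(pairs, aggregate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "enrichment_pairs.tsv")
  p2 <- file.path(dir, "enrichment_aggregate.tsv")
  utils::write.table(pairs, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(aggregate, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
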