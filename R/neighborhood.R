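#' KO annotation rule
#'
#' A gene receives a KO label when its profile-HMM hit covers strictly more
#' than `min_cov_frac` of the KO model AND its bitscore strictly exceeds
#' `min_bitscore_frac` times the KO's adaptive bitscore threshold.
#'
#' @param min_cov_frac minimum model-coverage fraction, default 0.5.
#' @param min_bitscore_frac minimum fraction of the KO threshold, default 0.5.
#' @return list with the two fields, class `ko_rule`.
#' @export
ko_rule <- function(min_cov_frac = 0.5, min_bitscore_frac = 0.5) {
  if (min_cov_frac <= 0 || min_cov_frac > 1 ||
      min_bitscore_frac <= 0 || min_bitscore_frac > 1) {
    stop("rule fractions must lie in (0, 1]")
  }
  structure(list(min_cov_frac = min_cov_frac,
                 min_bitscore_frac = min_bitscore_frac), class = "ko_rule")
}

#' Label genes with KO families from homology hits
#'
#' Consumes a long hits table (one row per gene x KO homology hit, the shape
#' of kofamscan output) and returns one row per gene with the set of
#' qualifying KO labels under the supplied [ko_rule()]. Genes whose hits all
#' fail the rule keep an empty label set. Coordinates are 1-based inclusive.
#'
#' @param hits data.frame with columns `genome`, `gene`, `contig`, `start`,
#'   `end`, `strand`, `ko`, `bitscore`, `cov_frac`, `ko_threshold`.
#' @param rule a [ko_rule()].
#' @return data.frame of class `genome_annotation`: columns `genome`, `gene`,
#'   `contig`, `start`, `end`, `strand` and list-column `kos`, sorted by
#'   (genome, contig, start).
#' @export
annotate_genes <- function(hits, rule = ko_rule()) {
  required <- c("genome", "gene", "contig", "start", "end", "strand",
                "ko", "bitscore", "cov_frac", "ko_threshold")
  missing <- setdiff(required, names(hits))
  if (length(missing)) {
    stop("hits table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(hits$cov_frac < 0 | hits$cov_frac > 1)) {
    stop("cov_frac outside [0, 1]")
  }
  if (any(hits$start >= hits$end)) stop("gene start must precede end")
  pass <- hits$cov_frac > rule$min_cov_frac &
    hits$bitscore > rule$min_bitscore_frac * hits$ko_threshold
  gene_key <- paste(hits$genome, hits$gene, sep = "\r")
  first <- !duplicated(gene_key)
  genes <- hits[first, c("genome", "gene", "contig", "start", "end", "strand")]
  labels <- lapply(split(ifelse(pass, hits$ko, NA_character_), gene_key),
                   function(k) sort(unique(k[!is.na(k)])))
  genes$kos <- unname(labels[gene_key[first]])
  genes <- genes[order(genes$genome, genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

# Internal: per-genome integer encoding for fast repeated counting.
# Returns list of genomes, each with start/end, contig integer codes,
# label sets as integer vectors, and the anchor flag per gene.
.nb_index <- function(ann, anchor_ko) {
  ko_levels <- sort(unique(unlist(ann$kos)))
  if (!anchor_ko %in% ko_levels) {
    stop("anchor KO '", anchor_ko, "' absent from every genome")
  }
  idx <- split(seq_len(nrow(ann)), ann$genome)
  genomes <- lapply(idx, function(i) {
    labs <- lapply(ann$kos[i], function(k) match(k, ko_levels))
    list(start = ann$start[i], end = ann$end[i],
         contig = as.integer(factor(ann$contig[i])),
         labels = labs,
         has_anchor = vapply(labs, function(v) {
           match(anchor_ko, ko_levels) %in% v
         }, TRUE))
  })
  list(ko_levels = ko_levels, anchor = match(anchor_ko, ko_levels),
       genomes = genomes)
}

# Internal: per-KO counts for one genome under a label assignment `ord`
# (ord[i] = index of the label set sitting at gene position i).
# A gene inside the window union contributes each of its labels once;
# the anchor KO itself is excluded from the returned tallies.
.nb_genome_counts <- function(g, ord, window_bp, n_kos, anchor) {
  anchor_pos <- which(g$has_anchor[ord])
  if (!length(anchor_pos)) return(NULL)
  in_window <- logical(length(ord))
  for (ct in unique(g$contig[anchor_pos])) {
    on_ct <- g$contig == ct
    ap <- anchor_pos[g$contig[anchor_pos] == ct]
    lo <- g$start[ap] - window_bp
    hi <- g$end[ap] + window_bp
    # union of windows: a gene overlaps the union iff it overlaps any window
    for (k in seq_along(ap)) {
      in_window <- in_window | (on_ct & g$start <= hi[k] & g$end >= lo[k])
    }
  }
  labs <- unlist(g$labels[ord[in_window]])
  if (!length(labs)) return(NULL)
  cnt <- tabulate(labs, nbins = n_kos)
  cnt[anchor] <- 0L
  cnt
}

#' Observed KO counts in windows around an anchor gene family
#'
#' For every genome, takes the union of windows `[start - window_bp,
#' end + window_bp]` around each anchor-labeled gene (same contig), and
#' counts, per KO, the genes whose interval intersects that union — each
#' gene contributing each of its labels once per genome, summed across
#' genomes. Labels of anchor genes other than the anchor KO itself are
#' included; the anchor KO is not counted.
#'
#' @param ann a `genome_annotation` from [annotate_genes()].
#' @param anchor_ko KO id of the anchor family (e.g. `"K00441"`).
#' @param window_bp window half-width in bp, default 10000.
#' @return named integer vector of observed counts (KOs with count > 0).
#' @export
observed_counts <- function(ann, anchor_ko, window_bp = 10000) {
  ix <- .nb_index(ann, anchor_ko)
  total <- integer(length(ix$ko_levels))
  for (g in ix$genomes) {
    cnt <- .nb_genome_counts(g, seq_along(g$labels), window_bp,
                             length(ix$ko_levels), ix$anchor)
    if (!is.null(cnt)) total <- total + cnt
  }
  names(total) <- ix$ko_levels
  total[total > 0L]
}

#' Within-genome label-permutation test for neighborhood enrichment
#'
#' Tests, per KO, whether its observed co-occurrence within `window_bp` of
#' anchor-labeled genes exceeds a null distribution generated by randomly
#' reassigning gene label sets within each genome (gene positions fixed,
#' label sets move as units, anchor labels shuffled along with the rest).
#' The raw empirical p-value is the fraction of permutations whose count is
#' at least the observed count; a KO is called a hit when the observed count
#' strictly exceeds the permuted count in at least `ceil(0.99 * n_perm)`
#' permutations (the "990 or more out of 1000" rule). KOs never observed in
#' any window are skipped. An add-one-smoothed p-value is also reported.
#'
#' @param ann a `genome_annotation`.
#' @param anchor_ko anchor KO id.
#' @param window_bp window half-width in bp, default 10000.
#' @param n_perm number of permutations, default 1000 (minimum 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame: `ko`, `observed`, `p_raw`, `p_smoothed`, `hit`.
#' @export
permutation_test <- function(ann, anchor_ko, window_bp = 10000,
                             n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  ix <- .nb_index(ann, anchor_ko)
  n_kos <- length(ix$ko_levels)
  obs <- integer(n_kos)
  for (g in ix$genomes) {
    cnt <- .nb_genome_counts(g, seq_along(g$labels), window_bp, n_kos,
                             ix$anchor)
    if (!is.null(cnt)) obs <- obs + cnt
  }
  keep <- which(obs > 0L)
  ge <- integer(length(keep))  # #{permutations with null count >= observed}
  withr::local_seed(seed)
  for (j in seq_len(n_perm)) {
    null <- integer(n_kos)
    for (g in ix$genomes) {
      ord <- sample.int(length(g$labels))
      cnt <- .nb_genome_counts(g, ord, window_bp, n_kos, ix$anchor)
      if (!is.null(cnt)) null <- null + cnt
    }
    ge <- ge + (null[keep] >= obs[keep])
  }
  gt <- n_perm - ge  # observed strictly greater
  data.frame(ko = ix$ko_levels[keep], observed = obs[keep],
             p_raw = ge / n_perm,
             p_smoothed = (ge + 1) / (n_perm + 1),
             hit = gt >= ceiling(0.99 * n_perm),
             row.names = NULL)
}

#' Write neighborhood test results as TSV
#' @param result data.frame from [permutation_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
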