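#' KO presence profiles for biosynthetic gene clusters
#'
#' Attaches to each BGC the union of qualifying KO labels over its contained
#' genes, looked up in a labeled `genome_annotation` (see
#' [annotate_genes()], which applies the coverage/bitscore rule).
#'
#' @param bgcs data.frame with columns `bgc_id`, `genome`, `contig`, `start`,
#'   `end` and list-column `gene_ids` (gene ids contained in the cluster).
#' @param ann a `genome_annotation` whose `gene` ids resolve the BGC genes.
#' @return `bgcs` with a `kos` list-column of KO presence sets.
#' @export
bgc_ko_presence <- function(bgcs, ann) {
  pos <- lapply(bgcs$gene_ids, function(g) {
    i <- match(g, ann$gene)
    if (anyNA(i)) {
      stop("unresolved gene id(s): ", paste(g[is.na(i)], collapse = ", "))
    }
    i
  })
  bgcs$kos <- lapply(pos, function(i) sort(unique(unlist(ann$kos[i]))))
  bgcs
}

#' Filter and group BGCs by KO co-occurrence
#'
#' Drops BGCs with fewer than `min_kos` present KO families, computes
#' pairwise Jaccard distances on the binary KO presence profiles
#' (`1 - |A intersect B| / |A union B|`), and cuts an average-linkage
#' hierarchical clustering into `min(k_groups, n)` flat groups. BGCs are
#' processed in `bgc_id` order so the grouping is deterministic.
#'
#' @param bgcs data.frame with `bgc_id`, `genome` and list-column `kos`.
#' @param min_kos minimum KO presence count, default 3.
#' @param k_groups number of flat groups to cut, default 256.
#' @return list of class `bgc_groups`: `membership` (data.frame `bgc_id`,
#'   `genome`, `group`), `profiles` (per-group KO frequency, KO x group
#'   matrix of member fractions), `k` (number of groups).
#' @export
filter_and_cluster <- function(bgcs, min_kos = 3, k_groups = 256) {
  sizes <- lengths(bgcs$kos)
  keep <- bgcs[sizes >= min_kos, , drop = FALSE]
  if (!nrow(keep)) stop("no BGC passes the >= ", min_kos, " KO filter")
  keep <- keep[order(keep$bgc_id), , drop = FALSE]
  kos <- sort(unique(unlist(keep$kos)))
  mat <- matrix(0L, nrow(keep), length(kos),
                dimnames = list(keep$bgc_id, kos))
  for (i in seq_len(nrow(keep))) mat[i, keep$kos[[i]]] <- 1L
  k <- min(k_groups, nrow(keep))
  if (k == nrow(keep)) {
    grp <- seq_len(nrow(keep))
  } else {
    d <- stats::dist(mat, method = "binary")  # Jaccard distance on 0/1 rows
    hc <- stats::hclust(d, method = "average")
    grp <- unname(stats::cutree(hc, k = k))
  }
  membership <- data.frame(bgc_id = keep$bgc_id, genome = keep$genome,
                           group = grp, row.names = NULL)
  profiles <- vapply(seq_len(k), function(g) {
    colMeans(mat[grp == g, , drop = FALSE])
  }, numeric(length(kos)))
  dimnames(profiles) <- list(kos, paste0("group", seq_len(k)))
  structure(list(membership = membership, profiles = profiles, k = k),
            class = "bgc_groups")
}

#' Strain-by-group BGC presence matrix
#'
#' @param groups a `bgc_groups` object from [filter_and_cluster()].
#' @param strain_map named character vector mapping genome id -> strain id
#'   (identity mapping if genomes are strains).
#' @param all_strains optional full strain universe for the rows (strains
#'   with no BGC get all-zero rows).
#' @return binary strain x group matrix.
#' @export
group_presence <- function(groups, strain_map = NULL, all_strains = NULL) {
  mem <- groups$membership
  genome_strain <- if (is.null(strain_map)) {
    stats::setNames(unique(mem$genome), unique(mem$genome))
  } else strain_map
  unmapped <- setdiff(mem$genome, names(genome_strain))
  if (length(unmapped)) {
    stop("unmapped genome(s): ", paste(unmapped, collapse = ", "))
  }
  strain <- unname(genome_strain[mem$genome])
  rows <- if (is.null(all_strains)) unique(strain) else all_strains
  m <- matrix(0L, length(rows), groups$k,
              dimnames = list(rows, paste0("group", seq_len(groups$k))))
  m[cbind(match(strain, rows), mem$group)] <- 1L
  m
}

#' Association scan of BGC-group presence against a phenotype
#'
#' Delegates to [association_scan()] with the binary presence columns used
#' directly (no standardization: t and p are scale-invariant for a single
#' regressor).
#'
#' @param presence binary strain x group matrix from [group_presence()].
#' @param phenotype named per-strain phenotype vector.
#' @param tree [ape::phylo] tree.
#' @param fdr BH q-value cutoff, default 0.01.
#' @return data.frame of regression results (see [association_scan()]).
#' @export
bgc_association_scan <- function(presence, phenotype, tree, fdr = 0.01) {
  association_scan(presence, phenotype, tree, fdr = fdr, standardize = FALSE)
}
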