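#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-community generator. The defaults
#' mirror the study design this pipeline targets: paired carrier/supernatant
#' compartments sampled over six passages in biological triplicate with
#' technical triplicates, a Brownian strain trait on the community phylogeny,
#' and sparse planted genotype effects.
#'
#' @param n_strains number of strains (tree leaves), >= 3.
#' @param n_kos number of KO gene families in the genotype matrix.
#' @param n_causal number of causal KOs (<= n_kos).
#' @param effect_beta phenotype shift per standardized genotype unit.
#' @param bm_sigma2 Brownian rate of the latent trait (>= 0).
#' @param noise_sd residual SD (>= 0), used for both the phenotype residual
#'   and the per-sample compartment noise.
#' @param design data.frame of sample cells with columns `condition`,
#'   `passage`, `bio_rep`, `tech_rep`; rows must be unique.
#' @param detection_floor abundances below this fraction are zeroed.
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 64, n_kos = 2000, n_causal = 1,
                       effect_beta = 2, bm_sigma2 = 1, noise_sd = 0.1,
                       design = carrier_design(), detection_floor = 1e-6,
                       seed = 1) {
  if (n_strains < 3) stop("n_strains must be >= 3")
  if (n_causal > n_kos) stop("n_causal must not exceed n_kos")
  if (bm_sigma2 < 0 || noise_sd < 0) stop("rates and SDs must be >= 0")
  if (detection_floor < 0 || detection_floor > 1) {
    stop("detection_floor must be a fraction")
  }
  if (anyDuplicated(design)) stop("design cells must be unique")
  structure(list(n_strains = n_strains, n_kos = n_kos, n_causal = n_causal,
                 effect_beta = effect_beta, bm_sigma2 = bm_sigma2,
                 noise_sd = noise_sd, design = design,
                 detection_floor = detection_floor, seed = seed),
            class = "sim_config")
}

#' Paired carrier/supernatant sample design
#'
#' @param conditions compartment condition labels; must come in
#'   carrier/supernatant pairs sharing a prefix.
#' @param passages passage numbers, default 1:6.
#' @param bio_reps biological replicates, default 1:3.
#' @param tech_reps technical replicates, default 1:3.
#' @return data.frame with one row per sample cell.
#' @export
carrier_design <- function(conditions = c("mucin-carrier", "mucin-supernatant"),
                           passages = 1:6, bio_reps = 1:3, tech_reps = 1:3) {
  expand.grid(condition = conditions, passage = passages, bio_rep = bio_reps,
              tech_rep = tech_reps, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Simulate a pure-birth community phylogeny
#'
#' Draws a rooted binary Yule tree and rescales it so every root-to-tip path
#' has length 1 (unit-depth ultrametric). Leaves are labeled "S0001", ...
#'
#' @param n_leaves number of leaves, >= 3.
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_leaves, seed = 1) {
  if (n_leaves < 3) stop("n_leaves must be >= 3 (downstream PGLS needs it)")
  withr::local_seed(seed)
  tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("S%04d", seq_len(n_leaves))
  tr
}

# Internal: one Brownian draw per column on the tree (leaves x n matrix).
.bm_draws <- function(tree, n, sigma2 = 1) {
  C <- bm_covariance(tree)
  L <- .chol_or_jitter(C * sigma2)
  Z <- matrix(stats::rnorm(nrow(C) * n), nrow(C), n)
  out <- L %*% Z
  rownames(out) <- rownames(C)
  out
}

#' Simulate a bitscore genotype matrix with phylogenetic signal
#'
#' For each KO a latent Brownian trait on the tree is thresholded at its
#' `presence_rate` quantile to decide presence. Present strains draw a
#' bitscore of `threshold_k * (1 + |N(0.5, 0.1)|)`; absent strains draw
#' uniformly below half the threshold, so the adaptive-threshold labeling
#' rule separates the two groups.
#'
#' @param tree [ape::phylo] tree whose leaves are the strains.
#' @param n_kos number of KO columns.
#' @param presence_rate target presence fraction per KO, in (0, 1].
#' @param seed integer seed.
#' @return list of class `genotype_matrix`: `bitscore` (strain x KO matrix),
#'   `threshold` (per-KO adaptive thresholds), `presence` (logical matrix).
#' @export
simulate_genotypes <- function(tree, n_kos, presence_rate = 0.5, seed = 1) {
  if (length(tree$tip.label) < 3) stop("tree must have >= 3 leaves")
  if (presence_rate <= 0 || presence_rate > 1) {
    stop("presence_rate must lie in (0, 1]")
  }
  withr::local_seed(seed)
  latent <- .bm_draws(tree, n_kos)
  present <- apply(latent, 2, function(z) {
    z >= stats::quantile(z, 1 - presence_rate)
  })
  rownames(present) <- rownames(latent)
  threshold <- stats::runif(n_kos, 50, 500)
  n <- nrow(present)
  bits <- matrix(0, n, n_kos,
                 dimnames = list(rownames(present),
                                 sprintf("K%05d", seq_len(n_kos))))
  hi <- matrix(1 + abs(stats::rnorm(n * n_kos, 0.5, 0.1)), n, n_kos)
  lo <- matrix(stats::runif(n * n_kos, 0, 0.5), n, n_kos)
  bits[] <- sweep(ifelse(present, hi, lo), 2, threshold, `*`)
  names(threshold) <- colnames(bits)
  colnames(present) <- colnames(bits)
  structure(list(bitscore = bits, threshold = threshold, presence = present),
            class = "genotype_matrix")
}

#' Simulate the per-strain enrichment trait
#'
#' The true spatial-preference trait is the sum of a Brownian motion on the
#' tree (rate `bm_sigma2`), planted effects `beta * z_k` for each causal KO
#' (with `z_k` the standard-scaled presence indicator of KO k), and i.i.d.
#' Gaussian residual noise. This is exactly the generative model the PGLS
#' scan assumes, so effect recovery is unbiased by construction.
#'
#' @param tree [ape::phylo] tree.
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param causal_kos character vector of causal KO ids (subset of columns).
#' @param beta effect size per standardized presence unit.
#' @param bm_sigma2 Brownian rate.
#' @param noise_sd residual SD.
#' @param seed integer seed.
#' @return named numeric vector of traits (names = strain ids).
#' @export
simulate_phenotype <- function(tree, genotypes, causal_kos, beta = 2,
                               bm_sigma2 = 1, noise_sd = 0.1, seed = 1) {
  unknown <- setdiff(causal_kos, colnames(genotypes$bitscore))
  if (length(unknown)) {
    stop("unknown causal KO id(s): ", paste(unknown, collapse = ", "))
  }
  withr::local_seed(seed)
  ids <- tree$tip.label
  y <- stats::setNames(numeric(length(ids)), ids)
  if (bm_sigma2 > 0) y <- y + drop(.bm_draws(tree, 1, bm_sigma2))[ids]
  for (k in causal_kos) {
    pk <- as.numeric(genotypes$presence[ids, k])
    if (stats::sd(pk) == 0) {
      warning("causal KO ", k, " has constant presence; no effect planted")
      next
    }
    y <- y + beta * (pk - mean(pk)) / stats::sd(pk)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(ids), 0, noise_sd)
  y
}

#' Simulate a paired-compartment abundance table
#'
#' Baseline strain abundances are log-normal and shared across samples.
#' Carrier samples multiply the baseline by `exp(+trait/2 + eps)` and the
#' paired supernatant by `exp(-trait/2 + eps')` with independent
#' `eps ~ N(0, noise_sd^2)`, so the per-pair log abundance ratio equals the
#' trait in expectation. Conditions not ending in `-carrier`/`-supernatant`
#' (e.g. `no-carrier`, `inoculum`) receive the baseline with noise only.
#' Each sample is renormalized to sum 1, then abundances below
#' `detection_floor` are zeroed. Horizontal coverage is a logistic function
#' of log10 abundance (midpoint 1e-5, scale 0.15 decades, saturating at 1),
#' so the 1% coverage detection rule fails strains below roughly 2e-6
#' abundance while the 1e-6 abundance rule alone would keep them: both
#' failure modes of the joint detection rule occur.
#'
#' @param trait named per-strain trait vector (see [simulate_phenotype()]).
#' @param design sample-cell data.frame (see [carrier_design()]); carrier
#'   cells must have a supernatant partner sharing (passage, bio_rep,
#'   tech_rep).
#' @param noise_sd per-sample multiplicative log-noise SD.
#' @param detection_floor zeroing threshold on relative abundance.
#' @param seed integer seed.
#' @return an [abundance_table()].
#' @export
simulate_abundance <- function(trait, design, noise_sd = 0.1,
                               detection_floor = 1e-6, seed = 1) {
  compartment <- ifelse(
    design$condition %in% c("no-carrier", "inoculum"), "neutral",
    ifelse(grepl("-carrier$", design$condition), "carrier",
           ifelse(grepl("-supernatant$", design$condition), "supernatant",
                  "neutral")))
  pair_key <- function(rows, suffix) {
    d <- design[rows, , drop = FALSE]
    paste(sub(suffix, "", d$condition), d$passage, d$bio_rep, d$tech_rep,
          sep = "\r")
  }
  ck <- pair_key(compartment == "carrier", "-carrier$")
  sk <- pair_key(compartment == "supernatant", "-supernatant$")
  if (!setequal(ck, sk)) {
    stop("design is unpaired: every carrier cell needs a supernatant cell ",
         "sharing (passage, bio_rep, tech_rep), and vice versa")
  }
  withr::local_seed(seed)
  n <- length(trait)
  ids <- names(trait)
  # wide log-normal baseline: defined gut communities span ~5 orders of
  # magnitude in relative abundance
  baseline <- exp(stats::rnorm(n, log(1 / n), 3))
  shift <- c(carrier = 0.5, supernatant = -0.5, neutral = 0)[compartment]
  m <- nrow(design)
  eps <- matrix(stats::rnorm(n * m, 0, noise_sd), n, m)
  ra <- baseline * exp(outer(trait, shift) + eps)
  ra <- sweep(ra, 2, colSums(ra), `/`)
  sample_id <- sprintf("%s_P%s_B%s_T%s", design$condition, design$passage,
                       design$bio_rep, design$tech_rep)
  dimnames(ra) <- list(ids, sample_id)
  ra[ra < detection_floor] <- 0
  cov <- stats::plogis((log10(pmax(ra, .Machine$double.xmin)) + 5) / 0.15)
  cov[ra == 0] <- 0
  dimnames(cov) <- dimnames(ra)
  abundance_table(cbind(sample_id = sample_id, design), ra, cov)
}

#' Simulate genome annotations with planted KO colocalization
#'
#' Lays `genes_per_genome` genes on one contig per genome with fixed 1 kb
#' gene length and 200 bp gaps, labels each gene with one KO drawn uniformly
#' from a pool of `ko_pool` families, and relabels one randomly placed gene
#' per genome as the anchor KO. With probability `colocal_prob` (per
#' genome), each partner KO replaces the label of one distinct gene inside
#' the anchor's window, planting the colocalization signal the neighborhood
#' test should detect.
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome genes per genome.
#' @param ko_pool size of the background KO pool (labels "K00001", ...).
#' @param anchor_ko anchor KO id, default `"K00441"` (kept out of the
#'   background pool).
#' @param partner_kos partner KO ids to colocalize (members of the pool,
#'   disjoint from the anchor).
#' @param colocal_prob per-genome colocalization probability.
#' @param window window half-width in bp (must be >= the 1 kb gene length).
#' @param seed integer seed.
#' @return a `genome_annotation` data.frame (see [annotate_genes()]).
#' @export
simulate_annotations <- function(n_genomes = 50, genes_per_genome = 200,
                                 ko_pool = 2000, anchor_ko = "K00441",
                                 partner_kos = character(), colocal_prob = 0,
                                 window = 10000, seed = 1) {
  gene_len <- 1000; gap <- 200
  if (window < gene_len) stop("window must be at least the gene length")
  if (anchor_ko %in% partner_kos) {
    stop("partner KOs must be disjoint from the anchor")
  }
  pool <- setdiff(sprintf("K%05d", seq_len(ko_pool) + 10000), anchor_ko)
  if (length(setdiff(partner_kos, pool))) {
    stop("partner KOs must belong to the background pool (K10001...)")
  }
  withr::local_seed(seed)
  starts <- (seq_len(genes_per_genome) - 1L) * (gene_len + gap) + 1L
  ends <- starts + gene_len - 1L
  out <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    genome <- sprintf("G%03d", g)
    lab <- sample(pool, genes_per_genome, replace = TRUE)
    a <- sample.int(genes_per_genome, 1)
    lab[a] <- anchor_ko
    if (length(partner_kos) && stats::runif(1) < colocal_prob) {
      near <- which(starts <= ends[a] + window & ends >= starts[a] - window)
      near <- setdiff(near, a)
      if (length(near) < length(partner_kos)) {
        stop("window too small to place all partner KOs")
      }
      lab[sample(near, length(partner_kos))] <- partner_kos
    }
    out[[g]] <- data.frame(genome = genome,
                           gene = sprintf("%s_g%04d", genome,
                                          seq_len(genes_per_genome)),
                           contig = "c1", start = starts, end = ends,
                           strand = "+", row.names = NULL)
    out[[g]]$kos <- as.list(lab)
  }
  ann <- do.call(rbind, out)
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Simulate biosynthetic gene clusters with planted group structure
#'
#' Creates `n_groups` disjoint KO signatures of `kos_per_group` families.
#' Each strain carries each group's BGC with probability `presence_prob`;
#' a member BGC keeps at least 80% of its signature KOs (a random deletion
#' of at most 20%) and gains up to `noise_kos` random extra KOs.
#'
#' @param strains character vector of strain ids (genome per strain).
#' @param n_groups number of BGC groups.
#' @param kos_per_group signature size, >= 3.
#' @param presence_prob per-strain carriage probability.
#' @param noise_kos maximum number of random extra KOs per BGC, default 1.
#' @param seed integer seed.
#' @return data.frame with columns `bgc_id`, `genome`, `contig`, `start`,
#'   `end`, `true_group` and list-column `kos`; attribute `planted_presence`
#'   holds the strain x group carriage matrix.
#' @export
simulate_bgcs <- function(strains, n_groups = 8, kos_per_group = 6,
                          presence_prob = 0.5, noise_kos = 1, seed = 1) {
  if (kos_per_group < 3) {
    stop("kos_per_group must be >= 3 (smaller clusters are filtered out)")
  }
  withr::local_seed(seed)
  signatures <- split(sprintf("K2%04d", seq_len(n_groups * kos_per_group)),
                      rep(seq_len(n_groups), each = kos_per_group))
  noise_pool <- sprintf("K3%04d", 1:100)
  planted <- matrix(stats::runif(length(strains) * n_groups) < presence_prob,
                    length(strains), n_groups,
                    dimnames = list(strains, paste0("group", seq_len(n_groups))))
  rows <- list()
  max_drop <- floor(0.2 * kos_per_group)
  for (s in seq_along(strains)) {
    for (g in seq_len(n_groups)) {
      if (!planted[s, g]) next
      sig <- signatures[[g]]
      n_drop <- sample.int(max_drop + 1, 1) - 1L
      kos <- if (n_drop > 0) sig[-sample.int(length(sig), n_drop)] else sig
      if (noise_kos > 0) {
        n_extra <- sample.int(noise_kos + 1, 1) - 1L
        if (n_extra > 0) kos <- c(kos, sample(noise_pool, n_extra))
      }
      rows[[length(rows) + 1]] <- data.frame(
        bgc_id = sprintf("%s_bgc%03d", strains[s], g),
        genome = strains[s], contig = "c1",
        start = (g - 1) * 50000 + 1, end = g * 50000,
        true_group = g, row.names = NULL)
      rows[[length(rows)]]$kos <- list(kos)
    }
  }
  bgcs <- do.call(rbind, rows)
  attr(bgcs, "planted_presence") <- planted
  bgcs
}
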