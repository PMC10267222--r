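#' Parse a fraction that may be written as a percentage
#'
#' Accepts a bare number (taken as a fraction) or a string with a trailing
#' `%` (divided by 100), guarding against the classic 0.01% vs 1e-4 trap.
#'
#' @param x numeric, or character like `"0.01%"`.
#' @return numeric fraction.
#' @export
as_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  pct <- grepl("%$", x)
  v <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (anyNA(v)) stop("cannot parse fraction: ", paste(x[is.na(v)], collapse = ", "))
  ifelse(pct, v / 100, v)
}

# Stable per-stage child seed derived from the master seed and stage name,
# kept inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Run the full synthetic-community analysis pipeline
#'
#' Orchestrates simulate -> collapse -> detect/richness -> prevalence filter
#' -> enrichment -> PGLS scan -> neighborhood test -> BGC grouping and scan,
#' writing per-stage TSVs plus a JSON manifest under `out_dir`. Runs are
#' deterministic given (config, seed): each stage receives a child seed
#' derived from the master seed and the stage name.
#'
#' @param config list (or path to a YAML file) with optional entries:
#'   `simulation` (arguments for [sim_config()]); `thresholds` with
#'   `min_abund`, `min_cov`, `prev_abund`, `prev_frac`, `fdr`, `window_bp`,
#'   `n_perm`, `k_groups`, `min_kos` (fractions may be percent strings);
#'   `passages` (aggregation window, default 3:6); `seed`. Alternatively an
#'   `inputs` entry with paths `abundance` (long TSV) and `tree` (Newick)
#'   runs the abundance/enrichment/scan stages on real tables. Exactly one
#'   of `simulation` / `inputs` must be present.
#' @param out_dir output directory.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!xor(is.null(config$simulation), is.null(config$inputs))) {
    stop("config must contain exactly one of 'simulation' or 'inputs'")
  }
  th <- config$thresholds
  thr <- function(name, default) {
    if (is.null(th[[name]])) default else as_fraction(th[[name]])
  }
  min_abund <- thr("min_abund", 1e-6); min_cov <- thr("min_cov", 0.01)
  prev_abund <- thr("prev_abund", 1e-4); prev_frac <- thr("prev_frac", 0.10)
  fdr <- thr("fdr", 0.01)
  window_bp <- if (is.null(th$window_bp)) 10000 else th$window_bp
  n_perm <- if (is.null(th$n_perm)) 1000 else th$n_perm
  k_groups <- if (is.null(th$k_groups)) 256 else th$k_groups
  min_kos <- if (is.null(th$min_kos)) 3 else th$min_kos
  passages <- if (is.null(config$passages)) 3:6 else config$passages
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("carrierscan")),
                   stages = list())
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e))
    })
    out
  }
  note <- function(name, rows, file = NA_character_) {
    manifest$stages[[name]] <<- list(rows = rows, file = file)
    message(sprintf("[%s] %d rows%s", name, rows,
                    if (is.na(file)) "" else paste0(" -> ", file)))
  }

  sim <- NULL
  if (!is.null(config$simulation)) {
    cfg <- do.call(sim_config, config$simulation)
    sim <- stage("simulate", {
      tree <- simulate_tree(cfg$n_strains, .stage_seed(seed, "tree"))
      geno <- simulate_genotypes(tree, cfg$n_kos,
                                 seed = .stage_seed(seed, "genotypes"))
      causal <- colnames(geno$bitscore)[seq_len(cfg$n_causal)]
      trait <- simulate_phenotype(tree, geno, causal, beta = cfg$effect_beta,
                                  bm_sigma2 = cfg$bm_sigma2,
                                  noise_sd = cfg$noise_sd,
                                  seed = .stage_seed(seed, "phenotype"))
      tab <- simulate_abundance(trait, cfg$design, noise_sd = cfg$noise_sd,
                                detection_floor = cfg$detection_floor,
                                seed = .stage_seed(seed, "abundance"))
      list(tree = tree, genotypes = geno, causal = causal, trait = trait,
           table = tab)
    })
    tab <- sim$table
    tree <- sim$tree
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_abundance_table(tab, file.path(out_dir, "abundance_raw.tsv"))
    note("simulate", nrow(tab$samples), "abundance_raw.tsv")
  } else {
    tab <- stage("read", read_abundance_table(config$inputs$abundance))
    tree <- stage("read_tree", parse_newick(file = config$inputs$tree))
    note("read", nrow(tab$samples))
  }

  collapsed <- stage("collapse", collapse_technical(tab))
  write_abundance_table(collapsed, file.path(out_dir, "abundance_collapsed.tsv"))
  note("collapse", ncol(collapsed$rel_abundance), "abundance_collapsed.tsv")

  pres <- stage("detect", detect(tab, min_abund, min_cov))
  rich <- data.frame(sample_id = colnames(pres), richness = colSums(pres))
  utils::write.table(rich, file.path(out_dir, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("detect", nrow(rich), "richness.tsv")

  prevalent <- stage("prevalence", prevalence_filter(tab, prev_abund, prev_frac))
  writeLines(prevalent, file.path(out_dir, "prevalent_strains.txt"))
  note("prevalence", length(prevalent), "prevalent_strains.txt")

  pairs <- stage("enrich", {
    conds <- unique(collapsed$samples$condition)
    carrier <- grep("-carrier$", conds, value = TRUE)[1]
    supernatant <- sub("-carrier$", "-supernatant", carrier)
    paired_log_ratios(collapsed, carrier, supernatant)
  })
  aggregate <- aggregate_enrichment(pairs, passages = passages)
  write_enrichment(pairs, aggregate, out_dir)
  note("enrich", nrow(aggregate), "enrichment_aggregate.tsv")

  scan <- NULL
  if (!is.null(sim)) {
    scan <- stage("scan", {
      pheno <- stats::setNames(aggregate$aggregate, aggregate$strain_id)
      pheno <- pheno[intersect(prevalent, names(pheno))]
      association_scan(sim$genotypes$bitscore[names(pheno), , drop = FALSE],
                       pheno, tree, fdr = fdr)
    })
    write_scan(scan, file.path(out_dir, "scan_global.tsv"))
    note("scan", nrow(scan), "scan_global.tsv")

    nb <- stage("neighborhood", {
      partners <- sprintf("K%05d", 10001:10004)
      ann <- simulate_annotations(n_genomes = 25, genes_per_genome = 120,
                                  ko_pool = 400, partner_kos = partners,
                                  colocal_prob = 1,
                                  seed = .stage_seed(seed, "annotations"))
      permutation_test(ann, "K00441", window_bp, n_perm,
                       seed = .stage_seed(seed, "perm"))
    })
    write_neighborhood(nb, file.path(out_dir, "neighborhood.tsv"))
    note("neighborhood", nrow(nb), "neighborhood.tsv")

    bgc <- stage("bgc", {
      bgcs <- simulate_bgcs(tree$tip.label, seed = .stage_seed(seed, "bgcs"))
      groups <- filter_and_cluster(bgcs, min_kos = min_kos,
                                   k_groups = k_groups)
      presence <- group_presence(groups, all_strains = tree$tip.label)
      pheno <- stats::setNames(aggregate$aggregate, aggregate$strain_id)
      list(groups = groups,
           scan = bgc_association_scan(presence, pheno, tree, fdr = fdr))
    })
    utils::write.table(bgc$groups$membership,
                       file.path(out_dir, "bgc_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_scan(bgc$scan, file.path(out_dir, "scan_bgc.tsv"))
    note("bgc", nrow(bgc$scan), "scan_bgc.tsv")
    res$neighborhood <- nb
    res$bgc <- bgc
  }

  manifest$config_hash <- unname(tools::md5sum(
    tempfile_with(config, out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- c(list(table = tab, collapsed = collapsed, presence = pres,
                prevalent = prevalent, pairs = pairs, aggregate = aggregate,
                scan = scan, sim = sim, manifest = manifest), res)
  invisible(res)
}

# Serialize the config to a canonical YAML file for hashing.
tempfile_with <- function(config, out_dir) {
  p <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, p)
  p
}
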