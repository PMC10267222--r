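#' Parse a Newick tree with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: requires branch lengths
#' on all edges, unique leaf labels, and non-negative lengths. Polytomies are
#' allowed.
#'
#' @param text Newick string, or `file` may be given instead.
#' @param file path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- withCallingHandlers(
    tryCatch(
      if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
      error = function(e) stop("malformed Newick: ", conditionMessage(e))),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w)))
  if (is.null(tr) || !inherits(tr, "phylo")) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("all edges must carry branch lengths")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Brownian-motion covariance induced by a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of leaves i and j;
#' the diagonal holds root-to-leaf depths. This is the trait covariance (up
#' to the Brownian rate) of a Brownian motion evolving along the branches.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param strain_ids optional ordered subset of leaves; the tree is pruned to
#'   these before computing, and the matrix rows/columns follow this order.
#' @return symmetric positive semi-definite matrix with strain dimnames.
#' @export
bm_covariance <- function(tree, strain_ids = NULL) {
  if (!is.null(strain_ids)) {
    missing <- setdiff(strain_ids, tree$tip.label)
    if (length(missing)) {
      stop("strain(s) absent from tree: ", paste(missing, collapse = ", "))
    }
    if (length(strain_ids) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, strain_ids)
    }
  } else {
    strain_ids <- tree$tip.label
  }
  C <- ape::vcv(tree)
  C[strain_ids, strain_ids]
}

# Cholesky with one shot of diagonal jitter for near-singular covariances.
.chol_or_jitter <- function(C) {
  L <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-10 * sum(diag(C)) / nrow(C)
    L <- tryCatch(t(chol(C + diag(jitter, nrow(C)))), error = function(e) NULL)
    if (is.null(L)) stop("covariance matrix is singular even after jitter")
  }
  L
}

#' Phylogenetic generalized least squares fit
#'
#' Fits `y = alpha + beta * x + eps` with `eps ~ N(0, sigma2 * C)` by
#' whitening: both sides are premultiplied by the inverse lower Cholesky
#' factor of `C`, and ordinary least squares is solved on the whitened data.
#' The residual variance uses the unbiased divisor (n - 2) and the two-sided
#' p-value comes from a Student t on n - 2 degrees of freedom. Because the
#' Brownian rate is profiled out, results are invariant to rescaling `C` by
#' any positive constant; with `C = I` the fit reduces exactly to OLS.
#'
#' @param y numeric response, one value per taxon.
#' @param x numeric predictor, nonzero variance.
#' @param C covariance matrix aligned with `y` and `x` (see
#'   [bm_covariance()]).
#' @return list with `beta_hat`, `se`, `t`, `p`, `intercept`, `sigma2`,
#'   `n_taxa`.
#' @export
pgls_fit <- function(y, x, C) {
  n <- length(y)
  if (n < 3) stop("need at least 3 taxa")
  if (length(x) != n || nrow(C) != n || ncol(C) != n) {
    stop("y, x and C must be aligned")
  }
  if (stats::var(x) == 0) stop("predictor has zero variance")
  L <- .chol_or_jitter(C)
  W <- forwardsolve(L, cbind(1, x, y))
  fit <- stats::lm.fit(W[, 1:2, drop = FALSE], W[, 3])
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 2)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- unname(fit$coefficients[2])
  tval <- beta / se[2]
  list(beta_hat = beta, se = unname(se[2]), t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - 2),
       intercept = unname(fit$coefficients[1]),
       sigma2 = sigma2, n_taxa = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Genome-wide genotype-phenotype association scan
#'
#' Runs one PGLS fit per genotype column (KO bitscores, BGC-group presence,
#' ...) against a per-strain phenotype such as the aggregate carrier
#' enrichment score, under the Brownian-motion covariance of the supplied
#' tree. Genotype columns are standard-scaled by default ((x - mean)/sd over
#' the scanned strains); zero-variance columns are skipped (`tested = FALSE`)
#' and excluded from the FDR family. Strains with a missing phenotype are
#' dropped before scanning. A positive effect means higher genotype values go
#' with carrier enrichment.
#'
#' The covariance is factored once and all columns are whitened in one pass,
#' so the scan is exactly equivalent to calling [pgls_fit()] per column but
#' much faster.
#'
#' @param genotypes numeric strain-by-feature matrix with dimnames.
#' @param phenotype named numeric vector (names = strain ids); NAs dropped.
#' @param tree [ape::phylo] covering the scanned strains.
#' @param fdr significance cutoff on BH q-values, default 0.01.
#' @param standardize standard-scale genotype columns (default TRUE; t and p
#'   are invariant to this for a single regressor).
#' @return data.frame: `feature`, `beta_hat`, `se`, `t`, `p`, `q`, `n_taxa`,
#'   `tested`, `significant`.
#' @export
association_scan <- function(genotypes, phenotype, tree, fdr = 0.01,
                             standardize = TRUE) {
  stopifnot(is.matrix(genotypes))
  keep <- names(phenotype)[!is.na(phenotype)]
  dropped <- setdiff(rownames(genotypes), keep)
  keep <- intersect(rownames(genotypes), keep)
  if (length(dropped)) {
    message(length(dropped), " strain(s) dropped (missing phenotype): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  if (length(keep) < 3) stop("fewer than 3 strains with phenotype")
  X <- genotypes[keep, , drop = FALSE]
  y <- phenotype[keep]
  C <- bm_covariance(tree, keep)
  L <- .chol_or_jitter(C)

  sds <- apply(X, 2, stats::sd)
  tested <- sds > 0
  if (standardize) {
    X[, tested] <- scale(X[, tested, drop = FALSE])
  }
  n <- length(keep)
  ones_w <- forwardsolve(L, rep(1, n))
  y_w <- forwardsolve(L, y)
  X_w <- forwardsolve(L, X)

  # closed-form simple regression with intercept on whitened data
  a <- sum(ones_w^2)
  d <- sum(ones_w * y_w)
  f <- sum(y_w^2)
  b <- colSums(ones_w * X_w)
  cc <- colSums(X_w^2)
  e <- colSums(y_w * X_w)
  det <- a * cc - b^2
  beta <- (a * e - b * d) / det
  alpha <- (cc * d - b * e) / det
  rss <- f - alpha * d - beta * e
  rss <- pmax(rss, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a / det)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)

  res <- data.frame(feature = colnames(genotypes),
                    beta_hat = beta, se = se, t = tval, p = p,
                    q = NA_real_, n_taxa = n, tested = tested,
                    significant = FALSE, row.names = NULL)
  res$beta_hat[!tested] <- NA_real_
  res$se[!tested] <- NA_real_
  res$t[!tested] <- NA_real_
  res$p[!tested] <- NA_real_
  if (any(tested)) {
    res$q[tested] <- bh_fdr(res$p[tested])
    res$significant[tested] <- res$q[tested] < fdr
  }
  res
}

#' Clade-restricted association scans
#'
#' Repeats [association_scan()] within phylum-level clades. By default the
#' Firmicutes, Firmicutes_A and Firmicutes_C phyla are merged into a single
#' clade. Clades with fewer than 3 strains carrying a phenotype are skipped
#' with a message.
#'
#' @inheritParams association_scan
#' @param taxonomy data.frame with `strain_id` and `phylum` columns.
#' @param merge_firmicutes merge the three Firmicutes phyla (default TRUE).
#' @return data.frame of per-clade scan results with a leading `clade`
#'   column.
#' @export
clade_scan <- function(genotypes, phenotype, tree, taxonomy, fdr = 0.01,
                       merge_firmicutes = TRUE) {
  lab <- taxonomy$phylum[match(rownames(genotypes), taxonomy$strain_id)]
  if (anyNA(lab)) stop("strains missing from taxonomy")
  if (merge_firmicutes) {
    lab[grepl("^Firmicutes", lab)] <- "Firmicutes_merged"
  }
  out <- list()
  for (clade in unique(lab)) {
    ids <- rownames(genotypes)[lab == clade]
    usable <- sum(!is.na(phenotype[ids]))
    if (usable < 3) {
      message("skipping clade '", clade, "': only ", usable,
              " strain(s) with phenotype")
      next
    }
    scan <- association_scan(genotypes[ids, , drop = FALSE], phenotype[ids],
                             tree, fdr = fdr)
    out[[clade]] <- cbind(clade = clade, scan)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fisher overlap test between two hit lists
#'
#' Builds the 2x2 contingency table of membership in two hit sets over a
#' common feature universe and applies the two-sided Fisher exact test. The
#' reported `log_odds` is the log of the conditional maximum-likelihood odds
#' ratio; the (Haldane-corrected) sample log odds ratio is also returned.
#' Infinite estimates from degenerate margins are capped to the sample value
#' and flagged.
#'
#' @param hitsA,hitsB character vectors of significant feature ids.
#' @param universe all tested feature ids.
#' @return list: `table` (2x2 counts), `log_odds`, `ci95`, `p`,
#'   `sample_log_odds`, `capped`.
#' @export
overlap_test <- function(hitsA, hitsB, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(hitsA, universe)) || length(setdiff(hitsB, universe))) {
    stop("hit lists must be subsets of the universe")
  }
  inA <- universe %in% hitsA
  inB <- universe %in% hitsB
  tab <- matrix(c(sum(inA & inB), sum(!inA & inB),
                  sum(inA & !inB), sum(!inA & !inB)),
                nrow = 2, dimnames = list(A = c("hit", "no"),
                                          B = c("hit", "no")))
  ft <- stats::fisher.test(tab)
  sample_lo <- log((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
                   ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)))
  lo <- log(unname(ft$estimate))
  capped <- !is.finite(lo)
  if (capped) lo <- sample_lo
  list(table = tab, log_odds = lo, ci95 = log(ft$conf.int), p = ft$p.value,
       sample_log_odds = sample_lo, capped = capped)
}

#' Write scan results as TSV
#'
#' Adds a `neg_log10_q` column so the file is directly volcano-plot ready
#' (effect size vs -log10 q).
#'
#' @param scan data.frame from [association_scan()] or [clade_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  scan$neg_log10_q <- -log10(scan$q)
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
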