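# Shared fixtures and independent oracles for the test suite.

# Small abundance table built directly from matrices.
make_table <- function(ra, meta = NULL, hc = NULL) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(ra),
                       condition = rep("mucin-carrier", ncol(ra)))
  }
  abundance_table(meta, ra, hc)
}

# Paired two-condition design table: abundance arrays indexed
# [strain, pair, compartment].
make_paired_table <- function(carrier, supernatant,
                              passages, bio_reps) {
  stopifnot(identical(dim(carrier), dim(supernatant)))
  n_pairs <- ncol(carrier)
  meta <- data.frame(
    sample_id = c(paste0("c", seq_len(n_pairs)), paste0("s", seq_len(n_pairs))),
    condition = rep(c("mucin-carrier", "mucin-supernatant"), each = n_pairs),
    passage = rep(passages, 2),
    bio_rep = rep(bio_reps, 2))
  ra <- cbind(carrier, supernatant)
  colnames(ra) <- meta$sample_id
  abundance_table(meta, ra)
}

# Independent GLS oracle: explicit C-inverse normal equations.
gls_oracle <- function(y, x, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  n <- length(y)
  sigma2 <- drop(t(r) %*% Ci %*% r) / (n - 2)
  se <- sqrt(diag(sigma2 * solve(XtCiX)))
  tval <- unname(beta[2] / se[2])
  list(beta_hat = unname(beta[2]), se = unname(se[2]), t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# Exhaustive hypergeometric oracle for the two-sided Fisher test on a 2x2
# table with fixed margins, plus the conditional-MLE odds ratio obtained by
# solving the noncentral hypergeometric mean equation.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(support, m1, m2, n1)
  p <- sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  ncmean <- function(psi) {
    w <- choose(m1, support) * choose(m2, n1 - support) * psi^support
    sum(support * w) / sum(w)
  }
  or <- if (a == min(support)) 0
        else if (a == max(support)) Inf
        else stats::uniroot(function(psi) ncmean(psi) - a,
                            c(1e-8, 1e8), tol = 1e-10)$root
  list(p = p, or = or)
}

# Ultrametric star tree with unit branch lengths (BM covariance = identity).
star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("S%04d", seq_len(n))
  tr
}
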