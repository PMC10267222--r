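test_that("Newick parsing validates structure and branch lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))

  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
  expect_error(parse_newick("((A:1,B:1):1,C:2;"), "malformed|Newick")
  expect_error(parse_newick("(A:1,B:1,C)"), "branch length|malformed")
  # polytomies accepted
  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(star), 3L)
})

test_that("BM covariance equals root-to-MRCA shared path lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(unname(bm_covariance(star)), diag(4))

  expect_error(bm_covariance(tr, c("A", "Z")), "Z")

  # positive semi-definite on random trees
  for (s in 1:5) {
    Cs <- bm_covariance(simulate_tree(20, s))
    expect_gte(min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("PGLS reduces to OLS under identity covariance and fits exact lines", {
  set.seed(1)
  n <- 12
  y <- rnorm(n); x <- rnorm(n)
  C <- diag(n)
  f <- pgls_fit(y, x, C)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(f$beta_hat, ols[2, 1], tolerance = 1e-10)
  expect_equal(f$se, ols[2, 2], tolerance = 1e-10)
  expect_equal(f$p, ols[2, 4], tolerance = 1e-10)

  # exact linear signal: slope 2, zero residual
  tr <- simulate_tree(8, 4)
  C2 <- bm_covariance(tr)
  x2 <- rnorm(8)
  f2 <- pgls_fit(2 * x2, x2, C2)
  expect_equal(f2$beta_hat, 2, tolerance = 1e-10)
  expect_lt(f2$sigma2, 1e-20)

  expect_error(pgls_fit(y[1:2], x[1:2], diag(2)), "3 taxa")
  expect_error(pgls_fit(y, rep(1, n), C), "zero variance")
})

test_that("PGLS matches the explicit-inverse GLS oracle on small trees", {
  set.seed(10)
  for (s in 1:20) {
    n <- sample(5:15, 1)
    tr <- if (s %% 2) simulate_tree(n, s) else ape::rtree(n)
    C <- bm_covariance(tr)
    y <- rnorm(n); x <- rnorm(n)
    f <- pgls_fit(y, x, C)
    o <- gls_oracle(y, x, C)
    expect_equal(f$beta_hat, o$beta_hat, tolerance = 1e-9)
    expect_equal(f$se, o$se, tolerance = 1e-9)
    expect_equal(f$p, o$p, tolerance = 1e-9)
  }
})

test_that("PGLS is invariant to rescaling the covariance", {
  set.seed(2)
  tr <- simulate_tree(15, 9)
  C <- bm_covariance(tr)
  y <- rnorm(15); x <- rnorm(15)
  f1 <- pgls_fit(y, x, C)
  f2 <- pgls_fit(y, x, 1000 * C)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-10)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  set.seed(6)
  tr <- simulate_tree(24, 13)
  dat <- data.frame(y = rnorm(24), x = rnorm(24), taxon = tr$tip.label)
  f <- pgls_fit(dat$y, dat$x, bm_covariance(tr)[dat$taxon, dat$taxon])
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(1, tr, form = ~taxon))
  sm <- summary(g)$tTable
  expect_equal(f$beta_hat, sm["x", "Value"], tolerance = 1e-6)
  expect_equal(f$se, sm["x", "Std.Error"], tolerance = 1e-6)
})

test_that("BH q-values reproduce the hand step-up and edge cases", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # under a full uniform null the chance of any q < 0.01 discovery is <= 0.01
  set.seed(21)
  any_disc <- replicate(400, any(bh_fdr(runif(50)) < 0.01))
  expect_lte(mean(any_disc), 0.01 + 3 * sqrt(0.01 * 0.99 / 400))
})

test_that("association scan matches per-column PGLS and handles degeneracies", {
  set.seed(14)
  tr <- simulate_tree(20, 5)
  g <- simulate_genotypes(tr, 8, 0.5, 6)
  y <- simulate_phenotype(tr, g, character(0), beta = 0, bm_sigma2 = 1,
                          noise_sd = 0, seed = 7)
  scan <- association_scan(g$bitscore, y, tr)
  C <- bm_covariance(tr, names(y))
  for (k in colnames(g$bitscore)) {
    x <- scale(g$bitscore[names(y), k])[, 1]
    f <- pgls_fit(y, x, C)
    i <- match(k, scan$feature)
    expect_equal(scan$beta_hat[i], f$beta_hat, tolerance = 1e-10)
    expect_equal(scan$p[i], f$p, tolerance = 1e-10)
  }

  # constant columns are untested and excluded from the FDR family
  gb <- g$bitscore
  gb[, 3] <- 7
  scan2 <- association_scan(gb, y, tr)
  expect_false(scan2$tested[3])
  expect_true(is.na(scan2$q[3]))
  expect_equal(bh_fdr(scan2$p[scan2$tested]), scan2$q[scan2$tested])

  # all-constant genotypes: empty hit list
  gc <- matrix(1, 20, 4, dimnames = list(tr$tip.label, paste0("K", 1:4)))
  scan3 <- association_scan(gc, y, tr)
  expect_false(any(scan3$tested))
  expect_false(any(scan3$significant))

  # strains with missing phenotype are dropped
  y2 <- y; y2[1:2] <- NA
  expect_message(scan4 <- association_scan(g$bitscore, y2, tr), "dropped")
  expect_equal(scan4$n_taxa[1], 18L)
  expect_error(association_scan(g$bitscore, setNames(rep(NA_real_, 20),
                                                     names(y)), tr),
               "fewer than 3")
})

test_that("scan hits under label permutation stay at the FDR-controlled null rate", {
  set.seed(33)
  tr <- simulate_tree(40, 17)
  g <- simulate_genotypes(tr, 300, 0.5, 18)
  y <- simulate_phenotype(tr, g, "K00001", beta = 2, bm_sigma2 = 1,
                          noise_sd = 0, seed = 19)
  # permute phenotype across strains: genotype linkage broken
  disc <- mean(replicate(5, {
    yp <- setNames(sample(y), names(y))
    mean(association_scan(g$bitscore, yp, tr)$significant)
  }))
  expect_lte(disc, 0.02)
})

test_that("clade scans merge the Firmicutes phyla and find clade-local effects", {
  set.seed(40)
  tr <- simulate_tree(30, 23)
  ids <- tr$tip.label
  tax <- data.frame(strain_id = ids,
                    phylum = rep(c("Firmicutes", "Firmicutes_A",
                                   "Firmicutes_C", "Bacteroidota",
                                   "Desulfobacterota"), each = 6))
  g <- simulate_genotypes(tr, 5, 0.5, 24)
  y <- simulate_phenotype(tr, g, character(0), beta = 0, bm_sigma2 = 1,
                          noise_sd = 0, seed = 25)
  res <- clade_scan(g$bitscore, y, tr, tax)
  expect_setequal(unique(res$clade),
                  c("Firmicutes_merged", "Bacteroidota", "Desulfobacterota"))
  expect_equal(unique(res$n_taxa[res$clade == "Firmicutes_merged"]), 18L)

  # a single-phylum taxonomy reproduces the global scan
  tax1 <- data.frame(strain_id = ids, phylum = "Bacteroidota")
  res1 <- clade_scan(g$bitscore, y, tr, tax1)
  glob <- association_scan(g$bitscore, y, tr)
  expect_equal(res1$p, glob$p)

  # clades below 3 phenotyped strains are skipped with a message
  y2 <- y; y2[tax$phylum == "Desulfobacterota"] <- NA
  expect_message(res2 <- clade_scan(g$bitscore, y2, tr, tax), "skipping clade")
  expect_false("Desulfobacterota" %in% res2$clade)
})

test_that("clade-restricted effects are found in their clade and nowhere else", {
  hits_in <- 0; hits_out <- 0
  for (s in 1:10) {
    tr <- simulate_tree(36, 50 + s)
    ids <- tr$tip.label
    half <- ids[1:18]
    tax <- data.frame(strain_id = ids,
                      phylum = ifelse(ids %in% half, "Bacteroidota",
                                      "Firmicutes"))
    withr::with_seed(60 + s, {
      x <- numeric(36); names(x) <- ids
      x[half] <- rbinom(18, 1, 0.5)
      g <- matrix(rnorm(36 * 40), 36, 40,
                  dimnames = list(ids, sprintf("K%05d", 1:40)))
      g[, 1] <- x
      yv <- drop(t(chol(bm_covariance(tr)))[ids, ids] %*% rnorm(36))
      y <- setNames(yv + 3 * x, ids)
    })
    res <- clade_scan(g, y, tr, tax, fdr = 0.01)
    in_clade <- res[res$clade == "Bacteroidota" & res$feature == "K00001", ]
    out_clade <- res[res$clade == "Firmicutes" & res$feature == "K00001", ]
    hits_in <- hits_in + as.integer(nrow(in_clade) && in_clade$significant)
    hits_out <- hits_out +
      as.integer(nrow(out_clade) && isTRUE(out_clade$significant))
  }
  expect_gte(hits_in, 8)
  expect_equal(hits_out, 0)
})

test_that("Fisher overlap test matches exhaustive hypergeometric enumeration", {
  # hand table [[8,2],[1,9]] over a universe of 20 features
  universe <- sprintf("f%02d", 1:20)
  hitsA <- universe[1:10]          # 8 shared + 2 A-only
  hitsB <- universe[c(1:8, 11)]    # 8 shared + 1 B-only
  res <- overlap_test(hitsA, hitsB, universe)
  expect_equal(unname(res$table[1, ]), c(8, 2))
  expect_equal(unname(res$table[2, ]), c(1, 9))
  oracle <- fisher_oracle(res$table)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$log_odds, log(oracle$or), tolerance = 1e-4)
  expect_gte(res$log_odds, res$ci95[1])
  expect_lte(res$log_odds, res$ci95[2])

  # balanced table: no association
  u2 <- sprintf("g%02d", 1:40)
  r2 <- overlap_test(u2[1:20], u2[c(1:10, 21:30)], u2)
  expect_equal(r2$p, 1)
  expect_equal(r2$log_odds, 0, tolerance = 1e-6)

  # perfectly nested hit lists: degenerate margin is capped and flagged
  r3 <- overlap_test(u2[1:20], u2[1:20], u2)
  expect_true(r3$capped)
  expect_true(is.finite(r3$log_odds))

  expect_error(overlap_test("z", u2[1], u2), "subset")
  expect_error(overlap_test("a", "b", character(0)), "empty")
})
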