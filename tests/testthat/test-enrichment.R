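test_that("pair scores follow the half-minimum zero-replacement rule", {
  carrier <- matrix(c(0.02, 0, 0, 0.004,
                      0.5, 0.004, 0.3, 0.1), 4, 2,
                    dimnames = list(c("sA", "sB", "sC", "sD"), NULL))
  supernatant <- matrix(c(0.01, 0.004, 0, 0.05,
                          0.3, 0.5, 0.1, 0.02), 4, 2,
                        dimnames = list(c("sA", "sB", "sC", "sD"), NULL))
  tab <- make_paired_table(carrier, supernatant, passages = c(1, 1),
                           bio_reps = c(1, 2))
  pr <- paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant")
  p1 <- pr[pr$bio_rep == 1, ]
  # 0.02 / 0.01
  expect_equal(p1$score[p1$strain_id == "sA"], log(2))
  # carrier zero replaced by half the carrier sample's min nonzero (0.004/2)
  expect_equal(p1$score[p1$strain_id == "sB"], log(0.002 / 0.004))
  # zero in both compartments -> missing
  expect_true(is.na(p1$score[p1$strain_id == "sC"]))
})

test_that("pair scores negate exactly under compartment swap", {
  set.seed(3)
  carrier <- matrix(runif(40, 0, 0.02), 10, 4,
                    dimnames = list(sprintf("s%02d", 1:10), NULL))
  carrier[sample(40, 6)] <- 0
  supernatant <- matrix(runif(40, 0, 0.02), 10, 4, dimnames = dimnames(carrier))
  supernatant[sample(40, 6)] <- 0
  tab <- make_paired_table(carrier, supernatant, passages = c(3, 4, 5, 6),
                           bio_reps = rep(1, 4))
  fwd <- paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant")
  rev <- paired_log_ratios(tab, "mucin-supernatant", "mucin-carrier")
  expect_equal(fwd$score, -rev$score)
  af <- aggregate_enrichment(fwd)
  ar <- aggregate_enrichment(rev)
  expect_equal(af$aggregate, -ar$aggregate)
})

test_that("aggregate is mean over SD and is log-base invariant", {
  carrier <- matrix(c(0.2, 0.2, 0.2) * exp(c(0.2, 0.4, 0.6)), 1, 3,
                    dimnames = list("sA", NULL))
  supernatant <- matrix(0.2, 1, 3, dimnames = list("sA", NULL))
  tab <- make_paired_table(carrier, supernatant, passages = c(4, 5, 6),
                           bio_reps = rep(1, 3))
  pr <- paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant")
  expect_equal(pr$score, c(0.2, 0.4, 0.6))
  ag <- aggregate_enrichment(pr)
  expect_equal(ag$aggregate, 2.0)  # mean 0.4 / sd 0.2
  expect_equal(ag$n_pairs_used, 3L)

  pr2 <- paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant",
                           log_base = 2)
  ag2 <- aggregate_enrichment(pr2)
  expect_equal(ag$aggregate, ag2$aggregate, tolerance = 1e-12)

  # scores [1, -1]: mean 0, aggregate 0
  c2 <- matrix(0.1 * exp(c(1, -1)), 1, 2, dimnames = list("sA", NULL))
  s2 <- matrix(0.1, 1, 2, dimnames = list("sA", NULL))
  t2 <- make_paired_table(c2, s2, passages = c(3, 4), bio_reps = c(1, 1))
  a2 <- aggregate_enrichment(paired_log_ratios(t2, "mucin-carrier",
                                               "mucin-supernatant"))
  expect_equal(a2$aggregate, 0)
})

test_that("late-passage selection keeps 12 of the 18 full-design pairs", {
  set.seed(5)
  n_pairs <- 18  # 6 passages x 3 bio reps
  carrier <- matrix(runif(n_pairs * 2, 0.01, 0.05), 2, n_pairs,
                    dimnames = list(c("sA", "sB"), NULL))
  supernatant <- matrix(runif(n_pairs * 2, 0.01, 0.05), 2, n_pairs,
                        dimnames = dimnames(carrier))
  tab <- make_paired_table(carrier, supernatant,
                           passages = rep(1:6, each = 3),
                           bio_reps = rep(1:3, times = 6))
  ag <- aggregate_enrichment(
    paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant"))
  expect_equal(ag$n_pairs_used, c(12L, 12L))
})

test_that("degenerate aggregates are flagged missing, never infinite", {
  carrier <- matrix(0.2, 1, 3, dimnames = list("sA", NULL))
  tab <- make_paired_table(carrier, carrier, passages = c(4, 5, 6),
                           bio_reps = rep(1, 3))
  pr <- paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant")
  expect_warning(ag <- aggregate_enrichment(pr), "zero-SD")
  expect_true(is.na(ag$aggregate))
  expect_equal(ag$flag, "zero_sd")

  # a single usable pair is too few
  t1 <- make_paired_table(carrier[, 1, drop = FALSE] * 2,
                          carrier[, 1, drop = FALSE],
                          passages = 4, bio_reps = 1)
  a1 <- aggregate_enrichment(paired_log_ratios(t1, "mucin-carrier",
                                               "mucin-supernatant"))
  expect_true(is.na(a1$aggregate))
  expect_equal(a1$flag, "too_few")
})

test_that("pairing errors name the offending key", {
  carrier <- matrix(0.1, 1, 2, dimnames = list("sA", NULL))
  meta <- data.frame(sample_id = c("c1", "c2", "s1"),
                     condition = c("mucin-carrier", "mucin-carrier",
                                   "mucin-supernatant"),
                     passage = c(1, 2, 1), bio_rep = 1)
  ra <- matrix(0.1, 1, 3, dimnames = list("sA", meta$sample_id))
  tab <- abundance_table(meta, ra)
  expect_error(paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant"),
               "2/1")
})

test_that("common rescaling of both compartments leaves scores unchanged", {
  set.seed(9)
  carrier <- matrix(runif(20, 0.01, 0.04), 5, 4,
                    dimnames = list(paste0("s", 1:5), NULL))
  supernatant <- matrix(runif(20, 0.01, 0.04), 5, 4,
                        dimnames = dimnames(carrier))
  tab <- make_paired_table(carrier, supernatant, passages = 3:6,
                           bio_reps = rep(1, 4))
  tab2 <- make_paired_table(carrier / 2, supernatant / 2, passages = 3:6,
                            bio_reps = rep(1, 4))
  expect_equal(
    paired_log_ratios(tab, "mucin-carrier", "mucin-supernatant")$score,
    paired_log_ratios(tab2, "mucin-carrier", "mucin-supernatant")$score)
})

test_that("in vivo mucosa/lumen scoring pairs individual x site", {
  set.seed(11)
  n_ind <- 13; n_site <- 3
  n_pairs <- n_ind * n_site
  meta <- data.frame(
    sample_id = paste0("lib", seq_len(2 * n_pairs)),
    condition = rep(c("mucosa", "lumen"), each = n_pairs),
    individual = rep(rep(seq_len(n_ind), each = n_site), 2),
    site = rep(rep(c("cecum", "colon", "ileum"), n_ind), 2))
  ra <- matrix(runif(2 * 2 * n_pairs, 0.1, 0.4), 2,
               dimnames = list(c("spA", "spB"), meta$sample_id))
  res <- invivo_enrichment(abundance_table(meta, ra))
  expect_equal(nrow(res$pairs), 2 * n_pairs)
  expect_equal(res$aggregate$n_pairs_used, c(39L, 39L))

  # hand check on a tiny 2 species x 4 pair design
  lu <- matrix(c(0.2, 0.1), 2, 4, dimnames = list(c("spA", "spB"), NULL))
  mu <- lu * rbind(exp(c(0.1, 0.2, 0.3, 0.4)), exp(-c(0.1, 0.2, 0.3, 0.4)))
  meta2 <- data.frame(sample_id = paste0("l", 1:8),
                      condition = rep(c("mucosa", "lumen"), each = 4),
                      individual = rep(rep(1:2, each = 2), 2),
                      site = rep(c("a", "b"), 4))
  ra2 <- cbind(mu, lu) / 2; colnames(ra2) <- meta2$sample_id
  res2 <- invivo_enrichment(abundance_table(meta2, ra2))
  # spA scores are 0.1..0.4 (mean 0.25, sd = sd(c(.1,.2,.3,.4))), spB negated
  expect_equal(res2$aggregate$aggregate,
               c(0.25, -0.25) / sd(c(0.1, 0.2, 0.3, 0.4)))
})
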