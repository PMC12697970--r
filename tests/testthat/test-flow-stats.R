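test_that("colony normalization maps the reference mean to 1", {
  tbl <- data.frame(experiment = "e1",
                    epo = c(0.5, 0.5, 0.5, 1),
                    ligand = c("none", "none", "IL-17A", "none"),
                    dose = c(0, 0, 20, 0),
                    replicate = c(1, 2, 1, 1),
                    count = c(10, 10, 15, 20))
  out <- normalize_colonies(tbl)
  expect_equal(out$relative, c(1, 1, 1.5, 2))
  # normalizing the relative column again is the identity up to ref mean 1
  tbl2 <- out; tbl2$count <- out$relative
  expect_equal(normalize_colonies(tbl2)$relative, out$relative)
  expect_error(normalize_colonies(tbl[tbl$epo == 1, ]), "reference")
})

test_that("Hill fit recovers planted parameters and is scale-covariant", {
  epo <- rep(10^seq(-2.5, 0.5, length.out = 10), each = 3)
  d <- data.frame(epo = epo,
                  relative = 2 * epo^1.5 / (0.1^1.5 + epo^1.5))
  cf <- coef(fit_hill(d))
  expect_equal(unname(cf["Vmax"]), 2, tolerance = 2e-3)
  expect_equal(unname(cf["EC50"]), 0.1, tolerance = 2e-3)
  expect_equal(unname(cf["h"]), 1.5, tolerance = 2e-3)
  # EC50 invariant to rescaling the response (Vmax absorbs the scale)
  d2 <- d; d2$relative <- d$relative * 7
  cf2 <- coef(fit_hill(d2))
  expect_equal(unname(cf2["EC50"]), unname(cf["EC50"]), tolerance = 1e-4)
  expect_equal(unname(cf2["Vmax"]), 7 * unname(cf["Vmax"]),
               tolerance = 1e-3)
  expect_error(fit_hill(data.frame(epo = epo, relative = 0)), "zero")
  expect_error(fit_hill(data.frame(epo = rep(c(0.1, 1), 5),
                                   relative = 1)), "4 distinct")
})

test_that("percent increase: identical arms give 0, planted amplification recovered", {
  tbl <- synth_colonies(seed = 5, poisson = FALSE)
  r <- percent_increase(tbl, "IL-17B")
  expect_equal(r$mean_pct, 0, tolerance = 1e-10)
  r2 <- percent_increase(tbl, "IL-17A")
  expect_equal(r2$mean_pct, 39, tolerance = 5e-3)  # integer rounding only
  noisy <- synth_colonies(seed = 6)
  r3 <- percent_increase(noisy, "IL-17A")
  expect_lt(abs(r3$mean_pct - 39), 5 * r3$sem_pct + 2)
  expect_error(percent_increase(tbl, "IL-99"), "arm")
})

test_that("fold-change matrix: self-reference is 1, planted effects recovered", {
  tbl <- synth_flow_counts(seed = 3, cv = 0.2)
  fc <- fold_change_matrix(tbl)
  self <- fc$fold_change[fc$treatment == "vehicle"]
  expect_equal(self, rep(1, length(self)))
  truth <- attr(tbl, "truth")
  got <- merge(fc[fc$treatment == "Epo", ],
               truth[, c("tissue", "subset", "Epo")],
               by = c("tissue", "subset"))
  # lognormal sampling error with cv 0.2, n = 6: well within 35%
  expect_lt(max(abs(log(got$fold_change / got$Epo))), 0.35)
  # global rescaling leaves fold-changes unchanged
  tbl2 <- tbl; tbl2$cells_per_g <- tbl$cells_per_g * 1e3
  expect_equal(fold_change_matrix(tbl2)$fold_change, fc$fold_change)
})

test_that("exact signed-rank p matches full sign enumeration at n = 6", {
  set.seed(1)
  for (rep in 1:5) {
    d <- round(rnorm(6, 0.3, 1), 2)
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    # enumerate all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- signs %*% r
    p_two <- min(1, 2 * min(mean(Wall >= W), mean(Wall <= W)))
    got <- signed_rank_test(d, alternative = "two.sided")
    expect_equal(got$p.value, p_two, tolerance = 1e-12)
    p_gr <- mean(Wall >= W)
    expect_equal(signed_rank_test(d, alternative = "greater")$p.value, p_gr)
  }
  # all-zero differences: degenerate p = 1
  expect_equal(signed_rank_test(rep(0, 5))$p.value, 1)
  # Pratt handling of zeros, against a hand enumeration: zeros occupy ranks
  # 1.5/1.5, signed ranks {3.5, 3.5, 5, 6}, W+ = 14.5, P(W >= 14.5) = 3/16
  d0 <- c(0, 0, 1, 2, 3, -1)
  r0 <- signed_rank_test(d0, zero_method = "pratt")
  expect_equal(r0$n, 4)
  expect_equal(r0$statistic, 14.5)
  expect_equal(r0$p.value, 2 * 3 / 16, tolerance = 1e-12)
})

test_that("signed-rank normal approximation is close to exact for moderate n", {
  set.seed(2)
  d <- rnorm(20, 0.4, 1)
  pe <- signed_rank_test(d, exact_max = 25)$p.value
  pn <- signed_rank_test(d, exact_max = 5)$p.value
  expect_lt(abs(pe - pn), 0.02)
})

test_that("paired gate comparison and BH across a declared family", {
  tbl <- synth_flow_counts(seed = 9)
  r <- paired_wilcoxon_groups(tbl, "Epo+IL-17A", "Epo",
                              groups = c("I", "II"),
                              alternative = "greater")
  expect_lt(r$p.value, 0.01)  # planted interaction makes combined larger
  # group III carries no Epo effect and no interaction: combined vs
  # IL-17A alone is pure noise there
  r3 <- paired_wilcoxon_groups(tbl, "Epo+IL-17A", "IL-17A", groups = "III")
  expect_gt(r3$p.value, 0.05)
  fam <- wilcoxon_family(tbl, list(
    list(treatment_a = "Epo+IL-17A", treatment_b = "Epo",
         groups = c("I", "II"), alternative = "greater"),
    list(treatment_a = "Epo+IL-17A", treatment_b = "Epo", groups = "III",
         alternative = "greater"),
    list(treatment_a = "IL-17A", treatment_b = "vehicle",
         alternative = "greater")))
  expect_equal(fam$p_adj, p.adjust(fam$p.value, "BH"))
  # hand application of the BH step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_true(all(fam$p_adj >= fam$p.value))
})

test_that("subset PCA: variance fractions sum to 1; planted factor loads on I/II", {
  tbl <- synth_flow_counts(seed = 21)
  pca <- subset_pca(tbl)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-10)
  expect_equal(nrow(pca$loadings), 44)  # 22 subsets x 2 tissues
  # the treatment-response factor (groups I/II co-vary) dominates PC1
  l1 <- abs(pca$loadings[, 1])
  g <- pca$features$group
  expect_gt(median(l1[g %in% c("I", "II")]), median(l1[g == "III"]))
  # degenerate: all mice identical
  tbl0 <- tbl
  tbl0$cells_per_g <- ave(tbl0$cells_per_g,
                          paste(tbl0$tissue, tbl0$subset))
  expect_error(subset_pca(tbl0), "degenerate|z-scored")
})

test_that("loading-group rank-sum: exact minimal p and null calibration", {
  # complete separation of 5 vs 5: two-sided p = 2 * (1 / choose(10, 5))
  x <- c(1, 2, 3, 4, 5); y <- c(6, 7, 8, 9, 10)
  p <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(p, 2 / choose(10, 5))
  tbl <- synth_flow_counts(seed = 2)
  pca <- subset_pca(tbl)
  r <- loading_group_test(pca)
  expect_true(r$p.value >= 0 && r$p.value <= 1)
  expect_error(loading_group_test(pca, groups_a = "nope"), "empty")
  # permuted labels: p uniform under the null (KS over simulated nulls)
  set.seed(4)
  vals <- rnorm(20)
  ps <- replicate(1000, {
    g <- sample(rep(c("A", "B"), 10))
    wilcox.test(vals[g == "A"], vals[g == "B"], exact = TRUE)$p.value
  })
  # discrete exact p-values are stochastically >= uniform: the rejection
  # rate at any alpha must not exceed alpha (within binomial error)
  for (a in c(0.05, 0.2, 0.5))
    expect_lt(mean(ps <= a), a + 2.58 * sqrt(a * (1 - a) / 1000))
})

test_that("Kruskal-Wallis H matches the hand formula; Conover + BY behave", {
  # 9 values, 3 groups; hand computation of tie-free H
  v <- c(1, 5, 9, 2, 6, 7, 3, 4, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- rank(v)
  H_hand <- 12 / (9 * 10) * sum(tapply(r, g, sum)^2 / 3) - 3 * 10
  out <- kruskal_conover(v, g)
  expect_equal(out$H, H_hand, tolerance = 1e-12)
  expect_equal(nrow(out$pairwise), 3)
  expect_true(all(out$pairwise$p_adj >= out$pairwise$p.value))
  # BY is more conservative than BH on the same p-vector
  pv <- out$pairwise$p.value
  expect_true(all(p.adjust(pv, "BY") >= p.adjust(pv, "BH")))
  # two identical groups: H ~ 0, omnibus p ~ 1
  out0 <- kruskal_conover(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(out0$H, 0.01)
  expect_gt(out0$omnibus_p, 0.9)
  expect_error(kruskal_conover(rep(1, 6), rep(c("a", "b"), 3)),
               "degenerate")
})

test_that("observed vs multiplicative fold change recovers the planted interaction", {
  # no interaction: ratio ~ 1 everywhere
  tbl0 <- synth_flow_counts(seed = 31, interaction = 1, cv = 0.15)
  m0 <- multiplicativity_observed(tbl0)
  ord <- m0$subset != "ProE" | m0$tissue != "spleen"  # ProE keeps its own
  expect_lt(max(abs(log(m0$ratio[ord]))), 0.5)
  # planted interaction = 2 on groups I/II only
  tbl2 <- synth_flow_counts(seed = 32, interaction = 2, cv = 0.15)
  m2 <- multiplicativity_observed(tbl2)
  ii <- m2$group %in% c("I", "II") & ord
  expect_equal(exp(mean(log(m2$ratio[ii]))), 2, tolerance = 0.25)
  expect_true(all(m2$super[ii]))
  g3 <- m2$group == "III"
  expect_lt(exp(mean(log(m2$ratio[g3]))), 1.3)
  # invariant to global rescaling
  tblr <- tbl2; tblr$cells_per_g <- tblr$cells_per_g * 1e4
  expect_equal(multiplicativity_observed(tblr)$ratio, m2$ratio)
  expect_error(multiplicativity_observed(tbl2[tbl2$treatment != "Epo", ]),
               "missing")
})

test_that("signed-rank type-I error is controlled at nominal 5% under the null", {
  set.seed(99)
  rej <- replicate(2000, {
    d <- rnorm(8)
    signed_rank_test(d)$p.value < 0.05
  })
  # binomial 99% CI around the (conservative, discrete) exact level
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 2000))
})
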