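test_that("the normality gate has its nominal operating characteristics", {
  set.seed(31)
  g <- normality_gate(rnorm(200))
  expect_named(g, c("classification", "W", "p"))
  # type-I rate of the gate close to its nominal 5%
  rej <- mean(replicate(1000,
    normality_gate(rnorm(50))$classification == "non_normal"))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # strongly skewed data are flagged essentially always
  pow <- mean(replicate(200,
    normality_gate(rexp(200))$classification == "non_normal"))
  expect_gt(pow, 0.99)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(2, 10)), "insufficient variance")
})

test_that("trend_with_age gates Pearson vs Spearman and flags degeneracy", {
  # coefficient a strictly increasing function of ED (tie structure shared)
  tab <- data.frame(ed = rep(c(13.5, 15.5, 17.5, 18.5), each = 5),
                    cc1 = rep(c(0.2, 0.4, 0.6, 0.8), each = 5))
  tr <- trend_with_age(tab, "cc1")
  expect_equal(tr$method, "spearman")  # discrete ED fails the gate
  expect_equal(tr$r, 1, tolerance = 1e-12)
  expect_lt(tr$p, 0.05)
  trp <- trend_with_age(tab, "cc1", method = "pearson")
  expect_equal(trp$method, "pearson")
  expect_gt(trp$r, 0.9)
  expect_error(trend_with_age(data.frame(ed = rep(13.5, 5), cc1 = rnorm(5)),
                              "cc1"),
               "degenerate design")
})

test_that("Spearman trends are invariant under monotone transforms", {
  set.seed(32)
  tab <- data.frame(ed = rep(c(13.5, 15.5, 17.5, 18.5), each = 8),
                    cc1 = runif(32))
  t1 <- trend_with_age(tab, "cc1", method = "spearman")
  tab$cc1 <- exp(5 * tab$cc1) - 2   # strictly monotone transform
  t2 <- trend_with_age(tab, "cc1", method = "spearman")
  expect_equal(t1$r, t2$r, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("null trends are rarely significant", {
  set.seed(33)
  p <- replicate(1000, {
    tab <- data.frame(ed = rep(c(13.5, 15.5, 17.5, 18.5), each = 6),
                      cc1 = rnorm(24))
    tr <- trend_with_age(tab, "cc1", method = "spearman")
    c(abs(tr$r), tr$p)
  })
  expect_gte(mean(p[2, ] > 0.05), 0.90)
  expect_lt(median(p[1, ]), 0.25)
})

test_that("group comparisons behave on identical, shifted and relabeled groups", {
  set.seed(34)
  x <- rnorm(13)
  same <- data.frame(ed = 15.5, group = rep(c("saline", "vpa"), each = 13),
                     cc1 = c(x, x))
  res <- compare_groups(same, "cc1", design = "saline_vs_vpa",
                        method = "rank_sum")
  expect_gt(res$p, 0.9)

  # groups 3 pooled SDs apart, n = 13: essentially always significant
  hits <- replicate(200, {
    tab <- data.frame(ed = 15.5,
                      group = rep(c("saline", "vpa"), each = 13),
                      cc1 = c(rnorm(13, 3), rnorm(13, 0)))
    compare_groups(tab, "cc1", design = "saline_vs_vpa")$p < 0.05
  })
  expect_gt(mean(hits), 0.99)

  # label order leaves p unchanged
  tab <- data.frame(ed = 15.5, group = rep(c("saline", "vpa"), each = 13),
                    cc1 = rnorm(26))
  flipped <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(compare_groups(tab, "cc1", design = "saline_vs_vpa")$p,
               compare_groups(flipped, "cc1", design = "saline_vs_vpa")$p)
})

test_that("stagewise design returns an omnibus plus all pairwise contrasts", {
  set.seed(35)
  tab <- data.frame(ed = rep(c(13.5, 15.5, 17.5, 18.5), each = 8),
                    group = "development",
                    cc1 = rnorm(32, rep(c(0, 0.3, 0.8, 1), each = 8), 0.3))
  res <- compare_groups(tab, "cc1", design = "stagewise")
  expect_equal(nrow(res), 1 + choose(4, 2))
  expect_equal(res$contrast[1], "omnibus")
  expect_lt(res$p[1], 0.01)
  holm <- compare_groups(tab, "cc1", design = "stagewise", adjust = "holm")
  pw <- holm$contrast != "omnibus"
  expect_true(all(holm$p_adj[pw] >= holm$p[pw]))
  expect_error(compare_groups(tab[tab$ed == 13.5, ], "cc1",
                              design = "stagewise"),
               ">= 2 embryonic days")
  expect_error(compare_groups(tab, "cc1", design = "saline_vs_vpa"),
               "present:")
})

test_that("epoch averaging aggregates to one row per fetus", {
  tab <- data.frame(mother_id = rep(c("m1", "m2", "m3"), each = 4),
                    fetus_id = rep(paste0("f", 1:6), each = 2),
                    epoch_index = rep(1:2, 6),
                    ed = 15.5,
                    group = rep(c("saline", "vpa"), each = 6),
                    cc1 = seq(0.1, 1.2, by = 0.1))
  res <- compare_groups(tab, "cc1", design = "saline_vs_vpa",
                        aggregate = "epoch_mean", method = "rank_sum")
  expect_equal(res$n, "3/3")
})

test_that("forced branches are calibrated under the null", {
  set.seed(36)
  reps <- 600
  p_an <- replicate(reps, {
    tab <- data.frame(ed = 15.5, group = rep(c("saline", "vpa"), each = 13),
                      cc1 = rnorm(26))
    compare_groups(tab, "cc1", design = "saline_vs_vpa",
                   method = "anova")$p
  })
  p_rs <- replicate(reps, {
    tab <- data.frame(ed = 15.5, group = rep(c("saline", "vpa"), each = 13),
                      cc1 = rnorm(26))
    compare_groups(tab, "cc1", design = "saline_vs_vpa",
                   method = "rank_sum")$p
  })
  expect_gt(mean(p_an < 0.05), 0.02)
  expect_lt(mean(p_an < 0.05), 0.09)
  expect_gt(mean(p_rs < 0.05), 0.02)
  expect_lt(mean(p_rs < 0.05), 0.09)
})
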