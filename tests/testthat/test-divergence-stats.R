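mk_dm <- function(taxa, value) {
  d <- matrix(value, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  diag(d) <- 0
  d
}

test_that("focal and grand mean distances are plain arithmetic means", {
  d <- mk_dm(c("W", "X", "Y"), 0)
  d["W", "X"] <- d["X", "W"] <- 1
  d["W", "Y"] <- d["Y", "W"] <- 3
  d["X", "Y"] <- d["Y", "X"] <- 2
  expect_equal(focal_mean_distance(d, "W"), 2)
  d2 <- mk_dm(c("W", "Z"), 0.7)
  expect_equal(focal_mean_distance(d2, "W"), 0.7)
  expect_error(focal_mean_distance(d, "Q"), "absent")
  expect_equal(grand_mean_distance(list(mk_dm(letters[1:3], 1),
                                        mk_dm(letters[1:3], 2))), 1.5)
  expect_equal(grand_mean_distance(list(d)), 2)
})

test_that("genes with missing taxa contribute their own pair means", {
  d7 <- mk_dm(paste0("t", 1:7), 2)
  d6 <- mk_dm(paste0("t", 1:6), 1)   # one taxon absent
  d3 <- mk_dm(paste0("t", 1:3), 4)
  expect_equal(grand_mean_distance(list(d7, d6, d3)), (2 + 1 + 4) / 3)
})

test_that("relative rates follow the published formula and its fixed points", {
  taxa <- c("W", "X", "Y")
  m1 <- mk_dm(taxa, 1); m2 <- mk_dm(taxa, 2)
  rr <- relative_rates(list(g1 = m1, g2 = m2), "W")
  expect_equal(rr$relative_rate, c(2 / 3, 4 / 3))
  # equal distances across genes: every rate is exactly 1
  rr1 <- relative_rates(list(g1 = m1, g2 = mk_dm(taxa, 1)), "W")
  expect_equal(rr1$relative_rate, c(1, 1))
  # scale invariance
  rr_scaled <- relative_rates(list(g1 = 37.5 * m1, g2 = 37.5 * m2), "W")
  expect_equal(rr_scaled$relative_rate, rr$relative_rate, tolerance = 1e-12)
  # a gene lacking the focal taxon is dropped with a warning
  expect_warning(
    rr_drop <- relative_rates(list(g1 = m1, g3 = mk_dm(c("X", "Y"), 1)), "W"),
    "lacking the focal taxon")
  expect_equal(nrow(rr_drop), 1)
})

test_that("one-sample t summary matches the closed form", {
  s <- one_sample_t(c(1, 2, 3), mu0 = 1)
  expect_equal(s$mean, 2)
  expect_equal(s$se, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(s$t, sqrt(3), tolerance = 1e-10)
  expect_equal(s$df, 2)
  sym <- one_sample_t(c(0.5, 1.5, 0.8, 1.2), mu0 = 1)
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_equal(sym$p, 1, tolerance = 1e-12)
  expect_error(one_sample_t(c(2, 2, 2)), "zero variance")
})

test_that("group means recombine into the combined mean", {
  tab <- clock_gene_table()
  g <- group_summaries(tab)
  expect_equal((9 * g$mean[g$category == "TTFL"] +
                  8 * g$mean[g$category == "PTM"]) / 17,
               g$mean[g$category == "combined"], tolerance = 1e-12)
})

test_that("identically drawn groups have statistically indistinguishable means", {
  set.seed(42)
  reps <- replicate(50, {
    rec <- data.frame(relative_rate = stats::rlnorm(17, 0, 0.4),
                      group = rep(c("TTFL", "PTM"), c(9, 8)))
    g <- group_summaries(rec)
    g$mean[g$category == "TTFL"] - g$mean[g$category == "PTM"]
  })
  expect_lt(abs(mean(reps)), 3 * stats::sd(reps) / sqrt(length(reps)))
})

test_that("2xk Fisher enumeration matches hand and closed-form results", {
  expect_equal(fisher_exact_2xk(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2xk(rbind(c(3, 1, 2), c(3, 1, 2))), 1,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2xk(tab), fisher_2x2_closed(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("2xk Fisher enumeration matches the reference implementation", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 2), 2)
    if (any(colSums(tab) == 0) || sum(tab) == 0) next
    expect_equal(fisher_exact_2xk(tab),
                 stats::fisher.test(tab, workspace = 2e6)$p.value,
                 tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
  expect_error(fisher_exact_2xk(matrix(0, 2, 2)), "all-zero")
})

test_that("rate-length regression detects collinearity and is calibrated under the null", {
  rec <- data.frame(relative_rate = c(1, 2, 3, 4), nucleotides = c(10, 20, 30, 40))
  r <- regress_rate_on_length(rec)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  set.seed(2)
  ps <- replicate(200, {
    rec <- data.frame(relative_rate = stats::rnorm(17),
                      nucleotides = sample(400:3000, 17))
    regress_rate_on_length(rec)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ANCOVA group t matches a hand-solved normal-equations fixture", {
  rec <- data.frame(relative_rate = c(1.0, 1.2, 1.4, 0.8, 0.9, 1.3),
                    group = rep(c("TTFL", "PTM"), each = 3),
                    nucleotides = c(100, 200, 300, 120, 220, 340))
  a <- ancova_group_effect(rec)
  X <- cbind(1, rec$group == "TTFL", rec$nucleotides)
  beta <- solve(t(X) %*% X, t(X) %*% rec$relative_rate)
  res <- rec$relative_rate - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(abs(a$t), abs(beta[2] / se), tolerance = 1e-10)
  expect_equal(a$df, 3)
  # identical groups: no effect
  rec0 <- rec
  rec0$relative_rate <- rep(c(1, 1.3, 1.1), 2)
  rec0$nucleotides <- rep(c(100, 200, 300), 2)
  expect_equal(abs(ancova_group_effect(rec0)$t), 0, tolerance = 1e-10)
})

test_that("residual ANOVA equals the squared pooled t and has power for real shifts", {
  tab <- clock_gene_table()
  ra <- residual_anova(tab)
  res <- stats::resid(stats::lm(relative_rate ~ nucleotides, data = tab))
  tt <- stats::t.test(res ~ tab$group, var.equal = TRUE)
  expect_equal(ra$F, unname(tt$statistic)^2, tolerance = 1e-10)
  set.seed(3)
  hits <- replicate(100, {
    rec <- data.frame(
      nucleotides = sample(400:3000, 40),
      group = rep(c("TTFL", "PTM"), each = 20))
    rec$relative_rate <- stats::rnorm(40) + (rec$group == "TTFL") * 1
    residual_anova(rec)$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
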