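test_that("mean/SD summaries use the n-1 denominator and degenerate rules", {
  s <- summarize_metric(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(summarize_metric(rep(4.2, 5))$sd, 0)
  expect_equal(summarize_metric(7)$sd, 0)
  expect_equal(summarize_metric(7)$mean, 7)
  expect_error(summarize_metric(numeric(0)), "empty")
})

# independent oracle: classical sums-of-squares ANOVA computed from scratch
anova_oracle <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group); n <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(values, group, function(v) (v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# independent oracle: Tukey-Kramer adjusted p from the studentized range
tukey_oracle <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group); n <- length(values)
  mse <- sum(unlist(tapply(values, group, function(v) (v - mean(v))^2))) / (n - k)
  means <- tapply(values, group, mean)
  sizes <- tapply(values, group, length)
  pairs <- utils::combn(levels(group), 2)
  p <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    stats::ptukey(q, k, n - k, lower.tail = FALSE)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_adj = as.numeric(p))
}

test_that("ANOVA matches the sums-of-squares oracle on a fixed fixture", {
  set.seed(501)
  values <- c(rnorm(8, 10, 2), rnorm(8, 12, 2), rnorm(8, 9, 2))
  group <- rep(c("CRT", "IMRT", "VMAT"), each = 8)
  got <- one_way_anova(values, group)
  want <- anova_oracle(values, group)
  expect_equal(got$F, want$F, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
  expect_equal(got$df_between, 2)
  expect_equal(got$df_within, 21)

  # two groups: F equals the square of the pooled-variance t statistic
  v2 <- values[1:16]; g2 <- group[1:16]
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(one_way_anova(v2, g2)$F, unname(tt$statistic)^2, tolerance = 1e-9)

  # permutations of the same values across groups: F = 0, p = 1
  base <- c(1, 2, 3, 4)
  got <- one_way_anova(c(base, rev(base), sample(base)),
                       rep(c("a", "b", "c"), each = 4))
  expect_equal(got$F, 0, tolerance = 1e-12)
  expect_equal(got$p, 1)

  # all-constant groups with equal means: F = 0, p = 1 (0/0 guarded)
  got <- one_way_anova(rep(5, 12), rep(c("a", "b", "c"), each = 4))
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)

  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), "at least two")
  expect_error(one_way_anova(1:3, c("a", "b", "c")), "at least two values")
})

test_that("Tukey HSD matches the studentized-range oracle", {
  set.seed(502)
  values <- c(rnorm(8, 10, 2), rnorm(8, 12, 2), rnorm(8, 9, 2))
  group <- rep(c("CRT", "IMRT", "VMAT"), each = 8)
  got <- tukey_hsd(values, group)
  want <- tukey_oracle(values, group)
  expect_equal(got$p_adj, want$p_adj, tolerance = 1e-4)
  # adjusted p >= unadjusted pairwise p under equal variances
  for (i in seq_len(nrow(got))) {
    sel <- group %in% c(got$group1[i], got$group2[i])
    raw <- stats::t.test(values[sel] ~ droplevels(factor(group[sel])),
                         var.equal = TRUE)$p.value
    expect_gte(got$p_adj[i] + 1e-9, raw)
  }

  # unequal group sizes go through the Tukey-Kramer variant
  values_u <- c(rnorm(5, 10), rnorm(8, 11), rnorm(6, 9))
  group_u <- rep(c("a", "b", "c"), times = c(5, 8, 6))
  expect_equal(tukey_hsd(values_u, group_u)$p_adj,
               tukey_oracle(values_u, group_u)$p_adj, tolerance = 1e-4)

  # identical groups: all pairwise p = 1
  got <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(got$p_adj == 1))

  # one far-separated group: its two pairs significant, the close pair not
  set.seed(503)
  v <- c(rnorm(8, 10, 1), rnorm(8, 10.3, 1), rnorm(8, 30, 1))
  g <- rep(c("a", "b", "c"), each = 8)
  got <- tukey_hsd(v, g)
  p_ab <- got$p_adj[got$group1 == "a" & got$group2 == "b"]
  expect_gt(p_ab, 0.05)
  expect_lt(max(got$p_adj[got$group2 == "c"]), 0.05)
})

test_that("ANOVA and Tukey respect shift/scale invariance and separation monotonicity", {
  set.seed(504)
  values <- c(rnorm(6, 5), rnorm(6, 6), rnorm(6, 7))
  group <- rep(c("a", "b", "c"), each = 6)
  base <- one_way_anova(values, group)
  shifted <- one_way_anova(values + 100, group)
  scaled <- one_way_anova(values * 3.7, group)
  expect_equal(base$p, shifted$p, tolerance = 1e-9)
  expect_equal(base$p, scaled$p, tolerance = 1e-9)

  # moving two group means apart (variances fixed) never raises Tukey p
  centred <- values - ave(values, group)
  seps <- c(0.5, 1, 2, 4)
  ps <- vapply(seps, function(d) {
    v <- centred + rep(c(0, d, 2 * d), each = 6)
    tukey_hsd(v, group)$p_adj[1]   # a-b pair
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-9))
})

test_that("cohort report assembles means, tests and flags consistently", {
  # three byte-identical modalities: equal means, all pairwise p = 1
  panels <- expand.grid(
    patient_id = sprintf("P%d", 1:4), modality = c("CRT", "IMRT", "VMAT"),
    stringsAsFactors = FALSE
  )
  panels$structure <- "lung"; panels$metric <- "V5"
  panels$value <- rep(c(40, 42, 44, 46), times = 3)
  rep1 <- build_report(panels = panels)
  expect_equal(rep1$crt_mean, rep1$imrt_mean)
  expect_equal(rep1$crt_mean, 43)
  expect_true(all(c(rep1$p_crt_imrt, rep1$p_crt_vmat, rep1$p_imrt_vmat) == 1))
  expect_false(any(rep1$sig_crt_imrt))

  # significance flags match the 0.05 threshold elementwise
  panels$value[panels$modality == "VMAT"] <- c(80, 82, 84, 86)
  rep2 <- build_report(panels = panels)
  expect_true(rep2$p_crt_vmat < 0.05 && rep2$sig_crt_vmat)
  expect_true(rep2$p_crt_imrt > 0.05 && !rep2$sig_crt_imrt)

  # ANOVA gating suppresses pairwise p when the omnibus test is null
  panels$value <- rep(c(40, 42, 44, 46), times = 3)
  rep3 <- build_report(panels = panels, gate_on_anova = TRUE)
  expect_true(is.na(rep3$p_crt_imrt))

  # unbalanced cohorts are rejected with the missing pairs named
  expect_error(build_report(panels = panels[panels$modality != "VMAT" |
                                              panels$patient_id != "P2", ]),
               "P2, VMAT")
})
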