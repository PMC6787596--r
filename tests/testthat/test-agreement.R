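# Device-agreement statistics: Pearson, Bland-Altman, two-way ANOVA,
# repeated-reading correlations.

textbook_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

test_that("pearson matches the textbook formula and handles exact relations", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson(x, -x)$r, -1.0)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  expect_lt(abs(pearson(x, y)$r - textbook_pearson(x, y)), 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 2:3), "3 complete pairs")
})

test_that("pearson is invariant under positive affine transforms", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.5)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    c2 <- runif(1, 0.1, 5); d <- rnorm(1)
    expect_equal(pearson(a * x + b, c2 * y + d)$r, pearson(x, y)$r,
                 tolerance = 1e-12)
  }
})

test_that("bland_altman reproduces mean/SD limits and degenerate cases", {
  a <- c(1.2, 1.5, 2.0)
  ba0 <- bland_altman(a, a)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  bas <- bland_altman(a, a - 0.1)
  expect_equal(c(bas$bias, bas$loa_low, bas$loa_high), c(0.1, 0.1, 0.1))
  # random pairs vs the direct mean/SD oracle
  set.seed(10)
  x <- rnorm(50, 3, 1); y <- x + rnorm(50, 0.05, 0.1)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_lt(abs(ba$bias - mean(d)), 1e-12)
  expect_lt(abs(ba$loa_high - (mean(d) + 1.96 * sd(d))), 1e-12)
  expect_lt(abs(ba$loa_low - (mean(d) - 1.96 * sd(d))), 1e-12)
  expect_equal(ba$points$mean, (x + y) / 2)
})

test_that("bland_altman is antisymmetric under device relabelling", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(25, 2); y <- rnorm(25, 2.1)
    f <- bland_altman(x, y); r <- bland_altman(y, x)
    expect_equal(f$bias, -r$bias, tolerance = 1e-12)
    expect_equal(f$loa_low, -r$loa_high, tolerance = 1e-12)
    expect_equal(f$loa_high, -r$loa_low, tolerance = 1e-12)
  }
})

test_that("two-factor ANOVA matches a cell-means sums-of-squares oracle", {
  # balanced 2 x 3 design with known effects
  set.seed(21)
  dev <- rep(c("a", "b"), each = 30)
  grp <- rep(rep(c("g1", "g2", "g3"), each = 10), 2)
  mu <- 2 + 0.3 * (dev == "b") + 0.5 * (grp == "g2") - 0.4 * (grp == "g3") +
    0.2 * (dev == "b" & grp == "g3")
  y <- mu + rnorm(60, sd = 0.3)
  tab <- two_factor_anova(y, dev, grp)

  # independent oracle: classical balanced two-way SS decomposition
  n_cell <- 10; a <- 2; b <- 3
  gm <- mean(y)
  m_dev <- tapply(y, dev, mean)
  m_grp <- tapply(y, grp, mean)
  m_cell <- tapply(y, interaction(dev, grp), mean)
  ss_a <- b * n_cell * sum((m_dev - gm)^2)
  ss_b <- a * n_cell * sum((m_grp - gm)^2)
  ss_cells <- n_cell * sum((m_cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, interaction(dev, grp)))^2)
  f_a <- (ss_a / (a - 1)) / (ss_e / (a * b * (n_cell - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_e / (a * b * (n_cell - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) / (ss_e / (a * b * (n_cell - 1)))

  expect_lt(abs(tab$sum_sq[tab$term == "device"] - ss_a), 1e-9)
  expect_lt(abs(tab$sum_sq[tab$term == "group"] - ss_b), 1e-9)
  expect_lt(abs(tab$sum_sq[tab$term == "device:group"] - ss_ab), 1e-9)
  expect_lt(abs(tab$f[tab$term == "device"] - f_a), 1e-9)
  expect_lt(abs(tab$f[tab$term == "group"] - f_b), 1e-9)
  expect_lt(abs(tab$f[tab$term == "device:group"] - f_ab), 1e-9)
})

test_that("ANOVA edge cases: constant response, empty cells, t-test reduction", {
  dev <- rep(c("a", "b"), each = 6)
  grp <- rep(c("g1", "g2"), 6)
  tab0 <- two_factor_anova(rep(5, 12), dev, grp)
  expect_true(all(tab0$f[tab0$term != "residuals"] == 0))
  # empty cell is named in the error
  expect_error(
    two_factor_anova(rnorm(8), rep(c("a", "b"), each = 4),
                     c(rep("g1", 4), rep("g2", 4))),
    "empty cell")
  # single-level second factor reduces to one-way ANOVA with F = t^2
  set.seed(3)
  y <- c(rnorm(12, 1), rnorm(12, 1.4))
  d <- rep(c("a", "b"), each = 12)
  tab <- two_factor_anova(y, d, rep("all", 24))
  tt <- t.test(y ~ d, var.equal = TRUE)
  expect_equal(tab$f[tab$term == "device"], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("repeated-reading correlations match per-pair Pearson with deletion", {
  m <- cbind(c(1, 2, 3, 4, 5), c(1.1, 2.2, 2.8, 4.3, 5.1),
             c(0.9, 2.1, 3.3, 3.8, 5.2))
  rr <- repeated_reading_correlation(m)
  expect_equal(rr$pair, c("1-2", "1-3", "2-3"))
  for (j in 1:3) {
    pr <- pearson(m[, utils::combn(3, 2)[1, j]], m[, utils::combn(3, 2)[2, j]])
    expect_equal(rr$r[j], pr$r)
    expect_equal(rr$p[j], pr$p)
  }
  # duplicate columns correlate perfectly
  dup <- repeated_reading_correlation(cbind(1:5, 1:5))
  expect_equal(dup$r[1], 1.0)
  # independent noise decorrelates at large n
  set.seed(9)
  noise <- repeated_reading_correlation(cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(noise$r[1]), 0.1)
  # a column with too many missing readings is reported unavailable
  m2 <- m; m2[1:3, 3] <- NA
  rr2 <- repeated_reading_correlation(m2)
  expect_false(rr2$available[rr2$pair == "1-3"])
  expect_equal(rr2$n[rr2$pair == "1-3"], 2)
})

test_that("agreement report bundles the benchmark statistics coherently", {
  set.seed(33)
  n <- 30
  truth <- runif(n, 1, 4)
  paired <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:10), 3),
    group = rep(rep(c("control", "asthma", "COPD"), c(4, 3, 3)), 3),
    maneuver_index = rep(1:3, each = 10),
    value_device_a = truth + rnorm(n, 0, 0.03),
    value_device_b = truth + rnorm(n, 0.02, 0.03))
  rep_ <- agreement_report(paired, "FEV1")
  expect_equal(rep_$n_pairs, n)
  expect_true(rep_$loa_low <= rep_$bias && rep_$bias <= rep_$loa_high)
  expect_lte(abs(rep_$pearson_r), 1)
  expect_true(all(c("device", "group", "device:group") %in%
                    rep_$anova_table$term))
  # incomplete pairs are excluded and counted
  paired$value_device_b[1] <- NA
  rep2 <- agreement_report(paired, "FEV1")
  expect_equal(rep2$n_pairs, n - 1)
  expect_equal(rep2$n_excluded, 1)
  # per-subject mode aggregates maneuvers first
  rep3 <- agreement_report(paired[complete.cases(paired), ], "FEV1",
                           anova_mode = "per_subject")
  expect_equal(rep3$anova_table$df[rep3$anova_table$term == "residuals"],
               2 * 10 - 6)
})
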