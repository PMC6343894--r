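test_that("Kruskal-Wallis matches hand values and degenerate limits", {
  k <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(k$statistic, 7.2)
  expect_equal(k$df, 2L)
  expect_equal(k$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  tied <- kruskal_wallis(rep(5, 12), rep(1:3, each = 4))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  expect_error(kruskal_wallis(1:5, rep(1, 5)), "at least 2 groups")
  expect_error(kruskal_wallis(1:4, rep(1:2, 3)), "equal length")
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test under heavy ties", {
  set.seed(20)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(3:8, k, replace = TRUE)
    g <- rep(seq_len(k), n)
    x <- sample(1:4, sum(n), replace = TRUE)  # many ties
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, naive_kruskal(x, g), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(30); g <- rep(1:3, each = 10)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(exp(x), g)$statistic, h0)
  expect_equal(kruskal_wallis(x^3, g)$statistic, h0)
  expect_equal(kruskal_wallis(rank(x), g)$statistic, h0)
})

test_that("Nemenyi contrasts match an independent evaluation of the formulas", {
  set.seed(6)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  g <- rep(c("a", "b", "c"), each = 4)
  N <- 12; k <- 3
  r <- rank(x)
  rbar <- tapply(r, g, mean)

  ours <- nemenyi_pairwise(x, g, "chisq")
  for (row in seq_len(nrow(ours))) {
    i <- ours$group1[row]; j <- ours$group2[row]
    stat <- (rbar[[i]] - rbar[[j]])^2 / ((N * (N + 1) / 12) * (1 / 4 + 1 / 4))
    expect_equal(ours$statistic[row], stat, tolerance = 1e-12)
    expect_equal(ours$p_value[row], pchisq(stat, k - 1, lower.tail = FALSE))
  }

  tuk <- nemenyi_pairwise(x, g, "tukey")
  for (row in seq_len(nrow(tuk))) {
    i <- tuk$group1[row]; j <- tuk$group2[row]
    q <- abs(rbar[[i]] - rbar[[j]]) / sqrt((N * (N + 1) / 24) * (1 / 4 + 1 / 4))
    expect_equal(tuk$statistic[row], q, tolerance = 1e-12)
    expect_equal(tuk$p_value[row], ptukey(q, k, Inf, lower.tail = FALSE))
  }

  # identical rank means give statistic 0, p = 1
  x2 <- rep(c(1, 2, 3), 3)
  eq <- nemenyi_pairwise(x2, rep(c("a", "b", "c"), each = 3), "chisq")
  expect_equal(eq$statistic, rep(0, 3))
  expect_equal(eq$p_value, rep(1, 3))

  expect_error(nemenyi_pairwise(1:6, rep(1:2, 3)), "at least 3 groups")
})

test_that("the largest rank gap earns the smallest Nemenyi p in balance", {
  set.seed(8)
  x <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 5))
  g <- rep(1:3, each = 5)
  res <- nemenyi_pairwise(x, g)
  r <- rank(x); rbar <- tapply(r, g, mean)
  gaps <- abs(rbar[match(res$group1, names(rbar))] -
                rbar[match(res$group2, names(rbar))])
  expect_equal(order(gaps), order(-res$p_value))
})

test_that("CA total inertia equals chi-squared over N", {
  set.seed(30)
  for (i in 1:10) {
    tab <- matrix(rpois(24, 8) + 1, 4, 6)
    ca <- correspondence_analysis(tab)
    chi <- suppressWarnings(stats::chisq.test(tab)$statistic)
    expect_equal(ca$total_inertia, unname(chi) / sum(tab), tolerance = 1e-10)
    expect_equal(sum(ca$proportion), 1, tolerance = 1e-10)
    expect_length(ca$principal_inertias, 3)  # min(4, 6) - 1 axes
  }
})

test_that("CA handles rank-1 and 2x2 tables as the geometry dictates", {
  # proportional rows: independence exactly, inertia 0, degenerate
  tab <- rbind(c(2, 4, 8), c(1, 2, 4), c(4, 8, 16))
  ca <- correspondence_analysis(tab)
  expect_true(ca$degenerate)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(is.na(ca$proportion)))

  # any associated 2x2 table has a single axis carrying everything
  tab2 <- rbind(c(10, 2), c(3, 9))
  ca2 <- correspondence_analysis(tab2)
  expect_length(ca2$proportion, 1)
  expect_equal(ca2$proportion, 1)

  expect_error(correspondence_analysis(rbind(c(1, 0), c(2, 0))), "all-zero")
  expect_error(correspondence_analysis(matrix(1, 1, 3)), "at least 2 rows")
  expect_error(correspondence_analysis(rbind(c(-1, 2), c(1, 1))),
               "non-negative")
})

test_that("CA row scores reproduce chi-squared distances between profiles", {
  set.seed(31)
  tab <- matrix(rpois(20, 6) + 1, 4, 5)
  ca <- correspondence_analysis(tab)
  d_scores <- unname(as.matrix(dist(ca$row_scores)))
  expect_equal(d_scores, profile_chisq_dist(tab), tolerance = 1e-10)
})

test_that("univariate one-factor PERMANOVA reduces to classical ANOVA", {
  set.seed(40)
  for (i in 1:5) {
    y <- rnorm(18)
    g <- factor(rep(1:3, each = 6))
    pm <- permanova(y, g, n_permutations = 49, seed = i)
    f_ref <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pm$terms$F[1], f_ref, tolerance = 1e-10)
  }
})

test_that("two-way sequential PERMANOVA matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(41)
  Y <- matrix(rpois(25 * 4, 10), 25, 4)
  f <- data.frame(
    event = rep(c("HP", "HP", "BF", "HP", "BF"), each = 5),
    configuration = rep(c("R0", "R1", "R1", "R2", "R2"), each = 5)
  )
  pm <- permanova(Y, f, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(Y ~ event + configuration, data = f,
                       method = "euclidean", permutations = 99, by = "terms")
  expect_equal(pm$terms$SumOfSqs[1:2], ad$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pm$terms$F[1:2], ad$F[1:2], tolerance = 1e-8)
  expect_equal(pm$terms$Df[1:2], ad$Df[1:2])
})

test_that("PERMANOVA pseudo-F is seed-independent; p is floored", {
  set.seed(42)
  Y <- matrix(rnorm(30), 15, 2)
  g <- factor(rep(1:3, each = 5))
  a <- permanova(Y, g, n_permutations = 99, seed = 1)
  b <- permanova(Y, g, n_permutations = 99, seed = 999)
  expect_identical(a$terms$F, b$terms$F)
  expect_gte(min(a$terms$p_value, na.rm = TRUE), 1 / 100)

  # strong separation bottoms out at 1/(n_perm + 1)
  Ys <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10, 50), 5, 2),
              matrix(rnorm(10, 100), 5, 2))
  strong <- permanova(Ys, g, n_permutations = 199, seed = 3)
  expect_equal(strong$terms$p_value[1], 1 / 200)

  expect_error(permanova(Y[1:3, ], factor(1:3), n_permutations = 9),
               "residual degrees of freedom")
})

test_that("PERMANOVA holds its nominal size under the null", {
  set.seed(43)
  g <- factor(rep(1:5, each = 5))
  n <- 25
  reject <- 0
  nsim <- 500
  for (s in seq_len(nsim)) {
    Y <- matrix(rnorm(n * 3), n, 3)
    pm <- permanova(Y, g, n_permutations = 199, seed = s)
    if (pm$terms$p_value[1] <= 0.05) reject <- reject + 1
  }
  expect_gt(reject / nsim, 0.03)
  expect_lt(reject / nsim, 0.07)
})

test_that("tidy_stat flattens every result type", {
  x <- rnorm(30); g <- rep(1:3, each = 10)
  expect_named(tidy_stat(kruskal_wallis(x, g), "glucose"),
               c("method", "response", "term", "statistic", "df", "p_value"))
  expect_equal(nrow(tidy_stat(nemenyi_pairwise(x, g), "glucose")), 3)
  pm <- permanova(x, factor(g), n_permutations = 9, seed = 1)
  expect_equal(tidy_stat(pm)$term, "factor")
})
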