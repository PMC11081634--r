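test_that("Kruskal-Wallis H matches the rank-sum formula", {
  # hand computation for {1,2,3} vs {4,5,6}: H = 12/(N(N+1)) * sum n_i
  # (Rbar_i - (N+1)/2)^2 = 3.857 with no ties
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 3.857, tolerance = 1e-3)
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_error(kruskal_wallis(1:5, c("a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    h1 <- kruskal_wallis(x, g)$statistic
    h2 <- kruskal_wallis(exp(3 * x) + 5, g)$statistic
    expect_equal(h1, h2)
  }
})

test_that("Kruskal-Wallis matches an independent rank computation", {
  brute_h <- function(x, g) {
    r <- rank(x)
    N <- length(x)
    num <- sum(tapply(r, g, function(ri) {
      length(ri) * (mean(ri) - (N + 1) / 2)^2
    }))
    h <- 12 / (N * (N + 1)) * num
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  set.seed(82)
  for (i in 1:1000) {
    n <- sample(6:15, 1)
    x <- sample(1:8, n, replace = TRUE) # plenty of ties
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (min(table(g)) < 2 || length(unique(g)) < 2) next
    expect_equal(kruskal_wallis(x, g)$statistic, brute_h(x, g),
                 tolerance = 1e-10)
  }
})

test_that("mixed ANOVA reproduces a manual sums-of-squares decomposition", {
  # balanced 2 (between) x 2 x 2 (within) design, 4 subjects per group
  set.seed(83)
  d <- expand.grid(subject = sprintf("s%02d", 1:8),
                   w1 = c("lo", "hi"), w2 = c("x", "y"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:4), "g1", "g2")
  d$y <- rnorm(nrow(d)) + (d$group == "g2") * 0.8 + (d$w1 == "hi") * 0.5
  res <- mixed_anova_3way(d, dv = "y", within = c("w1", "w2"),
                          between = "group", subject = "subject")

  # independent oracle: textbook mean-based SS for the balanced mixed design
  gm <- mean(d$y)
  cell <- function(...) aggregate(y ~ ..., data = d, FUN = mean)
  n_s <- 8; n_w1 <- 2; n_w2 <- 2
  ms <- aggregate(y ~ subject, d, mean)
  mg <- aggregate(y ~ group, d, mean)
  m1 <- aggregate(y ~ w1, d, mean)
  m2 <- aggregate(y ~ w2, d, mean)
  mg1 <- aggregate(y ~ group + w1, d, mean)
  mg2 <- aggregate(y ~ group + w2, d, mean)
  m12 <- aggregate(y ~ w1 + w2, d, mean)
  mg12 <- aggregate(y ~ group + w1 + w2, d, mean)
  ms1 <- aggregate(y ~ subject + w1, d, mean)
  ms2 <- aggregate(y ~ subject + w2, d, mean)
  ss_g <- 4 * n_w1 * n_w2 * sum((mg$y - gm)^2)
  ss_subj <- n_w1 * n_w2 * sum((ms$y - gm)^2) - ss_g
  ss_1 <- n_s * n_w2 * sum((m1$y - gm)^2)
  ss_g1 <- 4 * n_w2 * sum((mg1$y - gm)^2) - ss_g - ss_1
  ss_s1 <- n_w2 * sum((ms1$y - gm)^2) - ss_subj - ss_g - ss_1 - ss_g1
  ss_2 <- n_s * n_w1 * sum((m2$y - gm)^2)
  ss_g2 <- 4 * n_w1 * sum((mg2$y - gm)^2) - ss_g - ss_2
  ss_s2 <- n_w1 * sum((ms2$y - gm)^2) - ss_subj - ss_g - ss_2 - ss_g2
  ss_12 <- n_s * sum((m12$y - gm)^2) - ss_1 - ss_2
  ss_g12 <- 4 * sum((mg12$y - gm)^2) -
    ss_g - ss_1 - ss_2 - ss_g1 - ss_g2 - ss_12
  ss_tot <- sum((d$y - gm)^2)
  ss_s12 <- ss_tot - ss_g - ss_subj - ss_1 - ss_g1 - ss_s1 -
    ss_2 - ss_g2 - ss_s2 - ss_12 - ss_g12
  f_expect <- c(
    group = (ss_g / 1) / (ss_subj / 6),
    w1 = (ss_1 / 1) / (ss_s1 / 6),
    "group:w1" = (ss_g1 / 1) / (ss_s1 / 6),
    w2 = (ss_2 / 1) / (ss_s2 / 6),
    "group:w2" = (ss_g2 / 1) / (ss_s2 / 6),
    "w1:w2" = (ss_12 / 1) / (ss_s12 / 6),
    "group:w1:w2" = (ss_g12 / 1) / (ss_s12 / 6))
  for (eff in names(f_expect)) {
    expect_equal(res$statistic[res$effect == eff], unname(f_expect[eff]),
                 tolerance = 1e-8, label = paste("F for", eff))
  }
  # SS decomposition is exhaustive on the balanced design
  parts <- c(ss_g, ss_subj, ss_1, ss_g1, ss_s1, ss_2, ss_g2, ss_s2,
             ss_12, ss_g12, ss_s12)
  expect_equal(sum(parts), ss_tot, tolerance = 1e-8)
})

test_that("constant responses yield null effects and incomplete cases drop", {
  d <- expand.grid(subject = sprintf("s%02d", 1:6),
                   w1 = c("lo", "hi"), w2 = c("x", "y"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:3), "g1", "g2")
  d$y <- 1
  res <- mixed_anova_3way(d, dv = "y", within = c("w1", "w2"),
                          between = "group", subject = "subject")
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
  d2 <- d
  d2$y <- rnorm(nrow(d2))
  d2$y[d2$subject == "s01"][1] <- NA
  expect_message(
    res2 <- mixed_anova_3way(d2, dv = "y", within = c("w1", "w2"),
                             between = "group", subject = "subject"),
    "dropping 1 participant")
})

test_that("an injected group shift is detected against null companions", {
  set.seed(84)
  hits <- 0L
  others_null <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    d <- expand.grid(subject = sprintf("s%02d", 1:12),
                     w1 = c("lo", "hi"), w2 = c("b1", "b2"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:6), "g1", "g2")
    d$y <- rnorm(nrow(d), sd = 0.5) + (d$group == "g2") * 1.5
    res <- mixed_anova_3way(d, dv = "y", within = c("w1", "w2"),
                            between = "group", subject = "subject")
    res <- fdr_family(res)
    hits <- hits + (res$p_fdr[res$effect == "group"] < 0.05)
    others_null <- others_null +
      all(res$p_fdr[res$effect != "group"] >= 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
  expect_gte(others_null / n_rep, 0.8)
})

test_that("paired t matches the one-sample t on differences", {
  res0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_identical(res0$note, "degenerate")
  res_c <- paired_t(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_identical(res_c$note, "degenerate")
  expect_equal(res_c$p, 0)
  set.seed(85)
  for (i in 1:50) {
    a <- rnorm(10)
    b <- rnorm(10)
    res <- paired_t(a, b)
    ref <- t.test(a - b)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p, ref$p.value)
  }
})

test_that("BH adjustment matches the step-up computation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  stepup <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  set.seed(86)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, stepup(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # order-preserving
  }
})

test_that("tests hold their nominal type-I rate under the null", {
  set.seed(87)
  n_rep <- 10000L
  # Kruskal-Wallis, 3 groups of 8
  g <- rep(c("a", "b", "c"), each = 8)
  kw_rej <- mean(replicate(n_rep, {
    kruskal_wallis(rnorm(24), g)$p < 0.05
  }))
  expect_lt(abs(kw_rej - 0.05), 0.015)
  # paired t, n = 12 (vectorised over replicates)
  a <- matrix(rnorm(12 * n_rep), 12)
  b <- matrix(rnorm(12 * n_rep), 12)
  d <- a - b
  tstat <- sqrt(12) * colMeans(d) / apply(d, 2, sd)
  t_rej <- mean(2 * pt(-abs(tstat), 11) < 0.05)
  expect_lt(abs(t_rej - 0.05), 0.015)
})
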