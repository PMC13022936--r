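test_that("normality screen computes type-2 moments and applies the [-1,1] rule", {
  # symmetric 3-point sample: skewness exactly 0
  ns <- normality_screen(c(-1, 0, 1))
  expect_equal(ns$skewness, 0)
  expect_true(ns$acceptable)
  # hand oracle for the type-2 (SPSS) estimators on a fixed sample
  x <- c(1.2, -0.4, 0.3, 2.5, -1.1, 0.8, 0.1, -0.6)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  g1 <- m3 / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- m4 / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  ns2 <- normality_screen(x)
  expect_equal(ns2$skewness, G1, tolerance = 1e-12)
  expect_equal(ns2$kurtosis, G2, tolerance = 1e-12)
  # one extreme outlier among normals gets flagged
  set.seed(31)
  y <- c(rnorm(30), 25)
  expect_false(normality_screen(y)$acceptable)
  # large standard-normal sample: both moments near zero
  z <- rnorm(1e4)
  nz <- normality_screen(z)
  expect_lt(abs(nz$skewness), 0.1)
  expect_lt(abs(nz$kurtosis), 0.1)
  expect_error(normality_screen(c(1, 2)), "insufficient-data")
})

test_that("mixed ANOVA reproduces the classical sums-of-squares oracle", {
  # fixed 6-subject toy table, constant covariate (drops out)
  toy <- data.frame(
    group = rep(c("clinical", "control"), each = 3),
    age = 10,
    a = c(5.0, 6.0, 5.5, 4.0, 4.5, 4.2),
    b = c(4.8, 5.9, 5.6, 3.1, 3.6, 3.4)
  )
  full <- mixed_anova_covariate(toy, "a", "b")
  res <- full$anova
  # Bonferroni pairwise set: group at each level, condition in each group
  expect_identical(nrow(full$pairwise), 4L)
  expect_true(all(full$pairwise$p_adj >= 0 & full$pairwise$p_adj <= 1))
  # explicit classical mixed-design decomposition on the stacked data
  y <- c(toy$a, toy$b)
  subj <- rep(1:6, 2)
  w <- rep(1:2, each = 6)
  g <- rep(toy$group, 2)
  GM <- mean(y)
  S <- tapply(y, subj, mean)
  G <- tapply(y, g, mean)
  W <- tapply(y, w, mean)
  M <- tapply(y, list(g, w), mean)
  ss_between <- 2 * sum((S - GM)^2)
  ss_group <- sum(tapply(y, g, length) * (G - GM)^2)
  ss_err_b <- ss_between - ss_group
  ss_within_tot <- sum((y - S[subj])^2)
  ss_w <- sum(tapply(y, w, length) * (W - GM)^2)
  ss_int <- sum(vapply(rownames(M), function(gg) {
    sum(3 * (M[gg, ] - G[gg] - W + GM)^2)
  }, 0))
  ss_err_w <- ss_within_tot - ss_w - ss_int
  f_oracle <- c(
    within = (ss_w / 1) / (ss_err_w / 4),
    interaction = (ss_int / 1) / (ss_err_w / 4),
    group = (ss_group / 1) / (ss_err_b / 4)
  )
  expect_equal(res$F[res$effect == "within"], f_oracle[["within"]],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "within:group"],
               f_oracle[["interaction"]], tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group"], f_oracle[["group"]],
               tolerance = 1e-10)
  expect_equal(res$peta2[res$effect == "group"],
               ss_group / (ss_group + ss_err_b), tolerance = 1e-10)
  expect_equal(res$df2, rep(4, 3))
})

test_that("mixed ANOVA degenerates gracefully with no within-condition change", {
  tab <- data.frame(
    group = rep(c("clinical", "control"), each = 4),
    age = c(10, 12, 14, 16, 11, 13, 15, 17),
    a = c(5, 6, 7, 8, 4, 5, 6, 7)
  )
  tab$b <- tab$a  # identical condition values: d = 0 for everyone
  res <- mixed_anova_covariate(tab, "a", "b")$anova
  expect_lt(res$F[res$effect == "within"], 1e-6)
  expect_lt(res$F[res$effect == "within:group"], 1e-6)
  expect_error(
    mixed_anova_covariate(
      data.frame(group = c("x", "x", "y"), age = 1:3,
                 a = rnorm(3), b = rnorm(3)), "a", "b"),
    "fewer than 2"
  )
})

test_that("one-way ANCOVA adjusts out an age confound", {
  set.seed(32)
  # identical group means, uninformative covariate: F near 0
  tab0 <- data.frame(group = rep(c("clinical", "control"), each = 20),
                     age = 15)
  tab0$dv <- rep(rnorm(20), 2)  # same values in both groups
  r0 <- ancova_oneway(tab0, "dv")$anova
  expect_lt(r0$F[r0$effect == "group"], 1e-6)
  # dv perfectly linear in age with confounded age distributions:
  # the unadjusted t-test rejects, the ANCOVA group effect is null
  tabc <- data.frame(group = rep(c("clinical", "control"), each = 20),
                     age = c(seq(8, 18, length.out = 20),
                             seq(18, 28, length.out = 20)))
  tabc$dv <- 2 * tabc$age
  t_raw <- t.test(dv ~ group, tabc)$p.value
  expect_lt(t_raw, 1e-6)
  rc <- ancova_oneway(tabc, "dv")$anova
  expect_lt(rc$F[rc$effect == "group"], 1e-6)
})

test_that("ANCOVA detects a 1-SD group offset at n = 40 per group", {
  hits <- vapply(1:30, function(s) {
    set.seed(400 + s)
    tab <- data.frame(group = rep(c("clinical", "control"), each = 40),
                      age = runif(80, 5, 34))
    tab$dv <- rnorm(80) + ifelse(tab$group == "clinical", 1, 0)
    r <- ancova_oneway(tab, "dv")$anova
    r$p[r$effect == "group"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  set.seed(33)
  n <- 12
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  z <- rnorm(n)
  pp <- partial_pearson(x, y, data.frame(z = z))
  Z <- cbind(1, z)
  rx <- x - Z %*% solve(crossprod(Z), crossprod(Z, x))
  ry <- y - Z %*% solve(crossprod(Z), crossprod(Z, y))
  r_or <- cor(rx, ry)[1]
  expect_equal(pp$r, r_or, tolerance = 1e-12)
  df <- n - 2 - 1
  t_or <- r_or * sqrt(df / (1 - r_or^2))
  expect_equal(pp$p, 2 * pt(-abs(t_or), df), tolerance = 1e-12)
  # exactly orthogonal covariate leaves the plain correlation unchanged
  zres <- residuals(lm(rnorm(n) ~ x + y))
  pp2 <- partial_pearson(x, y, data.frame(z = zres))
  expect_equal(pp2$r, cor(x, y), tolerance = 1e-12)
  # y fully explained by a covariate: partial r collapses to zero
  pp3 <- partial_pearson(x, y, data.frame(z = y))
  expect_equal(pp3$r, 0)
  expect_error(partial_pearson(x, rep(1, n), data.frame(z = z)),
               "undefined-correlation")
})

test_that("BH step-up matches the hand-computed rule and is monotone", {
  # p(k) <= k * 0.05 / 4 for all four: everything rejected
  expect_identical(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  expect_identical(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_identical(fdr_bh(0.04), TRUE)
  expect_identical(fdr_bh(numeric(0)), logical(0))
  # explicit step-up oracle on random vectors
  set.seed(34)
  for (i in 1:25) {
    p <- runif(sample(3:12, 1))
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * 0.05 / m)
    oracle <- rep(FALSE, m)
    if (length(ks)) oracle[o[seq_len(max(ks))]] <- TRUE
    expect_identical(fdr_bh(p), oracle)
    # monotonicity: lowering one p never un-rejects another
    j <- sample(m, 1)
    p2 <- p
    p2[j] <- p[j] / 2
    f1 <- fdr_bh(p)
    f2 <- fdr_bh(p2)
    expect_true(all(f2[-j] >= f1[-j]))
  }
})

test_that("a single-pair screen reduces to partial_pearson plus one-test BH", {
  set.seed(35)
  tab <- data.frame(sex = sample(c("M", "F"), 30, TRUE),
                    age = runif(30, 5, 34))
  tab$feat <- rnorm(30)
  tab$adhd <- 0.6 * tab$feat + rnorm(30)
  pairs <- data.frame(feature = "feat", score = "adhd", family = "adhd")
  scr <- correlation_screen(tab, pairs)
  pp <- partial_pearson(tab$feat, tab$adhd,
                        data.frame(sex = as.numeric(factor(tab$sex)),
                                   age = tab$age))
  expect_equal(scr$r, pp$r, tolerance = 1e-12)
  expect_equal(scr$p, pp$p, tolerance = 1e-12)
  expect_identical(scr$fdr_flag, pp$p <= 0.05)
  expect_identical(scr$covariates, "sex,age")
  # age-normed scores drop the age covariate
  tab$nviq <- rnorm(30)
  pairs2 <- data.frame(feature = "feat", score = "nviq",
                       family = "cognition")
  scr2 <- correlation_screen(tab, pairs2)
  expect_identical(scr2$covariates, "sex")
  expect_error(
    correlation_screen(tab, data.frame(feature = "nope", score = "adhd",
                                       family = "adhd")),
    "config"
  )
})
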