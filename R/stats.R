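# Inference layer: normality screen, mixed-design ANOVA with covariate,
# one-way ANCOVA, covariate-adjusted Pearson correlations with BH FDR.

#' Skewness/kurtosis normality screen
#'
#' Sample skewness and excess kurtosis (type 2 estimators, as reported
#' by SPSS); the distribution is considered acceptable when both lie in
#' `[-1, 1]`. Kurtosis needs at least 4 observations; with n = 3 only
#' skewness is screened.
#'
#' @param values Numeric sample, n >= 3.
#' @return List `skewness`, `kurtosis`, `acceptable`.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("insufficient-data: n must be >= 3")
  sk <- e1071::skewness(values, type = 2)
  ku <- if (length(values) >= 4) e1071::kurtosis(values, type = 2) else NA_real_
  ok <- abs(sk) <= 1 && (is.na(ku) || abs(ku) <= 1)
  list(skewness = sk, kurtosis = ku, acceptable = ok)
}

# Residual sum of squares of a least-squares fit of y on design X.
rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# F ratio with degenerate cases resolved: a zero effect sum of squares
# gives F = 0 even when the error term is also zero (no effect, no
# evidence), and a positive effect with zero error gives Inf.
safe_f <- function(ss_eff, ss_err, df2) {
  tol <- 1e-12 * max(ss_err, ss_eff, 1)
  if (ss_eff <= tol) return(0)
  if (ss_err <= tol) return(Inf)
  (ss_eff / 1) / (ss_err / df2)
}

#' Mixed-design 2 x 2 ANOVA with a continuous covariate
#'
#' Two-level within-subject factor (e.g. habituation: S1 vs SPrecDev, or
#' change detection: SPrecDev vs Dev), two-level between-subject group
#' factor and a mean-centred continuous covariate, decomposed with Type
#' III sums of squares through the exact general-linear-model split for
#' a 2-level within factor: between-subject effects (group, covariate)
#' are tested on the subject means `(a + b)/2`, within-subject effects
#' (condition, condition x group, condition x covariate) on the
#' differences `a - b`, with sum-coded group contrasts so unbalanced
#' groups are weighted equally. With a constant covariate the covariate
#' column is dropped and the classical mixed-design ANOVA is recovered
#' exactly. Rows with missing values are excluded listwise.
#'
#' @param table data.frame of one row per subject.
#' @param dv_a,dv_b Column names of the within-condition values (e.g.
#'   S1 and SPrecDev amplitude).
#' @param group Column name of the two-level group factor.
#' @param covariate Column name of the covariate (NULL for none).
#' @return List with `anova` (data.frame `effect`, `F`, `df1`, `df2`,
#'   `p`, `peta2`), `pairwise` (data.frame `contrast`, `estimate`,
#'   `p_adj` -- Bonferroni x2 within each contrast set), and `n` used.
#' @export
mixed_anova_covariate <- function(table, dv_a, dv_b, group = "group",
                                  covariate = "age") {
  cols <- c(dv_a, dv_b, group, covariate)
  keep <- stats::complete.cases(table[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) message(n_dropped, " subject(s) excluded listwise")
  tab <- table[keep, , drop = FALSE]
  gf <- factor(tab[[group]])
  if (nlevels(gf) != 2L) stop("group must have exactly 2 levels")
  if (any(tabulate(gf) < 2L)) stop("fatal: a group has fewer than 2 subjects")

  a <- tab[[dv_a]]
  b <- tab[[dv_b]]
  m <- (a + b) / 2
  d <- a - b
  n <- length(a)
  gsum <- ifelse(gf == levels(gf)[1], 1, -1)   # sum coding
  x <- if (!is.null(covariate)) {
    xc <- tab[[covariate]] - mean(tab[[covariate]])
    if (stats::sd(xc) > 0) xc else NULL
  } else NULL

  one <- rep(1, n)
  Xfull <- if (is.null(x)) cbind(one, gsum) else cbind(one, x, gsum)
  p_full <- ncol(Xfull)
  type3 <- function(y, drop_col) {
    ss_err <- rss(Xfull, y)
    ss_eff <- max(rss(Xfull[, -drop_col, drop = FALSE], y) - ss_err, 0)
    df2 <- n - p_full
    Fv <- safe_f(ss_eff, ss_err, df2)
    data.frame(F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               peta2 = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0)
  }
  gcol <- p_full
  rows <- list()
  rows$within <- cbind(effect = "within", type3(d, 1))
  rows$wg <- cbind(effect = "within:group", type3(d, gcol))
  if (!is.null(x)) rows$wa <- cbind(effect = "within:age", type3(d, 2))
  rows$group <- cbind(effect = "group", type3(m, gcol))
  if (!is.null(x)) rows$age <- cbind(effect = "age", type3(m, 2))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  # Pairwise Bonferroni contrasts: group difference at each condition
  # level (x2), and condition difference within each group (x2).
  adj_contrast <- function(y, label) {
    fit <- stats::lm(y ~ Xfull - 1)
    sm <- suppressWarnings(summary(fit))$coefficients
    est <- 2 * sm[gcol, 1]          # level1 - level2 under sum coding
    data.frame(contrast = label, estimate = est,
               p_adj = min(1, 2 * sm[gcol, 4]), stringsAsFactors = FALSE)
  }
  within_group <- function(lv) {
    idx <- gf == lv
    dg <- d[idx]
    Xg <- if (is.null(x)) matrix(1, sum(idx)) else cbind(1, x[idx])
    fit <- stats::lm(dg ~ Xg - 1)
    sm <- suppressWarnings(summary(fit))$coefficients
    data.frame(contrast = paste0("within@", lv), estimate = sm[1, 1],
               p_adj = min(1, 2 * sm[1, 4]), stringsAsFactors = FALSE)
  }
  pairwise <- rbind(
    adj_contrast(a, paste0("group@", dv_a)),
    adj_contrast(b, paste0("group@", dv_b)),
    within_group(levels(gf)[1]),
    within_group(levels(gf)[2])
  )
  list(anova = res, pairwise = pairwise, n = n)
}

#' One-way ANCOVA (two groups, one covariate)
#'
#' Group effect on a single dependent variable adjusted for a
#' mean-centred covariate, Type III sums of squares; the single
#' Bonferroni group comparison equals the unadjusted test.
#'
#' @inheritParams mixed_anova_covariate
#' @param dv Dependent-variable column name.
#' @return List `anova` (rows `group` and, when the covariate varies,
#'   `age`), `pairwise`, `n`.
#' @export
ancova_oneway <- function(table, dv, group = "group", covariate = "age") {
  cols <- c(dv, group, covariate)
  keep <- stats::complete.cases(table[, cols, drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  gf <- factor(tab[[group]])
  if (nlevels(gf) != 2L) stop("group must have exactly 2 levels")
  if (any(tabulate(gf) < 2L)) stop("fatal: a group has fewer than 2 subjects")
  y <- tab[[dv]]
  n <- length(y)
  gsum <- ifelse(gf == levels(gf)[1], 1, -1)
  x <- if (!is.null(covariate)) {
    xc <- tab[[covariate]] - mean(tab[[covariate]])
    if (stats::sd(xc) > 0) xc else NULL
  } else NULL
  Xfull <- if (is.null(x)) cbind(1, gsum) else cbind(1, x, gsum)
  gcol <- ncol(Xfull)
  ss_err <- rss(Xfull, y)
  df2 <- n - ncol(Xfull)
  t3 <- function(drop_col, label) {
    ss_eff <- max(rss(Xfull[, -drop_col, drop = FALSE], y) - ss_err, 0)
    Fv <- safe_f(ss_eff, ss_err, df2)
    data.frame(effect = label, F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               peta2 = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0)
  }
  res <- t3(gcol, "group")
  if (!is.null(x)) res <- rbind(res, t3(2, "age"))
  fit <- stats::lm(y ~ Xfull - 1)
  sm <- suppressWarnings(summary(fit))$coefficients
  pairwise <- data.frame(
    contrast = paste(levels(gf), collapse = " - "),
    estimate = 2 * sm[gcol, 1], p_adj = sm[gcol, 4],
    stringsAsFactors = FALSE
  )
  list(anova = res, pairwise = pairwise, n = n)
}

#' Partial Pearson correlation
#'
#' Correlation of the residuals of `x` and `y` after linear removal of
#' the covariates from both; the p value uses the t transform with
#' `df = n - 2 - k` for k covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame of covariate columns, or
#'   NULL for a plain Pearson correlation.
#' @return List `r`, `p`, `df`, `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(1, length(x), 1)
    k <- 0L
  } else {
    Z <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    k <- ncol(Z) - 1L
  }
  ok <- stats::complete.cases(cbind(x, y, Z))
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2) stop("insufficient-data: n must exceed covariates + 2")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation: zero residual variance")
  }
  df <- n - 2L - k
  # a variable fully explained by the covariates leaves only numerical
  # dust in its residuals: the partial correlation is zero by definition
  if (stats::sd(rx) < 1e-10 * stats::sd(x) ||
      stats::sd(ry) < 1e-10 * stats::sd(y)) {
    return(list(r = 0, p = 1, df = df, n = n))
  }
  r <- stats::cor(rx, ry)
  tv <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tv), df), df = df, n = n)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: reject all `p <= p_(k*)` with
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector of rejections (empty input gives empty
#'   output).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Covariate-adjusted correlation screen with per-family FDR
#'
#' Runs a partial Pearson correlation for every configured
#' (feature, score) pair -- sex is always a covariate; age is added for
#' instruments without age-based norms -- and applies Benjamini-Hochberg
#' FDR within each named family (one family per clinical domain).
#'
#' @param table data.frame with `sex`, `age`, and all feature and score
#'   columns (typically the clinical group's joined feature table).
#' @param pairs data.frame with columns `feature`, `score`, `family`
#'   and optionally `use_age` (logical; defaults to TRUE except for the
#'   age-normed `nviq` and `adaptive` scores).
#' @param q FDR level.
#' @return data.frame `feature`, `score`, `family`, `covariates`, `r`,
#'   `p`, `n`, `fdr_flag`, sorted by family then p.
#' @export
correlation_screen <- function(table, pairs, q = 0.05) {
  stopifnot(all(c("feature", "score", "family") %in% names(pairs)))
  if (!"use_age" %in% names(pairs)) {
    pairs$use_age <- !(pairs$score %in% c("nviq", "adaptive"))
  }
  if (!all(pairs$feature %in% names(table))) {
    stop("config: unknown feature column in pairs")
  }
  if (!all(pairs$score %in% names(table))) {
    stop("config: unknown score column in pairs")
  }
  sex_num <- as.numeric(factor(table$sex))
  out <- lapply(seq_len(nrow(pairs)), function(j) {
    covs <- if (pairs$use_age[j]) {
      data.frame(sex = sex_num, age = table$age)
    } else {
      data.frame(sex = sex_num)
    }
    pp <- tryCatch(
      partial_pearson(table[[pairs$feature[j]]],
                      table[[pairs$score[j]]], covs),
      error = function(e) list(r = NA_real_, p = NA_real_,
                               n = nrow(table))
    )
    data.frame(
      feature = pairs$feature[j], score = pairs$score[j],
      family = pairs$family[j],
      covariates = if (pairs$use_age[j]) "sex,age" else "sex",
      r = pp$r, p = pp$p, n = pp$n, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res$fdr_flag <- FALSE
  for (fam in unique(res$family)) {
    idx <- which(res$family == fam & !is.na(res$p))
    if (length(idx)) res$fdr_flag[idx] <- fdr_bh(res$p[idx], q)
  }
  res[order(res$family, res$p), ]
}

#' Default screen pairs over the full feature grid
#'
#' All amplitude and latency features at both regions of interest
#' crossed with the six clinical scores, one FDR family per clinical
#' domain.
#'
#' @param feature_cols Feature column names (default: full grid from
#'   [extract_features()] naming).
#' @param rois Regions of interest used to build the default grid.
#' @return data.frame `feature`, `score`, `family`.
#' @export
default_screen_pairs <- function(feature_cols = NULL,
                                 rois = c("Cz", "FCz")) {
  if (is.null(feature_cols)) {
    specs <- component_specs()
    feature_cols <- unlist(lapply(rois, function(roi) {
      cols <- c()
      for (i in seq_len(nrow(specs))) {
        cls <- if (specs$name[i] == "P3a") c("SPrecDev", "Dev") else
          c("S1", "SPrecDev", "Dev")
        cols <- c(cols, paste(roi, specs$name[i], rep(cls, each = 2),
                              c("amp", "lat"), sep = "_"))
      }
      c(cols, paste(roi, "MMN", c("amp", "lat"), sep = "_"))
    }))
  }
  scores <- c(nviq = "cognition", asd_severity = "autistic_symptoms",
              adaptive = "adaptive", social_avoidance = "social_avoidance",
              depressed_mood = "anxiety_depression", adhd = "adhd")
  expand <- expand.grid(feature = feature_cols, score = names(scores),
                        stringsAsFactors = FALSE)
  expand$family <- unname(scores[expand$score])
  expand
}
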