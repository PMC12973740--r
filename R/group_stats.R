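# Nonparametric three-group comparison layer: tie-corrected
# Kruskal-Wallis, Dunn's pairwise z tests with Bonferroni correction,
# rank eta-squared, Cohen's f, achieved power under the fixed-effects
# one-way ANOVA approximation, and the age/sex covariate regression.

check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("`samples` must be a list of >= 2 numeric vectors")
  }
  sizes <- vapply(samples, length, integer(1))
  if (any(sizes < 2L)) {
    stop("insufficient data: every group needs >= 2 observations")
  }
  invisible(sizes)
}

#' Kruskal-Wallis test across groups
#'
#' Mid-rank H with tie correction and a chi-square upper-tail p-value on
#' k - 1 degrees of freedom. A dataset in which every observation is
#' identical is defined to give H = 0 (and p = 1): the tie-correction
#' denominator vanishes there, and a constant dataset carries no group
#' effect.
#'
#' @param samples list of numeric vectors, one per group (each >= 2
#'   observations).
#' @return A list with `H`, `df`, `p` and `n` (group sizes).
#' @export
kruskal_wallis <- function(samples) {
  sizes <- check_samples(samples)
  x <- unlist(samples, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(samples) - 1L, p = 1, n = sizes))
  }
  g <- factor(rep(seq_along(samples), sizes))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = sizes)
}

#' Dunn's pairwise post-hoc tests with Bonferroni correction
#'
#' Pairwise z statistics on pooled mid-ranks with tie correction,
#' two-sided raw p-values, and Bonferroni-adjusted p = min(1, m * raw)
#' where m is the number of pairwise tests performed.
#'
#' @param samples list of numeric vectors, one per group.
#' @return A data.frame with one row per group pair: `group_i`,
#'   `group_j`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_bonferroni <- function(samples) {
  sizes <- check_samples(samples)
  k <- length(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), sizes)
  N <- length(x)
  r <- rank(x) # mid-ranks
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group_i = integer(m), group_j = integer(m),
                    z = numeric(m), p_raw = numeric(m), p_adj = numeric(m))
  for (p_i in seq_len(m)) {
    i <- pairs[1, p_i]; j <- pairs[2, p_i]
    se <- sqrt(s2 * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    out[p_i, ] <- list(i, j, unname(z), praw, min(1, m * praw))
  }
  out
}

#' Rank eta-squared from the Kruskal-Wallis statistic
#'
#' The default convention is eta2 = H / (N - 1), the rank analogue of the
#' ANOVA variance-explained ratio. An alternative small-sample-adjusted
#' convention eta2 = (H - k + 1) / (N - k) is available via `convention`;
#' the two disagree noticeably at moderate N.
#'
#' @param H Kruskal-Wallis statistic (>= 0).
#' @param n_total total number of observations (>= 3).
#' @param convention `"h_over_n_minus_1"` (default) or `"adjusted"`.
#' @param k number of groups (used only by the adjusted convention).
#' @return Rank eta-squared.
#' @export
eta_squared_from_h <- function(H, n_total,
                               convention = c("h_over_n_minus_1",
                                              "adjusted"),
                               k = 3L) {
  convention <- match.arg(convention)
  if (n_total < 3) stop("invalid parameter: n_total must be >= 3")
  if (H < 0) stop("invalid parameter: H must be >= 0")
  switch(convention,
         h_over_n_minus_1 = H / (n_total - 1),
         adjusted = (H - k + 1) / (n_total - k))
}

#' Cohen's f from eta-squared
#'
#' f = sqrt(eta2 / (1 - eta2)).
#'
#' @param eta2 variance-explained effect size in \[0, 1).
#' @return Cohen's f (>= 0).
#' @export
cohens_f <- function(eta2) {
  if (eta2 < 0 || eta2 >= 1) {
    stop("invalid parameter: eta2 must lie in [0, 1)")
  }
  sqrt(eta2 / (1 - eta2))
}

#' Achieved power under the one-way ANOVA approximation
#'
#' Fixed-effects one-way ANOVA power: noncentrality lambda = f^2 * N,
#' numerator df = k - 1, denominator df = N - k; power is the upper-tail
#' probability of the noncentral F beyond the central-F critical value at
#' `alpha`. With f = 0 this reduces to alpha.
#'
#' @param f Cohen's f (>= 0).
#' @param k number of groups (>= 2).
#' @param n_total total sample size (> k).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return Achieved power in \[alpha, 1\].
#' @export
anova_power <- function(f, k, n_total, alpha = 0.05) {
  if (f < 0) stop("invalid parameter: f must be >= 0")
  if (k < 2 || n_total <= k) {
    stop("invalid parameter: need k >= 2 groups and n_total > k")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("invalid parameter: alpha must be in (0, 1)")
  }
  df1 <- k - 1
  df2 <- n_total - k
  lambda <- f^2 * n_total
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}

#' Age/sex covariate regression for a regional metric
#'
#' Ordinary least squares of the per-patient metric on age (years) and
#' sex (indicator for male), the confounding check applied to each
#' region's fractal dimension.
#'
#' @param records a cohort table (see [make_cohort()] / [read_cohort()]).
#' @param region region whose rows are analysed (e.g. `"anterior"`).
#' @param metric column to regress (default `"fd"`).
#' @return A data.frame with rows `age` and `sex`, columns `estimate`
#'   and `p`.
#' @export
covariate_regression <- function(records, region, metric = "fd") {
  sub <- records[records$region == region, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[, c("age", "sex", metric)]), ,
             drop = FALSE]
  if (nrow(sub) < 10L) {
    stop("insufficient data: need >= 10 complete records")
  }
  sub$sex_male <- as.numeric(sub$sex == "male")
  X <- cbind(1, sub$age, sub$sex_male)
  if (qr(X)$rank < 3L) {
    stop("collinearity error: rank-deficient age/sex design")
  }
  fit <- stats::lm(stats::reformulate(c("age", "sex_male"), metric),
                   data = sub)
  sm <- summary(fit)$coefficients
  data.frame(term = c("age", "sex"),
             estimate = sm[c("age", "sex_male"), "Estimate"],
             p = sm[c("age", "sex_male"), "Pr(>|t|)"],
             row.names = NULL)
}

#' Three-group comparison of every radiographic variable
#'
#' The machine-readable analogue of the study's summary tables: for each
#' variable (fractal dimension and lacunarity in the anterior, premolar
#' and molar regions; MCW and PMI on the right and left sides) it reports
#' per-group sizes, medians and ranges, the tie-corrected Kruskal-Wallis
#' H and p, Dunn-Bonferroni pairwise adjusted p-values, rank eta-squared,
#' Cohen's f and achieved power.
#'
#' @param records a cohort table with columns `group`, `region`, `fd`,
#'   `lacunarity`, `mcw`, `pmi`.
#' @param alpha significance level for the power computation.
#' @return A data.frame with one row per variable (10 for the full
#'   layout), of class `group_comparison`.
#' @export
compare_all <- function(records, alpha = 0.05) {
  grp <- factor(records$group, levels = cohort_groups)
  if (anyNA(grp)) {
    bad <- unique(records$group[is.na(grp)])
    stop("unknown group label: ", paste(bad, collapse = ", "))
  }
  layout <- rbind(
    expand.grid(variable = c("fd", "lacunarity"),
                where = cohort_regions, stringsAsFactors = FALSE),
    expand.grid(variable = c("mcw", "pmi"),
                where = cohort_sides, stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    v <- layout$variable[i]; wh <- layout$where[i]
    sub <- records[records$region == wh & !is.na(records[[v]]), ,
                   drop = FALSE]
    if (nrow(sub) == 0L) next
    samples <- split(sub[[v]], factor(sub$group, levels = cohort_groups))
    kw <- kruskal_wallis(samples)
    dn <- dunn_bonferroni(samples)
    N <- sum(kw$n)
    eta2 <- eta_squared_from_h(kw$H, N)
    f <- cohens_f(eta2)
    med <- vapply(samples, stats::median, numeric(1))
    mn <- vapply(samples, min, numeric(1))
    mx <- vapply(samples, max, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, region_or_side = wh,
      n_normal = kw$n[1], n_borderline = kw$n[2], n_high = kw$n[3],
      median_normal = med[1], min_normal = mn[1], max_normal = mx[1],
      median_borderline = med[2], min_borderline = mn[2],
      max_borderline = mx[2],
      median_high = med[3], min_high = mn[3], max_high = mx[3],
      H = kw$H, df = kw$df, p = kw$p,
      p_adj_normal_borderline = dn$p_adj[dn$group_i == 1 & dn$group_j == 2],
      p_adj_normal_high = dn$p_adj[dn$group_i == 1 & dn$group_j == 3],
      p_adj_borderline_high = dn$p_adj[dn$group_i == 2 & dn$group_j == 3],
      eta2 = eta2, cohens_f = f,
      power = anova_power(f, 3, N, alpha), alpha = alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}
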