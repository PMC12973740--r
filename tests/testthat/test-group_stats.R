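test_that("Kruskal-Wallis matches the rank-sum closed form and edge rules", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2) # 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1), no ties
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))$H, 0)
  expect_error(kruskal_wallis(list(1, c(2, 3), c(4, 5))),
               "insufficient data")
  # heavy ties keep H finite and p in (0, 1]
  kwt <- kruskal_wallis(list(c(1, 1, 2, 2), c(1, 2, 2, 3), c(2, 2, 3, 3)))
  expect_true(is.finite(kwt$H))
  expect_gt(kwt$p, 0); expect_lte(kwt$p, 1)
})

test_that("chi-square p agrees with a permutation oracle on small samples", {
  g <- rep(1:3, each = 5)
  cases <- list(
    list(seed = 42, shifts = c(0, 0.8, 1.2)),
    list(seed = 314, shifts = c(0, 0.3, 0.5))
  )
  for (cs in cases) {
    set.seed(cs$seed)
    x <- lapply(cs$shifts, function(m) rnorm(5, m))
    kw <- kruskal_wallis(x)
    v <- unlist(x)
    set.seed(cs$seed + 1)
    perm <- replicate(2000, kruskal_wallis(split(sample(v), g))$H)
    p_perm <- mean(perm >= kw$H - 1e-12)
    # chi-square approximation error dominates Monte-Carlo error at N=15
    expect_lt(abs(kw$p - p_perm), 0.03)
  }
})

test_that("Dunn z statistics separate the extreme pair and Bonferroni bounds hold", {
  d <- dunn_bonferroni(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(nrow(d), 3)
  imax <- which.max(abs(d$z))
  expect_equal(c(d$group_i[imax], d$group_j[imax]), c(1, 3))
  expect_true(all(d$p_adj >= d$p_raw))
  expect_true(all(d$p_adj <= pmin(1, 3 * d$p_raw) + 1e-12))
  same <- dunn_bonferroni(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_true(all(same$p_adj == 1))
})

test_that("type-I error and family-wise error stay at nominal level under the null", {
  set.seed(77)
  n <- c(10, 10, 10)
  reps <- 2000
  kw_rej <- logical(reps); fwer_rej <- logical(reps)
  for (i in seq_len(reps)) {
    samples <- lapply(n, function(m) rnorm(m))
    kw_rej[i] <- kruskal_wallis(samples)$p < 0.05
    fwer_rej[i] <- any(dunn_bonferroni(samples)$p_adj < 0.05)
  }
  mc <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(kw_rej) - 0.05), mc + 0.005)
  expect_lt(mean(fwer_rej), 0.05 + mc)
})

test_that("the effect-size chain reproduces the published sensitivity analysis", {
  eta2 <- eta_squared_from_h(6.104, 92)
  expect_equal(round(eta2, 3), 0.067)
  expect_equal(round(eta2, 4), 0.0671)
  f <- cohens_f(eta2)
  expect_equal(round(f, 2), 0.27)
  expect_equal(f, 0.268, tolerance = 1e-3)
  expect_equal(round(anova_power(0.27, 3, 92, 0.05), 2), 0.62)
  # both rounding paths land on the same two decimals
  expect_equal(round(anova_power(f, 3, 92, 0.05), 2), 0.61,
               tolerance = 0.011)
})

test_that("effect-size helpers respect their edge cases and conventions", {
  expect_equal(eta_squared_from_h(0, 50), 0)
  expect_equal(eta_squared_from_h(91, 92), 1) # H = N - 1 upper edge
  expect_equal(eta_squared_from_h(6.104, 92, convention = "adjusted"),
               (6.104 - 2) / 89)
  expect_error(eta_squared_from_h(6, 2), "n_total")
  expect_equal(cohens_f(0), 0)
  expect_equal(cohens_f(0.5), 1)
  expect_error(cohens_f(1), "eta2")
  expect_equal(anova_power(0, 3, 92, 0.05), 0.05, tolerance = 1e-9)
  # power strictly increasing in N at fixed f
  pw <- vapply(c(30, 60, 92, 150), function(N) anova_power(0.27, 3, N),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(anova_power(0.27, 3, 3), "n_total")
})

test_that("covariate regression recovers a planted age effect and null calibration", {
  # null: fd independent of age/sex
  set.seed(55)
  reps <- 500
  null_rej <- vapply(seq_len(reps), function(i) {
    co <- data.frame(region = "anterior", age = runif(92, 20, 90),
                     sex = sample(c("male", "female"), 92, TRUE),
                     fd = rnorm(92, 1.45, 0.1))
    covariate_regression(co, "anterior")$p[1] < 0.05
  }, logical(1))
  expect_lt(abs(mean(null_rej) - 0.05), 0.03)
  # planted slope 0.002/year recovered within its CI most of the time
  hits <- vapply(seq_len(200), function(i) {
    age <- runif(92, 20, 90)
    co <- data.frame(region = "anterior", age = age,
                     sex = sample(c("male", "female"), 92, TRUE),
                     fd = 1.3 + 0.002 * age + rnorm(92, 0, 0.05))
    est <- covariate_regression(co, "anterior")
    se <- abs(est$estimate[1]) / abs(qnorm(est$p[1] / 2))
    abs(est$estimate[1] - 0.002) < 1.96 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # sex coding direction flips the sign but not the p-value
  set.seed(9)
  co <- data.frame(region = "anterior", age = runif(40, 20, 90),
                   sex = rep(c("male", "female"), 20),
                   fd = rnorm(40, 1.45, 0.1))
  a <- covariate_regression(co, "anterior")
  co$sex <- ifelse(co$sex == "male", "female", "male")
  b <- covariate_regression(co, "anterior")
  expect_equal(a$estimate[2], -b$estimate[2])
  expect_equal(a$p[2], b$p[2])
  expect_error(covariate_regression(co[1:5, ], "anterior"),
               "insufficient")
})

test_that("compare_all emits the ten-variable table with coherent columns", {
  co <- make_cohort(cohort_params(seed = 12))
  cmp <- compare_all(co)
  expect_equal(nrow(cmp), 10)
  expect_setequal(cmp$variable[cmp$region_or_side == "anterior"],
                  c("fd", "lacunarity"))
  expect_setequal(cmp$region_or_side[cmp$variable == "mcw"],
                  c("right", "left"))
  expect_equal(cmp$n_normal + cmp$n_borderline + cmp$n_high, rep(92, 10))
  expect_true(all(cmp$eta2 >= 0 & cmp$eta2 < 1))
  expect_true(all(cmp$cohens_f >= 0))
  expect_true(all(cmp$power >= 0.05 - 1e-9 & cmp$power <= 1))
  expect_equal(cmp$eta2, cmp$H / 91, tolerance = 1e-12)
  bad <- co; bad$group[1] <- "elevated"
  expect_error(compare_all(bad), "elevated")
})

test_that("zero-shift cohorts show no excess significance", {
  eq <- matrix(1.45, 3, 3,
               dimnames = list(c("anterior", "premolar", "molar"), NULL))
  hits <- vapply(1:200, function(s) {
    co <- make_cohort(cohort_params(fd_medians = eq, seed = 3000 + s))
    anterior_fd_pvalue(co) < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200) + 0.01)
})
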