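toy_table <- function(play, rest, band = "beta", metric = "e_loc",
                      T = 0.35) {
  n <- length(play)
  data.frame(subject_id = rep(sprintf("S%02d", 1:n), 2),
             condition = rep(c("play", "rest"), each = n),
             band = band, threshold_T = T, metric = metric,
             value = c(play, rest), stringsAsFactors = FALSE)
}

test_that("paired t statistic matches the closed form on toy pairs", {
  tab <- toy_table(c(2, 3, 5), c(1, 2, 3))
  res <- paired_test_per_threshold(tab, "e_loc", "beta")
  # differences (1, 1, 2): t = (4/3) / (sd/sqrt(3)) = 4 exactly
  expect_equal(res$statistic, 4, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_play, 10 / 3)
  expect_equal(res$mean_rest, 2)
  expect_true(res$ci_low <= 4 / 3 && 4 / 3 <= res$ci_high)
})

test_that("identical paired values give a null result", {
  tab <- toy_table(c(0.4, 0.5, 0.6, 0.7), c(0.4, 0.5, 0.6, 0.7))
  res <- paired_test_per_threshold(tab, "e_loc", "beta")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a constant shift dominates tiny jitter", {
  set.seed(3)
  n <- 19
  rest <- runif(n, 0.3, 0.5)
  play <- rest + 0.1 + rnorm(n, sd = 1e-4)
  res <- paired_test_per_threshold(toy_table(play, rest), "e_loc", "beta")
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.01)
})

test_that("paired test is invariant to a common per-subject offset", {
  set.seed(4)
  n <- 12
  play <- runif(n); rest <- runif(n)
  shift <- runif(n, -5, 5)
  r1 <- paired_test_per_threshold(toy_table(play, rest), "e_loc", "beta")
  r2 <- paired_test_per_threshold(toy_table(play + shift, rest + shift),
                                  "e_loc", "beta")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("paired tests demand at least 3 complete pairs", {
  expect_error(paired_test_per_threshold(toy_table(c(1, 2), c(0, 1)),
                                         "e_loc", "beta"), "3 subjects")
  broken <- toy_table(c(1, 2, 3), c(0, 1, 2))
  broken <- broken[-4, ]
  expect_error(paired_test_per_threshold(broken, "e_loc", "beta"))
})

anova_table <- function(values, n_sub) {
  expand.grid(subject_id = sprintf("S%02d", 1:n_sub),
              condition = c("play", "rest"),
              band = c("delta", "theta", "alpha", "beta"),
              stringsAsFactors = FALSE) |>
    transform(threshold_T = 0.35, metric = "e_loc", value = values)
}

test_that("two-way ANOVA matches hand-computed sums of squares", {
  # 2 conditions x 2 bands x 2 replicates, worked by hand
  d <- data.frame(
    subject_id = rep(c("S1", "S2"), 4),
    condition = rep(c("play", "rest"), each = 4),
    band = rep(rep(c("alpha", "beta"), each = 2), 2),
    threshold_T = 0.35, metric = "e_loc",
    value = c(3, 5, 6, 8, 2, 4, 3, 5))
  res <- two_way_anova(d, "e_loc")
  # cell means: 4, 7, 3, 4; grand 4.5
  # SS_cond = 4*(5.5-4.5)^2*... classical decomposition:
  ssa <- 8 * ((5.5 - 4.5)^2 + (3.5 - 4.5)^2) / 2
  ssb <- 8 * ((3.5 - 4.5)^2 + (5.5 - 4.5)^2) / 2
  cellm <- c(4, 7, 3, 4)
  ssab <- 2 * sum((cellm - c(5.5 + 3.5 - 4.5, 5.5 + 5.5 - 4.5,
                             3.5 + 3.5 - 4.5, 3.5 + 5.5 - 4.5))^2)
  sse <- sum((c(3, 5, 6, 8, 2, 4, 3, 5) - rep(cellm, each = 2))^2)
  f_cond <- (ssa / 1) / (sse / 4)
  f_band <- (ssb / 1) / (sse / 4)
  f_int <- (ssab / 1) / (sse / 4)
  expect_equal(res$statistic[res$term == "condition"], f_cond)
  expect_equal(res$statistic[res$term == "band"], f_band)
  expect_equal(res$statistic[res$term == "condition:band"], f_int)
})

test_that("ANOVA sums of squares are additive", {
  set.seed(6)
  vals <- rnorm(2 * 4 * 10, mean = 0.5, sd = 0.1)
  d <- anova_table(vals, 10)
  fit <- stats::aov(value ~ condition * band, data = d)
  sm <- summary(fit)[[1]]
  ss <- sm$`Sum Sq`
  total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(ss), total, tolerance = 1e-9)
})

test_that("a planted condition effect dwarfs an absent band effect", {
  set.seed(7)
  n <- 19
  base <- rnorm(8 * n, 0.5, 0.05)
  d <- anova_table(base, n)
  d$value[d$condition == "play"] <- d$value[d$condition == "play"] + 0.08
  res <- two_way_anova(d, "e_loc")
  f <- setNames(res$statistic, res$term)
  expect_gt(f["condition"], 10 * f["band"])
  expect_lt(res$p_value[res$term == "condition"], 0.001)
})

test_that("ANOVA validates its layout", {
  set.seed(8)
  d <- anova_table(rnorm(8 * 4), 4)
  expect_error(two_way_anova(d[-1, ], "e_loc"), "balanced")
  d1 <- anova_table(rnorm(8), 1)
  expect_error(two_way_anova(d1, "e_loc"), "2 replicates")
  dc <- anova_table(rep(1, 8 * 4), 4)
  expect_error(two_way_anova(dc, "e_loc"), "variance")
  expect_error(two_way_anova(d, "nope"), "no rows")
})

test_that("headline report flags the planted band and is deterministic", {
  set.seed(9)
  n <- 12
  tabs <- list()
  for (b in c("delta", "theta", "alpha", "beta")) {
    rest <- runif(n, 0.4, 0.5)
    shift <- if (b == "beta") 0.15 else 0.005
    tabs[[b]] <- toy_table(rest + shift + rnorm(n, sd = 0.01), rest,
                           band = b)
  }
  tab <- do.call(rbind, tabs)
  h1 <- headline_report(tab)
  h2 <- headline_report(tab)
  expect_identical(h1, h2)
  expect_identical(unname(h1$max_contrast_band["e_loc"]), "beta")
  beta_row <- subset(h1$contrasts, band == "beta" & metric == "e_loc")
  expect_true(beta_row$significant)
})
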