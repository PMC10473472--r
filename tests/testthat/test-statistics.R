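test_that("r-squared is exact on perfect lines and invariant to affine maps", {
  x <- 1:20
  r <- pearson_r2(x, 2 * x)
  expect_equal(r$r2, 1)
  expect_equal(r$stars, "***")
  set.seed(5)
  y <- x + rnorm(20)
  a <- pearson_r2(x, y)
  b <- pearson_r2(3 * x - 7, y)        # affine map of x
  d <- pearson_r2(x, -0.5 * y + 2)     # affine map of y
  expect_equal(a$r2, b$r2)
  expect_equal(a$r2, d$r2)
  expect_error(pearson_r2(rep(1, 10), y[1:10]), "constant")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
  # independent draws decorrelate: r2 below 0.01 at n = 10^4
  set.seed(6)
  expect_lt(pearson_r2(rnorm(1e4), rnorm(1e4))$r2, 0.01)
})

test_that("significance stars follow the p-value convention", {
  p_stars <- mangolenticel:::p_stars
  expect_equal(p_stars(0.0001), "***")
  expect_equal(p_stars(0.005), "**")
  expect_equal(p_stars(0.03), "*")
  expect_equal(p_stars(0.2), "ns")
})

test_that("ordinary least squares recovers an exact line and scales its SE with noise", {
  x <- seq(10, 200, by = 10)
  fit <- suppressWarnings(linear_fit(x, 1.18 * x + 0.93))
  expect_equal(fit$slope, 1.18)
  expect_equal(fit$intercept, 0.93)
  expect_equal(fit$r2, 1)
  # same residual shape at twice the amplitude doubles the slope SE exactly
  set.seed(8)
  e <- rnorm(length(x))
  f1 <- linear_fit(x, x + 2 * e)
  f2 <- linear_fit(x, x + 4 * e)
  expect_equal(f2$slope_se, 2 * f1$slope_se)
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("well-separated groups get distinct Tukey letters, identical groups share one", {
  set.seed(12)
  g <- rep(c("lo", "mid", "hi"), each = 10)
  v <- rnorm(30, rep(c(0, 10, 20), each = 10), 0.1)
  out <- anova_tukey_letters(v, g)
  expect_equal(out$group, c("lo", "mid", "hi"))  # ascending mean order
  expect_equal(out$letters, c("a", "b", "c"))
  # all groups drawn identically: a single shared letter
  set.seed(13)
  v2 <- rnorm(30, 5, 1)
  out2 <- anova_tukey_letters(v2, g)
  expect_true(all(grepl("a", out2$letters)))
  expect_equal(length(unique(unlist(strsplit(out2$letters, "")))), 1L)
  # two coincident groups plus one distant: the pair shares a letter
  set.seed(14)
  v3 <- c(rnorm(10, 0, 0.5), rnorm(10, 0, 0.5), rnorm(10, 30, 0.5))
  out3 <- anova_tukey_letters(v3, g)
  lo <- out3$letters[out3$group %in% c("lo", "mid")]
  expect_equal(lo[1], lo[2])
  expect_false(out3$letters[out3$group == "hi"] %in% lo)
})

test_that("compact letters agree with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(19)
  # group-mean patterns with clear separation structure (differences are
  # either 0 or many residual SDs), so both adjustments make the same
  # pairwise calls and the comparison isolates the letter partition
  patterns <- list(c(0, 0, 8, 8), c(0, 8, 8, 16), c(0, 8, 16, 24),
                   c(0, 0, 0, 8), c(0, 8, 0, 8))
  for (rep_i in seq_along(patterns)) {
    g <- factor(rep(paste0("g", 1:4), each = 8))
    mu <- patterns[[rep_i]]
    v <- rnorm(32, rep(mu, each = 8), 1)
    ours <- anova_tukey_letters(v, g)
    fit <- stats::aov(v ~ g)
    cl <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))
    ref <- cl$mcletters$Letters
    # same partition: two groups share a letter in ours iff they do in ref
    share <- function(lets, a, b)
      length(intersect(strsplit(lets[a], "")[[1]],
                       strsplit(lets[b], "")[[1]])) > 0
    ours_l <- setNames(ours$letters, ours$group)
    for (a in levels(g)) for (b in levels(g)) if (a < b)
      expect_equal(share(ours_l, a, b), share(ref, a, b),
                   info = paste("pair", a, b, "rep", rep_i))
  }
})

test_that("adding replicates of a group never splits letters it already shares", {
  set.seed(23)
  g <- rep(c("a1", "a2", "b1"), each = 6)
  v <- rnorm(18, rep(c(0, 0.3, 5), each = 6), 1)
  base <- anova_tukey_letters(v, g)
  shared_before <- intersect(
    strsplit(base$letters[base$group == "a1"], "")[[1]],
    strsplit(base$letters[base$group == "a2"], "")[[1]])
  # duplicate the existing b1 data: evidence about a1 vs a2 cannot shrink
  g2 <- c(g, rep("b1", 6)); v2 <- c(v, v[g == "b1"])
  more <- anova_tukey_letters(v2, g2)
  shared_after <- intersect(
    strsplit(more$letters[more$group == "a1"], "")[[1]],
    strsplit(more$letters[more$group == "a2"], "")[[1]])
  expect_true(length(shared_before) > 0)
  expect_true(length(shared_after) > 0)
})

test_that("degenerate within-group variance collapses to a shared letter with warning", {
  g <- rep(c("x", "y"), each = 3)
  v <- rep(2, 6)
  expect_warning(out <- anova_tukey_letters(v, g), "degenerate")
  expect_equal(out$letters, c("a", "a"))
  expect_error(anova_tukey_letters(1:5, rep("x", 5)), "2 groups")
  expect_error(anova_tukey_letters(1:3, c("x", "x", "y")), "2 values")
})

test_that("paired summaries difference treatment against control within fruit", {
  d <- data.frame(
    pair = rep(1:6, 2),
    treatment = rep(c(TRUE, FALSE), each = 6),
    value = c(5:10, 5:10))
  out <- paired_effect(d)
  expect_equal(out$mean_paired_diff, 0)
  expect_equal(out$mean_treatment, out$mean_control)
  # constructed positive effect (exposed halos twice as large)
  d2 <- d; d2$value[d2$treatment] <- 2 * d2$value[d2$treatment]
  out2 <- paired_effect(d2)
  expect_gt(out2$mean_paired_diff, 0)
  expect_equal(out2$mean_paired_diff, mean(5:10))
  # order invariance
  set.seed(31)
  perm <- d2[sample(nrow(d2)), ]
  expect_equal(paired_effect(perm), out2)
  # per-time summaries keep pairs within time point
  d3 <- rbind(cbind(d2, time = 58), cbind(d, time = 100))
  out3 <- paired_effect(d3)
  expect_equal(out3$time, c(58, 100))
  expect_equal(out3$mean_paired_diff, c(mean(5:10), 0))
  # unpaired record is reported by pair id
  d4 <- d[-1, ]
  expect_error(paired_effect(d4), "pair 1")
})
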