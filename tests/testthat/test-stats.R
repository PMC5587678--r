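# Statistics layer: odds ratios, binomial tail, partner summaries,
# rank-based tests, FDR.

test_that("closed-form logistic OR equals the cross-product ratio", {
  set.seed(19)
  for (i in 1:50) {
    cts <- sample(1:500, 4, replace = TRUE)
    fit <- logistic_or(contingency_table(cts[1], cts[2], cts[3], cts[4]))
    expect_equal(fit$or, (cts[1] * cts[4]) / (cts[2] * cts[3]),
                 tolerance = 1e-6)
  }
})

test_that("closed-form and iterative logistic fits agree", {
  tab <- contingency_table(20, 15, 9, 31)
  cf <- logistic_or(tab)
  it <- logistic_or(tab, method = "glm")
  expect_equal(cf$beta1, it$beta1, tolerance = 1e-6)
  expect_equal(cf$beta0, it$beta0, tolerance = 1e-6)
})

test_that("symmetric tables give OR = 1 and beta1 = 0", {
  fit <- logistic_or(contingency_table(7, 7, 7, 7))
  expect_equal(fit$or, 1)
  expect_equal(fit$beta1, 0)
  expect_equal(fit$p_value, 1)
})

test_that("zero cells error unless the Haldane correction is requested", {
  expect_error(logistic_or(contingency_table(0, 5, 5, 5)), "haldane")
  fit <- logistic_or(contingency_table(0, 5, 5, 5), haldane = TRUE)
  expect_equal(fit$or, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("binomial frequency test is the exact upper tail", {
  expect_equal(binomial_frequency_test(0, 10), 1)
  expect_equal(binomial_frequency_test(8, 8, p0 = 0.25), 0.25^8)
  # direct pmf summation as an independent check (the reported-sample case)
  s <- 13; n <- 21; p0 <- 0.25
  direct <- sum(choose(n, s:n) * p0^(s:n) * (1 - p0)^(n - (s:n)))
  expect_equal(binomial_frequency_test(s, n, p0), direct, tolerance = 1e-12)
  # upper + lower tails partition exactly
  expect_equal(binomial_frequency_test(s, n, p0) + pbinom(s - 1, n, p0), 1)
  expect_error(binomial_frequency_test(5, 3), "invalid")
})

test_that("partner summaries exclude the target and honour the mode", {
  vals <- c(g4 = -1, g5 = 3)
  expect_equal(partner_summary(vals, "max"), 3)
  expect_equal(partner_summary(c(g4 = 2, g5 = 4), "mean"), 3)
  expect_equal(partner_summary(vals, "sum"), 2)
  one <- c(gX = 1.5)
  for (md in c("max", "mean", "sum")) {
    expect_equal(partner_summary(one, md), 1.5)
  }
  expect_error(partner_summary(c(gT = 1), target_gene = "gT"), "no partner")
})

test_that("sensitivity records join scores with partner expression", {
  prof <- expr_profile(tibble::tibble(
    gene = c("gT", "g4", "g5"),
    cl1 = c(9, -1, 3), cl2 = c(8, 6, 0)))
  scores <- tibble::tibble(unit = c("cl1", "cl2"), score = c(-2, 0.5))
  rec <- sensitivity_records(scores, prof, c("gT", "g4", "g5"), "gT")
  expect_equal(rec$partner_expr, c(3, 6))
  expect_equal(rec$any_partner_expressed, c(FALSE, TRUE))
  expect_error(sensitivity_records(scores, prof, c("gT", "gZ"), "gT"),
               "absent")
})

test_that("spearman matches a rank-formula recomputation", {
  expect_equal(spearman_sensitivity(tibble::tibble(
    score = 1:5, partner_expr = c(2, 4, 6, 8, 10),
    any_partner_expressed = TRUE))$rho, 1)
  expect_equal(spearman_sensitivity(tibble::tibble(
    score = 1:5, partner_expr = 5:1,
    any_partner_expressed = TRUE))$rho, -1)
  set.seed(29)
  x <- sort(rnorm(30)); y <- x + rnorm(30, sd = 0.5)
  rec <- tibble::tibble(score = y, partner_expr = x,
                        any_partner_expressed = TRUE)
  got <- spearman_sensitivity(rec)
  # independent recomputation: Pearson correlation of average ranks
  rho_ranks <- stats::cor(rank(x), rank(y))
  expect_equal(got$rho, rho_ranks, tolerance = 1e-12)
  expect_lt(got$p_one_tailed, 0.01)
  expect_error(spearman_sensitivity(tibble::tibble(
    score = c(1, 1, 1), partner_expr = 1:3,
    any_partner_expressed = TRUE)), "constant")
})

test_that("mann-whitney handles separation, ties and identical groups", {
  mk <- function(a, b) tibble::tibble(
    score = c(a, b),
    partner_expr = 0,
    any_partner_expressed = c(rep(TRUE, length(a)), rep(FALSE, length(b))))
  # complete separation, 5 vs 5, exact: p = 1 / choose(10, 5)
  sep <- mannwhitney_groups(mk(6:10, 1:5))
  expect_equal(sep$p_one_tailed, 1 / choose(10, 5))
  # identical groups: no evidence of a shift
  same <- mannwhitney_groups(mk(c(1, 3, 5), c(1, 3, 5)))
  expect_gte(same$p_one_tailed, 0.5)
  # fully tied data: p = 0.5 by convention
  expect_equal(mannwhitney_groups(mk(rep(2, 4), rep(2, 4)))$p_one_tailed,
               0.5)
  expect_error(mannwhitney_groups(mk(numeric(0), 1:3)), "empty")
})

test_that("exact and approximate mann-whitney agree for small groups", {
  set.seed(37)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    exact <- suppressWarnings(stats::wilcox.test(a, b,
      alternative = "greater", exact = TRUE)$p.value)
    approx <- suppressWarnings(stats::wilcox.test(a, b,
      alternative = "greater", exact = FALSE, correct = TRUE)$p.value)
    expect_equal(exact, approx, tolerance = 0.06)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  # permutation invariance up to reordering
  p <- c(0.002, 0.9, 0.04, 0.3, 0.011)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  # monotone in the sorted order
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("tidy and glance methods return well-formed tibbles", {
  fit <- logistic_or(contingency_table(167, 141, 111, 340))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(glance(fit)$n, 759)
  res <- enumerate_gmcs(make_fixture("complex_demo"), genes_L = "gB",
                        target_gene = "gA")
  expect_equal(tidy(res)$genes, "gA")
  expect_true(glance(res)$all_verified)
})
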