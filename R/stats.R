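#' 2x2 contingency table of essentiality predictions
#'
#' Cross-classifies predicted essentiality (rows of the underlying logistic
#' covariate) against reference essentiality: `a` = predicted essential and
#' reference essential, `b` = predicted non-essential among reference
#' essential, `c` = predicted essential among reference non-essential,
#' `d` = predicted non-essential and reference non-essential.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list of class `contingency_2x2`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty contingency table", call. = FALSE)
  structure(as.list(counts), class = "contingency_2x2")
}

#' Odds ratio of a 2x2 table via single-covariate logistic regression
#'
#' Fits the logistic model `logit P(reference essential | x) = b0 + b1 x`
#' with the binary predictor x = 1 when the method predicts the gene
#' essential. For a saturated 2x2 table the maximum-likelihood estimate has
#' the closed form `OR = exp(b1) = (a d) / (b c)`, which is what the
#' default method computes (analytically exact); `method = "glm"` runs the
#' iterative fit and exists for API symmetry. The p-value is the two-sided
#' Wald test on `b1` (`method = "glm"` additionally offers a likelihood-
#' ratio p through `lr = TRUE`).
#'
#' @param table a [contingency_table()], or a length-4 vector `(a, b, c,
#'   d)`.
#' @param haldane add 0.5 to every cell (continuity correction) instead of
#'   erroring on a zero cell.
#' @param method `"closed_form"` (default) or `"glm"`.
#' @param lr with `method = "glm"`, also report the likelihood-ratio
#'   p-value.
#' @return list of class `gmcs_or` with `beta0`, `beta1`, `or`, `se`,
#'   `p_value` (and `p_lr` if requested), plus the table.
#' @export
#' @examples
#' logistic_or(contingency_table(167, 141, 111, 340))$or
logistic_or <- function(table, haldane = FALSE,
                        method = c("closed_form", "glm"), lr = FALSE) {
  method <- match.arg(method)
  if (!inherits(table, "contingency_2x2")) {
    stopifnot(length(table) == 4)
    table <- contingency_table(table[1], table[2], table[3], table[4])
  }
  cts <- c(table$a, table$b, table$c, table$d)
  if (any(cts == 0)) {
    if (!haldane) {
      stop("zero cell makes the odds ratio undefined; set haldane = TRUE ",
           "to add 0.5 to every cell", call. = FALSE)
    }
    cts <- cts + 0.5
  }
  a <- cts[1]; b <- cts[2]; cc <- cts[3]; d <- cts[4]
  if (method == "closed_form") {
    beta1 <- log((a * d) / (b * cc))
    beta0 <- log(b / d)   # log-odds of reference essentiality at x = 0
  } else {
    ## expand to unit records and fit by IRLS
    y <- c(rep(1, a + b), rep(0, cc + d))
    x <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    beta0 <- unname(stats::coef(fit)[1])
    beta1 <- unname(stats::coef(fit)[2])
  }
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  p <- 2 * stats::pnorm(-abs(beta1 / se))
  out <- list(beta0 = beta0, beta1 = beta1, or = exp(beta1), se = se,
              p_value = p, table = table, method = method)
  if (lr && method == "glm") {
    out$p_lr <- stats::anova(fit, test = "LRT")[2, "Pr(>Chi)"]
  }
  structure(out, class = "gmcs_or")
}

#' @export
print.gmcs_or <- function(x, ...) {
  cat(sprintf("logistic odds ratio: OR = %.4g (beta1 = %.4g, SE = %.3g, ",
              x$or, x$beta1, x$se))
  cat(sprintf("two-sided Wald p = %.3g)\n", x$p_value))
  invisible(x)
}

#' Tidy a logistic odds-ratio fit
#'
#' @param x a `gmcs_or`.
#' @param ... unused.
#' @return tibble with one row per coefficient.
#' @export
tidy.gmcs_or <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "predicted_essential"),
                 estimate = c(x$beta0, x$beta1),
                 std.error = c(NA_real_, x$se),
                 p.value = c(NA_real_, x$p_value))
}

#' @export
glance.gmcs_or <- function(x, ...) {
  tibble::tibble(or = x$or, beta1 = x$beta1, se = x$se,
                 p.value = x$p_value,
                 n = x$table$a + x$table$b + x$table$c + x$table$d)
}

#' One-sided binomial frequency test
#'
#' Exact upper-tail probability `P(X >= successes)` for `X ~ Binomial(n,
#' p0)`: is a cut set's frequency of full silencing across samples
#' significantly higher than the baseline false-positive rate? The default
#' null `p0 = 0.25` is the conservative false-positive probability
#' estimated from reference loss-of-function screens.
#'
#' @param successes number of samples in which the event occurred.
#' @param n number of samples.
#' @param p0 null success probability.
#' @return the one-sided p-value.
#' @export
binomial_frequency_test <- function(successes, n, p0 = 0.25) {
  if (successes < 0 || n < 1 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("invalid counts: need 0 <= successes <= n (integers)",
         call. = FALSE)
  }
  stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
}

#' Summarise partner-gene expression for one unit
#'
#' For a sensitivity record the partner genes of the cut set (the set minus
#' the target gene) are summarised into a single expression value. The
#' default is the maximum: each partner is an escape route for silencing of
#' the target, and the most expressed one limits the knockout's effect.
#' Mean and sum are provided as alternatives.
#'
#' @param partner_values named numeric vector of partner-gene expression
#'   values (the target gene, if present, is dropped by name via
#'   `target_gene`).
#' @param mode `"max"`, `"mean"` or `"sum"`.
#' @param target_gene optional gene id to exclude.
#' @return numeric scalar.
#' @export
partner_summary <- function(partner_values, mode = c("max", "mean", "sum"),
                            target_gene = NULL) {
  mode <- match.arg(mode)
  if (!is.null(target_gene) && !is.null(names(partner_values))) {
    partner_values <- partner_values[setdiff(names(partner_values),
                                             target_gene)]
  }
  if (!length(partner_values)) {
    stop("no partner genes to summarise", call. = FALSE)
  }
  switch(mode, max = max(partner_values), mean = mean(partner_values),
         sum = sum(partner_values))
}

#' Build sensitivity records for one cut set
#'
#' Joins per-unit (e.g. cell line) sensitivity scores with partner-gene
#' expression: one row per unit with the partner summary and a flag for
#' "any partner expressed".
#'
#' @param scores tibble with columns `unit` and `score` (lower = more
#'   sensitive to silencing of the target).
#' @param profile an `expr_profile` whose sample columns are the units.
#' @param gene_set the cut set (target plus partners).
#' @param target_gene the target gene.
#' @param mode summary mode, see [partner_summary()].
#' @param threshold expression-call threshold.
#' @return tibble of class `sensitivity_records` with `unit`, `score`,
#'   `partner_expr`, `any_partner_expressed`.
#' @export
sensitivity_records <- function(scores, profile, gene_set, target_gene,
                                mode = "max",
                                threshold = attr(profile, "threshold") %||% 5) {
  partners <- setdiff(gene_set, target_gene)
  if (!length(partners)) stop("cut set has no partner genes", call. = FALSE)
  missing <- setdiff(partners, profile$gene)
  if (length(missing)) {
    stop("partner gene(s) absent from the expression profile: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- intersect(scores$unit, setdiff(names(profile), "gene"))
  if (!length(units)) {
    stop("no overlap between score units and profile samples",
         call. = FALSE)
  }
  rows <- lapply(units, function(u) {
    vals <- stats::setNames(
      vapply(partners, function(g) profile[[u]][profile$gene == g],
             numeric(1)), partners)
    tibble::tibble(unit = u,
                   score = scores$score[scores$unit == u][1],
                   partner_expr = partner_summary(vals, mode),
                   any_partner_expressed = any(vals >= threshold))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_records", class(out))
  out
}

#' Spearman association between sensitivity and partner expression
#'
#' Rank correlation between the per-unit sensitivity score and the partner
#' expression summary, with average ranks on ties. The one-tailed p-value
#' tests for positive association: higher partner expression should come
#' with a higher (less sensitive) score, because expressed partners rescue
#' the target's loss.
#'
#' @param records a [sensitivity_records()] tibble.
#' @return list with `rho` and `p_one_tailed`.
#' @export
spearman_sensitivity <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(records$score) == 0 || stats::sd(records$partner_expr) == 0) {
    stop("constant scores or partner expression: rank correlation ",
         "undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(records$partner_expr, records$score,
                    method = "spearman", alternative = "greater",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_one_tailed = ct$p.value)
}

#' Mann-Whitney comparison of sensitivity between expression groups
#'
#' Splits units into those with at least one partner gene expressed (group
#' A) and those with all partners lowly expressed (group B) and tests, one-
#' tailed, whether group A's scores are stochastically greater — silencing
#' should bite less when an escape route is transcribed. The exact U
#' distribution is used for small tie-free groups (both sizes <= 12), the
#' normal approximation with tie correction otherwise; fully degenerate
#' data (all values equal) gives p = 0.5.
#'
#' @param records a [sensitivity_records()] tibble.
#' @return list with `p_one_tailed`, `n_expressed`, `n_unexpressed`.
#' @export
mannwhitney_groups <- function(records) {
  a <- records$score[records$any_partner_expressed]
  b <- records$score[!records$any_partner_expressed]
  if (!length(a)) stop("group with an expressed partner is empty",
                       call. = FALSE)
  if (!length(b)) stop("group with all partners unexpressed is empty",
                       call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  if (stats::sd(c(a, b)) == 0) {
    p <- 0.5
  } else {
    use_exact <- !ties && min(length(a), length(b)) <= 12
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "greater",
                         exact = use_exact, correct = !use_exact))
    p <- wt$p.value
  }
  list(p_one_tailed = p, n_expressed = length(a), n_unexpressed = length(b))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), order-preserving with
#' the input.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
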