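#' Risk proportion table
#'
#' Tabulates at-risk vs no-risk counts and percentages, overall or within the
#' categories of a grouping attribute (gender, setting, classroom).
#'
#' @param classifications data frame as returned by [score_audit_all()]
#'   (needs an `at_risk` logical column plus any grouping columns).
#' @param by optional name of a grouping column.
#' @return data frame with columns `group` (`"all"` when `by` is `NULL`),
#'   `status`, `n`, `pct`; percentages sum to 100 within each group.
#' @export
risk_proportions <- function(classifications, by = NULL) {
  if (NROW(classifications) == 0) {
    ts_stop("risk_proportions needs at least one classification", "usage_error")
  }
  groups <- if (is.null(by)) rep("all", nrow(classifications))
            else as.character(classifications[[by]])
  out <- do.call(rbind, lapply(split(classifications$at_risk, groups), function(r) {
    data.frame(status = c("no_risk", "at_risk"),
               n = c(sum(!r), sum(r)),
               pct = 100 * c(sum(!r), sum(r)) / length(r),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(group = rep(names(split(classifications$at_risk, groups)),
                           each = 2), out)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test of association
#'
#' Thin wrapper over [stats::chisq.test()] for observed contingency counts,
#' without continuity correction by default (matching common STATA usage).
#'
#' @param table matrix of observed counts, at least 2x2, all nonnegative.
#' @param continuity apply the Yates continuity correction (2x2 only).
#' @return object of class `chi_square_result`: list with `statistic`, `df`,
#'   `p_value`, `table`, `continuity_corrected`.
#' @export
chi_square <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    ts_stop("contingency table needs at least 2 rows and 2 columns",
            "usage_error")
  }
  if (anyNA(table) || any(table < 0)) {
    ts_stop("contingency counts must be nonnegative", "validation_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    ts_stop("degenerate table: a row or column margin is zero",
            "degenerate_table_error")
  }
  ht <- suppressWarnings(chisq.test(table, correct = continuity))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 table = table,
                 continuity_corrected = continuity),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("X^2(%d, N = %d) = %.3f, p = %.4f%s\n", x$df, sum(x$table),
              x$statistic, x$p_value,
              if (x$continuity_corrected) " (continuity corrected)" else ""))
  invisible(x)
}

# Exact density of the sample Pearson correlation r for a bivariate-normal
# sample of size n with population correlation rho (Hotelling's form; the
# Gaussian hypergeometric factor is summed directly, the series converges
# geometrically for |x| < 1).
hyp2f1 <- function(a, b, c_, x, tol = 1e-13, maxit = 1000L) {
  term <- 1; s <- 1
  for (k in 0:maxit) {
    term <- term * (a + k) * (b + k) / ((c_ + k) * (k + 1)) * x
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

dcorr_sample <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r)
  exp(lc) * vapply(r, function(ri) hyp2f1(0.5, 0.5, n - 0.5, (rho * ri + 1) / 2),
                   numeric(1))
}

#' Power of the two-sided test of zero Pearson correlation
#'
#' Probability of rejecting the null hypothesis rho = 0 at level `alpha`
#' (two-sided t test on r) when the true bivariate-normal correlation is
#' `r_true` and the sample size is `n`. The default `"exact"` method
#' integrates the exact sampling distribution of r; `"fisher_z"` uses the
#' Fisher z approximation (z = atanh(r), SE = 1 / sqrt(n - 3)), which
#' understates power noticeably for large |r| at small n.
#'
#' @param r_true true correlation, |r_true| <= 1.
#' @param n sample size, at least 4.
#' @param alpha two-sided significance level (default 0.05).
#' @param method `"exact"` or `"fisher_z"`.
#' @return power in `[alpha, 1]`.
#' @export
power_for_r <- function(r_true, n, alpha = 0.05,
                        method = c("exact", "fisher_z")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 4) {
    ts_stop("power_for_r requires n >= 4", "usage_error")
  }
  n <- as.integer(n)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    ts_stop("alpha must lie in (0, 1)", "usage_error")
  }
  if (abs(r_true) > 1) ts_stop("|r_true| cannot exceed 1", "usage_error")
  if (r_true == 0) return(alpha)
  if (abs(r_true) >= 1 - 1e-12) return(1)
  if (method == "fisher_z") {
    zcrit <- qnorm(1 - alpha / 2)
    delta <- atanh(r_true) * sqrt(n - 3)
    return(pnorm(delta - zcrit) + pnorm(-delta - zcrit))
  }
  tcrit <- qt(1 - alpha / 2, n - 2)
  rcrit <- tcrit / sqrt(tcrit^2 + n - 2)
  upper <- integrate(dcorr_sample, rcrit, 1, rho = r_true, n = n,
                     rel.tol = 1e-9)$value
  lower <- integrate(dcorr_sample, -1, -rcrit, rho = r_true, n = n,
                     rel.tol = 1e-9)$value
  min(1, upper + lower)
}

#' Cross-layer correlation of transitive-triad participation
#'
#' Correlates, across two network layers on the same actors (e.g. the
#' consumption layer against the minimum-intensity or gender-homophilous
#' contact layer), vectors summarising each layer's transitive structure.
#' The default `node_profile` mode correlates the per-actor counts of
#' transitive triads each actor participates in; `census_vector` correlates
#' the 16 triad-type counts; `tie_level` correlates the vectorized
#' off-diagonal adjacencies.
#'
#' @param net_a,net_b [binary_network()]s over the same `actor_order`.
#' @param scheme a [transitivity_scheme()].
#' @param mode `"node_profile"`, `"census_vector"` or `"tie_level"`.
#' @param alpha significance level used for the attached power (default 0.05).
#' @param power_method passed to [power_for_r()].
#' @return object of class `layer_correlation`: list with `classroom`, `r`,
#'   `n` (vector length), `p_value` (two-sided, via the t transform), `power`
#'   (of the test at the observed r), `alpha`, `mode`, `layer_pair`.
#' @export
transitive_profile_correlation <- function(net_a, net_b,
                                           scheme = transitivity_scheme(),
                                           mode = c("node_profile",
                                                    "census_vector",
                                                    "tie_level"),
                                           alpha = 0.05,
                                           power_method = "exact") {
  mode <- match.arg(mode)
  if (!identical(net_a$actor_order, net_b$actor_order)) {
    ts_stop("networks have different actor orders", "alignment_error")
  }
  va <- layer_vector(net_a, scheme, mode)
  vb <- layer_vector(net_b, scheme, mode)
  n <- length(va)
  if (n < 3) ts_stop("correlation vectors need length >= 3", "usage_error")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    ts_stop(sprintf(
      "undefined correlation in classroom '%s': zero variance in the %s vector of layer '%s'",
      net_a$classroom, mode,
      if (stats::sd(va) == 0) net_a$layer else net_b$layer),
      "zero_variance_error")
  }
  r <- cor(va, vb)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  pw <- if (n >= 4) power_for_r(r, n, alpha, method = power_method) else NA_real_
  structure(list(classroom = net_a$classroom, r = r, n = n, p_value = p,
                 power = pw, alpha = alpha, mode = mode,
                 layer_pair = c(net_a$layer, net_b$layer)),
            class = "layer_correlation")
}

layer_vector <- function(net, scheme, mode) {
  switch(mode,
    node_profile = node_triad_profile(net, scheme)$transitive,
    census_vector = as.numeric(triad_census(net, scheme)$counts),
    tie_level = {
      a <- net$adjacency
      as.numeric(a[row(a) != col(a)])
    })
}

#' @export
print.layer_correlation <- function(x, ...) {
  cat(sprintf("<layer_correlation> '%s' %s~%s (%s): r = %.2f, p = %.4f, power = %.2f\n",
              x$classroom, x$layer_pair[1], x$layer_pair[2], x$mode,
              x$r, x$p_value, x$power))
  invisible(x)
}
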