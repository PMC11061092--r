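# Functional degree, the hub disruption index, and the study's statistics.

#' Functional degree (nodal connectivity strength)
#'
#' The per-region mean of the off-diagonal entries of a symmetric
#' connectivity matrix: each region's average functional connectivity to all
#' other regions. The diagonal is excluded.
#'
#' @param m A `connectivity_matrix` (or plain symmetric numeric matrix).
#' @return Tibble with columns `region`, `degree` and, when available, a
#'   `measure` column taken from the matrix attribute.
#' @export
functional_degree <- function(m) {
  if (nrow(m) < 2 || nrow(m) != ncol(m)) {
    abort("a square matrix with at least 2 regions is required")
  }
  w <- unclass(m)
  deg <- (rowSums(w) - diag(w)) / (ncol(w) - 1)
  labels <- rownames(w)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(nrow(w)))
  out <- tibble(region = labels, degree = deg)
  if (!is.null(attr(m, "measure"))) out$measure <- attr(m, "measure")
  out
}

degree_values <- function(x, arg) {
  if (is_tibble(x) || is.data.frame(x)) {
    col <- intersect(c("degree", "value", "pe"), names(x))[1]
    if (is.na(col)) abort(sprintf("`%s` has no degree/value column", arg))
    x[[col]]
  } else {
    as.numeric(x)
  }
}

#' Hub disruption index
#'
#' Ordinary least-squares regression of the per-region change in functional
#' degree (perturbed minus reference) on the degree in the reference model.
#' The slope is the hub disruption index (HDI): a significantly negative
#' slope means regions with high reference degree (hubs) lose
#' disproportionately more connectivity under the perturbation. The x-axis
#' is always the reference (balanced-model) degree; swapping the roles of
#' the two profiles is not a sign flip of the same regression.
#'
#' @param reference Per-region degrees of the reference (balanced) model:
#'   numeric vector or a tibble with a `degree` column.
#' @param perturbed Matching per-region degrees of the perturbed model.
#' @return An `hdi_fit` with elements `slope` (the HDI), `offset`,
#'   `r_squared`, `f_stat`, `df_num` (always 1), `df_den` (regions - 2) and
#'   `p_value`, plus the underlying `lm` fit. Supports [tidy()], [glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' hub_disruption_index(c(1, 2, 3), c(3, 2, 1))   # slope -2, offset 4
#' @export
hub_disruption_index <- function(reference, perturbed) {
  ref <- degree_values(reference, "reference")
  per <- degree_values(perturbed, "perturbed")
  if (length(ref) != length(per)) {
    abort("`reference` and `perturbed` must cover the same regions")
  }
  if (length(ref) < 3) abort("at least 3 regions are required")
  if (!all(is.finite(ref)) || !all(is.finite(per))) {
    abort("degrees must be finite")
  }
  if (var(ref) == 0) {
    abort("reference degrees have zero variance; HDI regression undefined",
          class = "eidyn_error_zero_variance")
  }
  d <- tibble(reference = ref, delta = per - ref)
  fit <- lm(delta ~ reference, data = d)
  sm <- suppressWarnings(summary(fit))
  # a constant degree change fits exactly with zero slope; define R^2 = 0
  r2 <- if (var(d$delta) == 0) 0 else sm$r.squared
  df_den <- length(ref) - 2L
  f_stat <- if (r2 >= 1) Inf else r2 * df_den / (1 - r2)
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      offset = unname(coef(fit)[1L]),
      r_squared = r2,
      f_stat = f_stat,
      df_num = 1L,
      df_den = df_den,
      p_value = unname(pf(f_stat, 1, df_den, lower.tail = FALSE)),
      fit = fit,
      data = d
    ),
    class = "hdi_fit"
  )
}

#' @export
print.hdi_fit <- function(x, ...) {
  cat(sprintf(
    "<hdi_fit> HDI slope = %.3f, offset = %.3f, R^2 = %.3f, F(%d, %d) = %.4g, p = %.3g\n",
    x$slope, x$offset, x$r_squared, x$df_num, x$df_den, x$f_stat, x$p_value
  ))
  invisible(x)
}

#' @method tidy hdi_fit
#' @export
tidy.hdi_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("offset", "slope"),
    estimate = unname(sm[, 1L]),
    std.error = unname(sm[, 2L]),
    statistic = unname(sm[, 3L]),
    p.value = unname(sm[, 4L])
  )
}

#' @method glance hdi_fit
#' @export
glance.hdi_fit <- function(x, ...) {
  tibble(
    hdi = x$slope, offset = x$offset, r.squared = x$r_squared,
    statistic = x$f_stat, df = x$df_num, df.residual = x$df_den,
    p.value = x$p_value
  )
}

#' Independent two-sample t-test with Cohen's d
#'
#' Two-sided independent-samples t-test (pooled variance by default, since
#' the study compares equal-sized sets of runs; Welch available) with the
#' pooled-SD Cohen's d effect size.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return One-row tibble: `t`, `df`, `p_value`, `cohens_d`, `mean_a`,
#'   `mean_b`.
#' @export
independent_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    abort("zero pooled variance; t-test undefined",
          class = "eidyn_error_zero_variance")
  }
  ht <- t.test(a, b, var.equal = var_equal)
  tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = (mean(a) - mean(b)) / sqrt(sp2),
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("at least 3 observations are required")
  if (var(x) == 0 || var(y) == 0) {
    abort("constant input; correlation undefined",
          class = "eidyn_error_zero_variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic is reported for the
#' `a`-over-`b` orientation (number of pairs where `a` beats `b`, ties
#' counting one half). The p-value is exact for small tie-free samples and
#' uses the tie-corrected normal approximation otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param a,b Nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `u`, `p_value`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 1 || length(b) < 1) abort("both groups must be nonempty")
  ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = NULL, correct = TRUE))
  tibble(u = unname(ht$statistic), p_value = ht$p.value)
}

bh_n_rejections <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= q * seq_len(m) / m)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' The two-stage linear step-up procedure: a first Benjamini-Hochberg pass
#' at level `q' = q / (1 + q)` estimates the number of true null hypotheses
#' `m0 = m - r1`; if `0 < r1 < m`, a second pass runs at level
#' `q' * m / m0`. Controls the false discovery rate at `q` for independent
#' and positively dependent tests while being less conservative than plain
#' Benjamini-Hochberg.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q Desired false discovery rate (default 0.01, the study setting).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_bky <- function(p, q = 0.01) {
  if (any(p < 0 | p > 1, na.rm = FALSE) || anyNA(p)) {
    abort("p-values must lie in [0, 1]", class = "eidyn_error_pvalues")
  }
  m <- length(p)
  if (m == 0L) return(logical(0))
  q1 <- q / (1 + q)
  r1 <- bh_n_rejections(p, q1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  q2 <- q1 * m / (m - r1)
  r2 <- bh_n_rejections(p, q2)
  p <= if (r2 == 0L) -Inf else sort(p)[r2]
}
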