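#' Sample skewness and excess kurtosis
#'
#' Moment-based normality summary: skewness `m3 / m2^(3/2)` and excess
#' kurtosis `m4 / m2^2 - 3` (zero for a normal distribution), where `mk`
#' are central sample moments.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return named numeric vector with `skewness` and `excess_kurtosis`.
#' @export
normality_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("input is constant: zero variance", call. = FALSE)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  c(skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  groups
}

#' One-way analysis of variance
#'
#' Partitions the total sum of squares into between- and within-group
#' components; `F = MSB / MSW` with `(k - 1, N - k)` degrees of freedom and
#' a p-value from the F distribution. When all observations are identical
#' the statistic is defined as `F = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @param alpha significance level carried into the result.
#' @return an object of class `fog_anova` with fields `F`, `df_between`,
#'   `df_within`, `p`, `alpha`, `ss_between`, `ss_within`, `ss_total`,
#'   `ms_between`, `ms_within`, `group_means`, `group_n`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
one_way_anova <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  all_x <- unlist(groups, use.names = FALSE)
  gm <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) {
    sum((groups[[i]] - means[i])^2)
  }, numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw <= 0) {
    Fstat <- if (ssb <= 1e-24) 0 else Inf
    p <- if (Fstat == 0) 1 else 0
  } else {
    Fstat <- msb / msw
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  structure(
    list(F = Fstat, df_between = dfb, df_within = dfw, p = p, alpha = alpha,
         ss_between = ssb, ss_within = ssw, ss_total = ssb + ssw,
         ms_between = msb, ms_within = msw,
         group_means = stats::setNames(means, nm),
         group_n = stats::setNames(ns, nm)),
    class = "fog_anova"
  )
}

#' @export
print.fog_anova <- function(x, ...) {
  cat(sprintf("<fog_anova> F(%d, %d) = %.3f, p = %.4g (alpha = %g)\n",
              x$df_between, x$df_within, x$F, x$p, x$alpha))
  invisible(x)
}

#' Tukey HSD all-pairs comparisons
#'
#' Post-hoc pairwise comparisons based on the studentized range
#' distribution, with the Tukey--Kramer correction for unbalanced group
#' sizes: `q = |mean_a - mean_b| / sqrt((MSW / 2) (1/n_a + 1/n_b))`, with
#' adjusted p-values from `ptukey(q, k, df_within)`.
#'
#' @param groups list of numeric vectors as in [one_way_anova()]; names are
#'   used as group labels.
#' @param alpha family-wise significance level.
#' @return a `data.frame` of class `fog_tukey` with columns `group_a`,
#'   `group_b`, `mean_diff` (b - a), `q_stat`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  an <- one_way_anova(groups, alpha = alpha)
  k <- length(groups)
  nm <- names(an$group_means)
  means <- an$group_means
  ns <- an$group_n
  msw <- an$ms_within
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((msw / 2) * (1 / ns[a] + 1 / ns[b]))
    diff <- means[b] - means[a]
    q <- if (se > 0) abs(diff) / se else if (abs(diff) < 1e-12) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    data.frame(group_a = nm[a], group_b = nm[b], mean_diff = unname(diff),
               q_stat = unname(q), p_adj = unname(p),
               significant = unname(p < alpha), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fog_tukey", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "df_within") <- an$df_within
  out
}

#' @export
print.fog_tukey <- function(x, ...) {
  cat(sprintf("<fog_tukey> Tukey HSD pairwise comparisons (alpha = %g)\n",
              attr(x, "alpha")))
  df <- data.frame(
    pair = paste(x$group_a, "vs", x$group_b),
    mean_diff = sprintf("%.3f", x$mean_diff),
    q = sprintf("%.3f", x$q_stat),
    p_adj = sprintf("%.4g", x$p_adj),
    sig = ifelse(x$significant, "*", "")
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
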