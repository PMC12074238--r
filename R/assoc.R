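# Rating-agreement and association statistics: ICC(3,k), Spearman rank
# correlation, Bartlett's test of sphericity.

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects, consistency, average-measures intraclass
#' correlation from the standard mean-square decomposition:
#' `(MS_items - MS_error) / MS_items`, where items are the rated targets
#' (columns) and the k raters (rows) are treated as fixed.
#'
#' @param wide_matrix Complete numeric matrix of ratings, raters in rows,
#'   items in columns; at least 2 of each. Missing cells are rejected (no
#'   imputation).
#' @return A `pam_icc` list: `icc`, `form` (`"ICC(3,k)"`), `n_items`,
#'   `n_raters`, and the mean squares `ms_items`, `ms_error`.
#' @examples
#' m <- rbind(c(1, 4, 7), c(1, 4, 7))  # perfect agreement, items differ
#' icc3k(m)$icc  # 1
#' @export
icc3k <- function(wide_matrix) {
  m <- as.matrix(wide_matrix)
  if (anyNA(m)) stop("missing cells are not supported (no imputation)",
                     call. = FALSE)
  k <- nrow(m) # raters
  n <- ncol(m) # items
  if (k < 2L || n < 2L) stop("need at least 2 raters and 2 items",
                             call. = FALSE)
  grand <- mean(m)
  item_means <- colMeans(m)
  rater_means <- rowMeans(m)
  ss_items <- k * sum((item_means - grand)^2)
  ss_raters <- n * sum((rater_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_items - ss_raters
  ms_items <- ss_items / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  structure(
    list(
      icc = (ms_items - ms_error) / ms_items,
      form = "ICC(3,k)",
      n_items = n, n_raters = k,
      ms_items = ms_items, ms_error = ms_error
    ),
    class = "pam_icc"
  )
}

#' @export
print.pam_icc <- function(x, ...) {
  cat(sprintf("%s = %.4f  (%d raters x %d items)\n",
              x$form, x$icc, x$n_raters, x$n_items))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties).
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither
#'   constant (the correlation is undefined for a constant vector).
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Spearman correlation is undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Bartlett's test of sphericity
#'
#' Tests whether the sample correlation matrix of a multivariate dataset
#' is the identity (no correlations to exploit by factor analysis). The
#' statistic is `-(n - 1 - (2p + 5) / 6) * ln det(R)` on the sample
#' correlation matrix `R`, referred to a chi-square with `p (p - 1) / 2`
#' degrees of freedom.
#'
#' @param data_matrix Numeric matrix or data frame, `n` rows (observations)
#'   by `p >= 2` columns (variables), with `n > p`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(data_matrix) {
  m <- as.matrix(data_matrix)
  n <- nrow(m)
  p <- ncol(m)
  if (p < 2L) stop("need at least 2 variables", call. = FALSE)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  R <- stats::cor(m)
  detR <- det(R)
  if (!is.finite(detR) || detR <= 0) {
    stop("correlation matrix is singular", call. = FALSE)
  }
  statistic <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE)
  )
}
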