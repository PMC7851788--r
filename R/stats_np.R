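# Nonparametric group comparisons implemented from their rank formulas:
# tie-corrected Kruskal-Wallis one-way ANOVA on ranks and Dunn's post hoc
# test with Bonferroni adjustment.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  if (any(!vapply(groups, length, 1L)))
    stop("every group must be non-empty")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, function(g) {
    g <- as.numeric(g)
    if (any(!is.finite(g))) stop("groups must contain finite values only")
    g
  })
}

# pooled mid-ranks plus the tie term sum(t^3 - t)
pooled_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)  # mid-ranks for ties
  t <- table(x)
  list(ranks = split(r, rep(seq_along(groups), lengths(groups))),
       n = lengths(groups), N = length(x),
       tie_sum = sum(t^3 - t))
}

#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1), divided by the tie-correction
#' factor 1 - sum(t^3 - t)/(N^3 - N); the p-value is the chi-square upper
#' tail with k-1 degrees of freedom (mid-rank convention for ties). When all
#' pooled values are identical the statistic is 0 and p = 1.
#'
#' @param groups Named list of >= 2 non-empty numeric vectors.
#' @return List of class `rank_test`: `statistic` (H), `df`, `p_value`,
#'   `method`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2), b = c(3, 4)))$statistic  # 2.4
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  pr <- pooled_ranks(groups)
  N <- pr$N
  if (N < 3L) stop("need total n >= 3")
  tie_factor <- 1 - pr$tie_sum / (N^3 - N)
  if (tie_factor <= 0) {  # all pooled values identical
    h <- 0
    p <- 1
  } else {
    rsum <- vapply(pr$ranks, sum, 0)
    h <- (12 / (N * (N + 1)) * sum(rsum^2 / pr$n) - 3 * (N + 1)) / tie_factor
    p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(statistic = h, df = length(groups) - 1L, p_value = p,
                 method = "Kruskal-Wallis rank sum test (tie-corrected)"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", signif(x$statistic, 6), ", df = ", x$df,
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' For every pair (i, j) of groups, z = (Rbar_i - Rbar_j) / sqrt\{\[N(N+1)/12
#' - sum(t^3 - t)/(12(N-1))\] (1/n_i + 1/n_j)\} on the pooled mid-ranks,
#' two-sided p from the standard normal, and p_adjusted = min(1, p m) with
#' m = k(k-1)/2 (all pairwise comparisons, whether reported or not). With
#' every pooled value tied the pairwise p values are 1.
#'
#' @param groups Named list of >= 2 non-empty numeric vectors.
#' @return List of class `rank_test` with the omnibus Kruskal-Wallis fields
#'   plus `pairwise`: a data.frame with `label_a`, `label_b`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  kw <- kruskal_wallis(groups)
  pr <- pooled_ranks(groups)
  N <- pr$N
  k <- length(groups)
  m <- k * (k - 1L) / 2L
  var_term <- N * (N + 1) / 12 - pr$tie_sum / (12 * (N - 1))
  rbar <- vapply(pr$ranks, mean, 0)
  labs <- names(groups)
  pairs <- utils::combn(k, 2)
  rows <- vector("list", ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se2 <- unname(var_term * (1 / pr$n[i] + 1 / pr$n[j]))
    if (se2 <= 0) {  # zero pooled variance: everything tied
      z <- 0; p <- 1
    } else {
      z <- unname((rbar[i] - rbar[j]) / sqrt(se2))
      p <- 2 * stats::pnorm(-abs(z))
    }
    rows[[c]] <- data.frame(label_a = labs[i], label_b = labs[j], z = z,
                            p_raw = p, p_adjusted = min(1, p * m))
  }
  pairwise <- do.call(rbind, rows)
  structure(list(statistic = kw$statistic, df = kw$df,
                 p_value = kw$p_value,
                 method = "Dunn's test with Bonferroni adjustment",
                 pairwise = pairwise),
            class = "rank_test")
}
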