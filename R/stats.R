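#' Paired t-test (crossover / within-group contrast)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the per-subject differences
#' `d = condition_a - condition_b`, with `df = n - 1` and a two-tailed p.
#'
#' @param condition_a,condition_b per-subject values under the two
#'   conditions, paired by position; no missing pairs.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))  # t = 3.464, df = 2
#' @export
paired_t <- function(condition_a, condition_b) {
  if (length(condition_a) != length(condition_b))
    stop("conditions must be paired: equal lengths required")
  if (anyNA(condition_a) || anyNA(condition_b))
    stop("no missing pairs allowed")
  d <- condition_a - condition_b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0)
    stop("zero-variance differences: the paired t statistic is undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       mean_diff = mean(d))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sort ascending; the i-th sorted p becomes
#' `max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1, and adjusted
#' values are returned in the input order.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # c(0.0199, 0.04)
#' @export
holm_sidak <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = FALSE) || anyNA(pvalues))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  ps <- pvalues[o]
  adj <- cummax(1 - (1 - ps)^(m - seq_len(m) + 1L))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Permutation treatment-by-time interaction test
#'
#' An assumption-light surrogate for the mixed factorial
#' (treatment-by-time) ANOVA used for repeated-measures series: each
#' subject's profile is centred on its own mean (removing the random
#' intercept), the statistic is the sum over timepoints of the squared
#' between-treatment differences of group means of the centred values, and
#' the null distribution is built by permuting treatment labels across
#' subjects. `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param values numeric matrix, subjects in rows, timepoints in columns
#'   (at least 2 columns).
#' @param treatment per-subject treatment labels (at least 2 levels, each
#'   with at least 2 subjects). For more than 2 levels the statistic sums
#'   squared differences over all level pairs.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed making the permutation stream reproducible.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
perm_interaction <- function(values, treatment, n_perm = 1000L, seed = 1L) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need >= 2 timepoints")
  if (nrow(values) != length(treatment))
    stop("one treatment label per subject (row) required")
  if (anyNA(values)) stop("values must be complete (rectangular design)")
  treatment <- as.factor(treatment)
  if (nlevels(treatment) < 2L) stop("need >= 2 treatment levels")
  if (any(table(treatment) < 2L))
    stop("every treatment level needs >= 2 subjects")
  if (n_perm < 100L) stop("n_perm must be >= 100")

  centred <- values - rowMeans(values)
  stat_fun <- function(lab) {
    gm <- rowsum(centred, lab) / as.vector(table(lab))
    s <- 0
    for (g in seq_len(nrow(gm) - 1L))
      for (h in seq.int(g + 1L, nrow(gm)))
        s <- s + sum((gm[g, ] - gm[h, ])^2)
    s
  }
  obs <- stat_fun(treatment)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(i) stat_fun(sample(treatment)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}
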