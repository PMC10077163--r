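# Seasonal significance tests: one-way ANOVA across seasons and the
# Wilcoxon rank-sum test with exact small-sample enumeration.

#' One-way ANOVA of per-station values across seasons
#'
#' Fixed-effects one-way analysis of variance (equal-variance F test) of
#' untransformed per-station abundances against season, with
#' `(g - 1, n - g)` degrees of freedom.
#'
#' @param values Numeric vector of per-station values of one taxon.
#' @param seasons Season label per value.
#' @return List: `statistic` (F), `p_value`, `df` (length 2).
#' @export
anova_seasons <- function(values, seasons) {
  stopifnot(length(values) == length(seasons))
  f <- factor(seasons)
  counts <- table(f)
  if (length(counts) < 2) stop("need at least 2 seasons")
  if (any(counts < 2)) {
    stop("every season needs >= 2 observations; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  fit <- stats::oneway.test(values ~ f, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       p_value = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of two independent samples. The statistic `W`
#' is the sum of the mid-ranks of `x` in the pooled ranking. For small
#' samples (`length(x) + length(y) <= exact_limit`) the p value is
#' computed by exact enumeration of all assignments of the pooled values
#' to the two samples (valid under ties, since mid-ranks are held fixed);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest pooled size for exact enumeration (default 12).
#' @return List: `statistic` (rank sum of `x`), `p_value`, `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4)) # W = 3, exact p = 1/3
wilcoxon_rank_sum <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y))
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])

  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[splits], nrow = nx))
    eps <- 1e-9
    p <- 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- w_obs - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)    # continuity correction
      p <- min(2 * stats::pnorm(-abs(z)), 1)
    }
    method <- "normal_approximation"
  }
  list(statistic = w_obs, p_value = p, method = method)
}
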