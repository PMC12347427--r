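## The two hypothesis tests of the analysis, with explicit exact/approximate
## regimes so p-values are reproducible: Mann-Whitney U (exact by full
## enumeration for small tie-free samples, otherwise normal approximation
## with tie and continuity corrections) and Pearson's chi-square test of
## independence.

#' Mann-Whitney U test
#'
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j` (+ 0.5 per tie). Exact
#' two-sided p by full enumeration of all `C(n_x + n_y, n_x)` allocations
#' when `max(n_x, n_y) <= 8` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return `test_result`: `statistic` (U of x), `p_value`, `method`, `df`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y))
    stemshield_stop("both samples must be non-empty", "empty_sample")
  nx <- length(x); ny <- length(y)
  U_of <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  U <- U_of(x, y)
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  if (max(nx, ny) <= 8 && !ties) {
    ranks <- rank(pooled)
    combos <- utils::combn(nx + ny, nx)
    ## U from the rank sum of the x-allocation
    Us <- colSums(matrix(ranks[combos], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
      greater = mean(Us >= U - 1e-9),
      less = mean(Us <= U + 1e-9),
      stemshield_stop("bad alternative", "invalid_parameter"))
    method <- "exact enumeration"
  } else {
    N <- nx + ny
    tj <- table(pooled)
    tie_term <- sum(tj^3 - tj) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    mu <- nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z_of <- function(u, cc) (u - mu - cc) / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = {
          cc <- sign(U - mu) * 0.5
          min(1, 2 * stats::pnorm(-abs(z_of(U, if (U == mu) 0 else cc))))
        },
        greater = stats::pnorm(z_of(U, 0.5), lower.tail = FALSE),
        less = stats::pnorm(z_of(U, -0.5)),
        stemshield_stop("bad alternative", "invalid_parameter"))
    }
    method <- "normal approximation, tie + continuity correction"
  }
  structure(list(statistic = U, p_value = p, method = method, df = NULL,
                 n = c(nx = nx, ny = ny), alternative = alternative),
            class = "test_result")
}

#' Pearson chi-square test of independence
#'
#' `chi^2 = sum (O - E)^2 / E` with `df = (r-1)(c-1)`; upper-tail p from the
#' chi-square distribution, no continuity correction. Sets `expected_low`
#' when any expected count is below 5.
#'
#' @param table r x c matrix of non-negative counts with positive row and
#'   column sums.
#' @return `test_result` with `statistic`, `p_value`, `df`, `method`,
#'   `expected`, `expected_low`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(!is.finite(tab)))
    stemshield_stop("counts must be finite and non-negative", "invalid_parameter")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stemshield_stop("need at least a 2x2 table", "invalid_parameter")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stemshield_stop("row and column sums must be positive", "invalid_parameter")
  E <- outer(rs, cs) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 df = df, method = "Pearson chi-square", expected = E,
                 expected_low = any(E < 5)),
            class = "test_result")
}

#' Pairwise stimulus comparisons between observed remodeling classes
#'
#' Convenience wrapper reproducing the zone-level box-plot comparison:
#' Mann-Whitney tests between each pair of observed classes, unadjusted.
#'
#' @param stimuli numeric vector of zone median stimuli.
#' @param labels observed class per zone.
#' @return data frame with one row per class pair (`group1`, `group2`,
#'   `n1`, `n2`, `U`, `p_value`, `method`).
#' @export
pairwise_class_tests <- function(stimuli, labels) {
  present <- intersect(remodeling_classes, unique(labels))
  if (length(present) < 2)
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0), U = numeric(0),
                      p_value = numeric(0), method = character(0),
                      stringsAsFactors = FALSE))
  pairs <- utils::combn(present, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- stimuli[labels == pr[1]]; y <- stimuli[labels == pr[2]]
    tr <- mann_whitney_u(x, y)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
               U = tr$statistic, p_value = tr$p_value, method = tr$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
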