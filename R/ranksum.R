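#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. For small samples (`n1 + n2 <=
#' exact_limit`) the null distribution of U is enumerated exactly over all
#' assignments of the pooled values (ties included); larger samples use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (nonempty).
#' @param exact_limit Combined sample size up to which exact enumeration
#'   is used (default 12; at most `choose(12, 6) = 924` assignments).
#' @return A `rank_sum_test` list: `statistic` (U for `x`), `p.value`,
#'   `method`, `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_limit = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (stats::var(pooled) == 0) {
    warning("all values identical in both samples; p = 1")
    return(structure(
      list(statistic = U, p.value = 1, method = "degenerate", n1 = n1, n2 = n2),
      class = "rank_sum_test"
    ))
  }

  if (n <= exact_limit) {
    combs <- utils::combn(n, n1)
    Us <- apply(combs, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (U - mu - 0.5 * sign(U - mu)) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  structure(
    list(statistic = U, p.value = p, method = method, n1 = n1, n2 = n2),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney rank sum: U = %g, p = %.4g (%s, n = %d + %d)\n",
    x$statistic, x$p.value, x$method, x$n1, x$n2
  ))
  invisible(x)
}

#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 method = x$method, n1 = x$n1, n2 = x$n2)
}
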