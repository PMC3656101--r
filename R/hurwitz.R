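#' Hurwitz zeta function for real s > 1
#'
#' Evaluates zeta(s, a) = sum_{k>=0} (k + a)^(-s) by direct summation of the
#' leading terms plus an Euler-Maclaurin tail correction, accurate to about
#' 1e-12 for s > 1 and a >= 1.  This is the normalizing constant of the
#' discrete power law p(x) = x^(-s) / zeta(s, x_min) on x >= x_min.
#'
#' @param s exponent, a single value > 1.
#' @param a shift parameter, a numeric vector with all values >= 1.
#' @return zeta(s, a), vectorized over \code{a}.
#' @examples
#' hurwitzZeta(2, 1)   # pi^2/6
#' @export
hurwitzZeta <- function(s, a) {
  if (length(s) != 1L || !is.finite(s) || s <= 1)
    stop("s must be a single finite value > 1")
  if (any(!is.finite(a)) || any(a < 1))
    stop("a must be finite and >= 1")
  N <- 16L
  ## leading sum: rows = k, columns = a
  k <- 0:(N - 1L)
  lead <- colSums(outer(k, a, function(k, a) (k + a)^(-s)))
  x <- a + N
  tail <- x^(1 - s) / (s - 1) + 0.5 * x^(-s)
  ## Euler-Maclaurin correction with Bernoulli numbers B_2..B_12
  bern <- c(1 / 6, -1 / 30, 1 / 42, -1 / 30, 5 / 66, -691 / 2730)
  poch <- 1
  for (j in seq_along(bern)) {
    two_j <- 2 * j
    ## rising product s (s+1) ... (s + 2j - 2), built incrementally
    poch <- poch * (if (j == 1) s else (s + two_j - 3) * (s + two_j - 2))
    tail <- tail + bern[j] / factorial(two_j) * poch * x^(-s - two_j + 1)
  }
  lead + tail
}
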