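## Discrete power law p(x) = x^-gamma / zeta(gamma, x_min) on x >= x_min.

## survival S(x) = P(X >= x) under the fitted law
plSurvival <- function(x, gamma, x_min) {
  hurwitzZeta(gamma, x) / hurwitzZeta(gamma, x_min)
}

## fitted CDF P(X <= x)
plCdf <- function(x, gamma, x_min) {
  1 - plSurvival(x + 1, gamma, x_min)
}

checkSamples <- function(samples) {
  if (any(!is.finite(samples)) || any(samples != round(samples)))
    stop("samples must be finite integers")
  if (any(samples < 0)) stop("samples must be non-negative")
  ## power law over x >= 1: isolated-node zeros are excluded from fitting
  as.integer(samples[samples >= 1])
}

.pl_gamma_upper <- 20

#' Maximum-likelihood exponent of a discrete power-law tail
#'
#' Fits gamma for p(x) = x^-gamma / zeta(gamma, x_min) to the samples with
#' value >= x_min by 1-D numerical maximization of the zeta-normalized
#' log-likelihood (tolerance 1e-6 on gamma), and reports the
#' Kolmogorov-Smirnov distance between the tail empirical CDF and the
#' fitted CDF.  Zero values (isolated nodes) are excluded.  A tail with no
#' variation above x_min drives gamma to the upper optimization bound and
#' is flagged degenerate.
#'
#' @param samples integer-valued sample (degrees, module sizes, ...).
#' @param x_min smallest value included in the tail.
#' @return A \linkS4class{PowerLawFit} (with \code{p_value = NA}; see
#'   \code{\link{plGofPValue}}).
#' @examples
#' x <- rPowerLaw(500, gamma = 2.5, x_min = 1, seed = 1)
#' fitGamma(x, x_min = 1)
#' @export
fitGamma <- function(samples, x_min) {
  x <- checkSamples(samples)
  if (x_min < 1 || x_min != round(x_min)) stop("x_min must be an integer >= 1")
  tail_x <- x[x >= x_min]
  if (length(tail_x) < 2L)
    stop("tail must hold at least 2 samples (x >= ", x_min, ")")
  n <- length(tail_x)
  slog <- sum(log(tail_x))
  nll <- function(gamma) n * log(hurwitzZeta(gamma, x_min)) + gamma * slog
  opt <- stats::optimize(nll, c(1 + 1e-6, .pl_gamma_upper), tol = 1e-6)
  gamma <- opt$minimum
  degenerate <- all(tail_x == x_min)
  if (degenerate) gamma <- .pl_gamma_upper
  new("PowerLawFit", x_min = as.integer(x_min), gamma = gamma,
      ks = ksDistance(tail_x, gamma, x_min), p_value = NA_real_,
      n_tail = n, degenerate = degenerate)
}

## max absolute CDF gap on the tail, evaluated at the distinct tail values
ksDistance <- function(tail_x, gamma, x_min) {
  ux <- sort(unique(tail_x))
  emp <- stats::ecdf(tail_x)(ux)
  fit <- plCdf(ux, gamma, x_min)
  ## also compare the empirical CDF just below each jump
  emp_lo <- c(0, emp[-length(emp)])
  fit_lo <- plCdf(ux - 1, gamma, x_min)
  max(abs(emp - fit), abs(emp_lo - fit_lo))
}

#' Fit a discrete power law with automatic x_min selection
#'
#' Scans candidate x_min over the distinct observed values, fits gamma at
#' each, and returns the fit whose tail minimizes the Kolmogorov-Smirnov
#' distance; ties break toward smaller x_min (the larger tail).
#'
#' @param samples integer-valued sample.
#' @param x_min optional fixed x_min; when given this is equivalent to
#'   \code{\link{fitGamma}}.
#' @return A \linkS4class{PowerLawFit}.
#' @examples
#' x <- rPowerLaw(500, gamma = 2.4, x_min = 2, seed = 1)
#' fitPowerLaw(c(x, rep(1, 100)))
#' @export
fitPowerLaw <- function(samples, x_min = NULL) {
  if (!is.null(x_min)) return(fitGamma(samples, x_min))
  x <- checkSamples(samples)
  if (length(unique(x)) < 2L) stop("need at least 2 distinct sample values")
  cands <- sort(unique(x))
  cands <- cands[vapply(cands, function(xm) sum(x >= xm) >= 2L, logical(1))]
  if (!length(cands))
    stop("no candidate x_min leaves at least 2 tail points")
  fits <- lapply(cands, function(xm) fitGamma(x, xm))
  ks <- vapply(fits, function(f) f@ks, numeric(1))
  fits[[which.min(ks)]]   # which.min takes the first = smallest x_min
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Semiparametric bootstrap: each replicate draws, for every original
#' observation, either a value resampled from the observed data below
#' x_min (with the observed below-tail probability) or a fresh draw from
#' the fitted power law; the replicate is then refit with its own x_min
#' scan and its KS distance recorded.  The p-value is the fraction of
#' replicates whose KS distance is at least the observed one, so small
#' p-values (< 0.05) reject the power-law hypothesis.
#'
#' @param samples the original integer-valued sample.
#' @param fit the \linkS4class{PowerLawFit} from \code{\link{fitPowerLaw}}.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed (required).
#' @return the fit with its \code{p_value} slot filled in.
#' @export
plGofPValue <- function(samples, fit, n_boot = 1000, seed) {
  if (missing(seed)) stop("an explicit `seed` is required")
  if (n_boot < 100) stop("n_boot must be >= 100")
  x <- checkSamples(samples)
  n <- length(x)
  below <- x[x < fit@x_min]
  p_tail <- 1 - length(below) / n
  ks_rep <- withSeed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take_tail <- stats::runif(n) < p_tail
      n_t <- sum(take_tail)
      rep_x <- integer(n)
      if (n_t) rep_x[take_tail] <- samplePl(n_t, fit@gamma, fit@x_min)
      if (n - n_t)
        rep_x[!take_tail] <- sample(below, n - n_t, replace = TRUE)
      f <- tryCatch(fitPowerLaw(rep_x), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f@ks
    }, numeric(1))
  })
  ks_rep <- ks_rep[!is.na(ks_rep)]
  fit@p_value <- mean(ks_rep >= fit@ks)
  fit
}

#' Exponent of the cumulative tail distribution
#'
#' For a power-law density p(x) ~ x^-gamma the cumulative distribution
#' P(x) = P(X >= x) ~ x^-(gamma - 1), so the cumulative exponent is
#' gamma - 1.
#'
#' @param fit a \linkS4class{PowerLawFit}.
#' @return gamma - 1.
#' @export
cumulativeExponent <- function(fit) {
  stopifnot(is(fit, "PowerLawFit"))
  fit@gamma - 1
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling from p(x) = x^-gamma / zeta(gamma, x_min):
#' draws inside a precomputed probability table are mapped by
#' \code{findInterval}; the rare draws beyond the table are resolved by
#' bisection on the exact zeta survival function.
#'
#' @param n number of draws.
#' @param gamma exponent (> 1).
#' @param x_min smallest value (>= 1).
#' @param seed integer RNG seed (required).
#' @return integer vector of n draws.
#' @export
rPowerLaw <- function(n, gamma, x_min = 1, seed) {
  if (missing(seed)) stop("an explicit `seed` is required")
  if (gamma <= 1) stop("gamma must exceed 1")
  withSeed(seed, samplePl(n, gamma, x_min))
}

samplePl <- function(n, gamma, x_min) {
  K <- 100000L
  ks <- x_min:(x_min + K - 1L)
  z <- hurwitzZeta(gamma, x_min)
  cdf <- cumsum(ks^(-gamma)) / z
  u <- stats::runif(n)
  idx <- findInterval(u, cdf) # 0 => first value
  out <- ks[pmin(idx + 1L, K)]
  over <- u > cdf[K]
  if (any(over)) {
    out[over] <- vapply(u[over], function(ui) {
      ## bisect on S(x) = P(X >= x): find smallest x with CDF(x) >= ui
      lo <- ks[K] + 1
      hi <- lo * 2
      while (1 - plSurvival(hi + 1, gamma, x_min) < ui) {
        lo <- hi + 1
        hi <- hi * 2
      }
      while (lo < hi) {
        mid <- (lo + hi) %/% 2
        if (1 - plSurvival(mid + 1, gamma, x_min) >= ui) hi <- mid
        else lo <- mid + 1
      }
      lo
    }, numeric(1))
  }
  as.integer(out)
}
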