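#' Fit the empirical null from control-guide enrichments
#'
#' Gene-level inference compares each gene's guide enrichments to the
#' distribution of control-guide enrichments (safe-targeting plus
#' non-targeting). The null density f0 is a Gaussian kernel density estimate
#' with bandwidth from Scott's rule ([stats::bw.nrd]), tabulated on a uniform
#' grid spanning `[min - 5 bw, max + 5 bw]`; the log-density is floored (at
#' `floor`) so outlier guides far outside the control range keep a finite
#' log-likelihood.
#'
#' @param control_stats numeric vector of control-guide log2 enrichments
#'   (>= 20 values required).
#' @param bandwidth kernel bandwidth; default Scott's rule.
#' @param floor lower bound on the log-density (default -30).
#' @param n_grid grid resolution (default 2048).
#' @return An object of class `null_model`.
#' @export
fit_null <- function(control_stats, bandwidth = NULL, floor = -30,
                     n_grid = 2048) {
  control_stats <- control_stats[is.finite(control_stats)]
  if (length(control_stats) < 20)
    stop("need at least 20 control statistics to fit the null")
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd(control_stats)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- max(stats::sd(control_stats), 1e-3) *
        length(control_stats)^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1e-3
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  lo <- min(control_stats) - 5 * bandwidth
  hi <- max(control_stats) + 5 * bandwidth
  d <- stats::density(control_stats, bw = bandwidth, from = lo, to = hi,
                      n = n_grid)
  f <- pmax(d$y, exp(floor))
  structure(
    list(control_stats = control_stats, bandwidth = bandwidth, floor = floor,
         x = d$x, f = f, step = d$x[2] - d$x[1]),
    class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Empirical null: KDE of %d control enrichments, bandwidth %.4g\n",
              length(x$control_stats), x$bandwidth))
  cat(sprintf("  support [%.3g, %.3g], log-density floor %g\n",
              min(x$x), max(x$x), x$floor))
  invisible(x)
}

# Null density f0 on the natural scale, vectorized linear interpolation on the
# tabulated grid; exp(floor) outside the support.
null_density <- function(null, q) {
  fl <- exp(null$floor)
  i <- floor((q - null$x[1]) / null$step) + 1
  w <- (q - null$x[1]) / null$step - (i - 1)
  inside <- i >= 1 & i < length(null$x)
  out <- rep(fl, length(q))
  ii <- i[inside]
  out[inside] <- null$f[ii] * (1 - w[inside]) + null$f[ii + 1] * w[inside]
  pmax(out, fl)
}

#' Evaluate the null log-density
#'
#' @param null a `null_model` from [fit_null()].
#' @param q numeric vector of enrichment values.
#' @return log f0(q), finite everywhere (floored).
#' @export
null_log_density <- function(null, q) {
  stopifnot(inherits(null, "null_model"))
  pmax(log(null_density(null, q)), null$floor)
}
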