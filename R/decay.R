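#' Passive-dilution null retention fractions
#'
#' The expected fraction of initially significant features still significant
#' after \eqn{d} divisions when marks are lost passively at 50 percent per
#' division: \eqn{0.5^d}.
#'
#' @param divisions non-negative division indices.
#' @return \code{0.5^divisions}.
#' @export
dilution_null <- function(divisions) {
  if (any(divisions < 0)) stop("divisions must be >= 0")
  0.5^divisions
}

#' Retention curve of T0-significant features
#'
#' For each division, the fraction of features significant at T0 that remain
#' significant, together with the passive-dilution null \eqn{0.5^d}.
#'
#' @param sig_t0 character vector of features significant at T0 (non-empty).
#' @param sig_by_timepoint named list (names = division indices) of character
#'   vectors of significant features per division.
#' @return object of class \code{retention_curve}: a data.frame with columns
#'   \code{division}, \code{observed}, \code{null}, plus attribute
#'   \code{n_t0}. Division 0, if absent from the input, is included with
#'   observed fraction 1 by construction.
#' @export
retention_fractions <- function(sig_t0, sig_by_timepoint) {
  if (length(sig_t0) == 0L) stop("empty T0 significant set")
  d <- as.numeric(names(sig_by_timepoint))
  if (any(is.na(d))) stop("sig_by_timepoint must be named by division index")
  o <- order(d)
  d <- d[o]; sig_by_timepoint <- sig_by_timepoint[o]
  obs <- vapply(sig_by_timepoint, function(s)
    length(intersect(sig_t0, s)) / length(sig_t0), numeric(1))
  if (!0 %in% d) {
    d <- c(0, d)
    obs <- c(1, obs)
  }
  curve <- data.frame(division = d, observed = unname(obs),
                      null = dilution_null(d))
  attr(curve, "n_t0") <- length(sig_t0)
  class(curve) <- c("retention_curve", "data.frame")
  curve
}

#' @export
print.retention_curve <- function(x, ...) {
  cat(sprintf("Retention curve (%d features significant at T0)\n",
              attr(x, "n_t0")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.retention_curve <- function(x, ...) {
  graphics::plot(x$division, x$observed, type = "b", pch = 19,
                 xlab = "divisions post-washout",
                 ylab = "fraction of T0-significant features still significant",
                 ylim = c(0, 1), ...)
  graphics::lines(x$division, x$null, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("observed", "50%-loss null"),
                   lty = c(1, 2), pch = c(19, NA),
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of observed and null retention
#'
#' Compares the observed retention fractions with the passive-dilution null.
#' The default treats the two fraction vectors as two samples and applies the
#' two-sample K-S test (maximum distance between their empirical CDFs, with
#' the asymptotic p-value); alternatively a one-sample K-S test of the
#' observed fractions against the empirical CDF of the null vector is
#' available.
#'
#' @param observed,null equal-length fraction vectors over the same
#'   divisions (length >= 3).
#' @param method \code{"two_sample"} (default) or \code{"one_sample"}.
#' @return list with \code{D} (statistic), \code{p}, and \code{method}.
#' @export
ks_compare <- function(observed, null, method = c("two_sample", "one_sample")) {
  method <- match.arg(method)
  if (length(observed) != length(null))
    stop("observed and null must have equal length")
  if (length(observed) < 3L) stop("need at least 3 timepoints")
  if (method == "two_sample") {
    kt <- suppressWarnings(stats::ks.test(observed, null, exact = FALSE))
    list(D = unname(kt$statistic), p = unname(kt$p.value), method = method)
  } else {
    Fnull <- stats::ecdf(null)
    kt <- suppressWarnings(stats::ks.test(observed, Fnull, exact = FALSE))
    list(D = unname(kt$statistic), p = unname(kt$p.value), method = method)
  }
}

#' Fit an exponential retention rate to a retention curve
#'
#' Least-squares fit of \eqn{\log_2(\mathrm{fraction})} against division over
#' the strictly positive fractions: the slope gives the per-division
#' retention rate \eqn{\hat r = 2^{\mathrm{slope}}} and the half-life in
#' divisions is \eqn{-1/\mathrm{slope}}. Passive dilution corresponds to
#' \eqn{\hat r = 0.5} (half-life of one division); maintained signal gives
#' \eqn{\hat r \approx 1} with an unbounded half-life.
#'
#' @param curve a \code{retention_curve}, or a data.frame with columns
#'   \code{division} and \code{observed}.
#' @return object of class \code{retention_fit}: list with \code{rate}
#'   (\eqn{\hat r}, capped at 1), \code{half_life} (divisions; \code{Inf}
#'   when unbounded), \code{r_squared}, \code{slope}, \code{unbounded} flag
#'   and \code{n_points}.
#' @export
fit_retention_rate <- function(curve) {
  keep <- is.finite(curve$observed) & curve$observed > 0
  if (sum(keep) < 3L)
    stop("need >= 3 strictly positive retention fractions")
  d <- curve$division[keep]
  y <- log2(curve$observed[keep])
  fit <- stats::lm(y ~ d)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  unbounded <- slope >= -1e-9
  out <- list(
    rate = min(2^slope, 1),
    half_life = if (unbounded) Inf else -1 / slope,
    r_squared = r2, slope = slope, unbounded = unbounded,
    n_points = sum(keep))
  class(out) <- "retention_fit"
  out
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf(
    "Retention-rate fit over %d points: r = %.3f per division (half-life %s divisions), R^2 = %.3f%s\n",
    x$n_points, x$rate,
    if (is.infinite(x$half_life)) "Inf" else sprintf("%.2f", x$half_life),
    x$r_squared, if (x$unbounded) " [unbounded: no measurable decay]" else ""))
  invisible(x)
}
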