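#' Calibrate B-statistics into Pc and Pnc
#'
#' Maps raw B-statistics to the two probability estimates the extractor
#' works with: `Pc`, the probability that a FoT belongs to a chemical named
#' entity, as a function of its CNE B-statistic, and `Pnc`, the probability
#' that it does not, as a function of its NON_CNE B-statistic.  The two
#' calibrations are independent one-vs-rest fits, so `Pc + Pnc` need not
#' equal 1.
#'
#' The default method splits the B axis into equal-frequency bins, takes the
#' empirical event frequency per bin, enforces monotonicity by
#' pool-adjacent-violators (a class probability cannot decrease as its own
#' B-statistic grows), and interpolates piecewise-linearly between bin
#' centres with constant extrapolation beyond the outermost centres.
#' `method = "poly"` instead fits a least-squares polynomial of degree
#' `degree` to the binned frequencies (weighted by bin size); its
#' predictions are clipped to `[0, 1]`.
#'
#' Inside [cner()] the B values fed to this function are leave-one-out
#' scores of the training FoTs, so the calibration is not biased by each
#' FoT's own contribution to the counts.
#'
#' @param b_cne B-statistics for class CNE, one per FoT.
#' @param b_ncne B-statistics for class NON_CNE, parallel to `b_cne`.
#' @param is_cne Logical vector: is each FoT truly part of a chemical named
#'   entity?
#' @param method `"binned"` (default) or `"poly"`.
#' @param bins Number of equal-frequency bins (default 20).
#' @param degree Polynomial degree for `method = "poly"` (default 5).
#' @return An object of class `"cner_calibration"`.
#' @export
calibrate_b <- function(b_cne, b_ncne, is_cne,
                        method = c("binned", "poly"),
                        bins = 20L, degree = 5L) {
  method <- match.arg(method)
  stopifnot(length(b_cne) == length(is_cne),
            length(b_ncne) == length(is_cne))
  if (!any(is_cne) || all(is_cne)) {
    stop("calibration needs both CNE and NON_CNE examples")
  }
  structure(list(
    method = method, bins = as.integer(bins), degree = as.integer(degree),
    pc = .calib_map(b_cne, is_cne, method, bins, degree),
    pnc = .calib_map(b_ncne, !is_cne, method, bins, degree)
  ), class = "cner_calibration")
}

# One one-vs-rest calibration map: bin B, per-bin event frequency,
# weighted pool-adjacent-violators, interpolation table (+ poly coefs).
.calib_map <- function(b, event, method, bins, degree) {
  edges <- unique(stats::quantile(b, probs = seq(0, 1, length.out = bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) {
    # degenerate: all B identical
    return(list(x = b[1L], y = mean(event), w = length(b), coef = NULL))
  }
  id <- findInterval(b, edges, rightmost.closed = TRUE, all.inside = TRUE)
  x <- as.numeric(tapply(b, id, mean))
  y <- as.numeric(tapply(event, id, mean))
  w <- as.numeric(tapply(event, id, length))
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  y <- .pava(y, w)
  list(x = x, y = y, w = w, coef = .poly_coef(x, y, w, degree, method))
}

.poly_coef <- function(x, y, w, degree, method) {
  if (method != "poly") return(NULL)
  d <- min(degree, length(x) - 1L)
  X <- outer(x, 0:d, `^`)
  stats::lm.wfit(X, y, w)$coefficients
}

# weighted pool-adjacent-violators: non-decreasing fit to (y, w)
.pava <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_len(n)) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    while (length(vals) > 1L &&
           vals[length(vals) - 1L] > vals[length(vals)]) {
      m <- length(vals)
      merged_w <- wts[m - 1L] + wts[m]
      merged_v <- (vals[m - 1L] * wts[m - 1L] + vals[m] * wts[m]) / merged_w
      merged_s <- sizes[m - 1L] + sizes[m]
      vals <- c(vals[seq_len(m - 2L)], merged_v)
      wts <- c(wts[seq_len(m - 2L)], merged_w)
      sizes <- c(sizes[seq_len(m - 2L)], merged_s)
    }
  }
  rep(vals, sizes)
}

.calib_eval <- function(map, b, method) {
  if (method == "poly" && !is.null(map$coef)) {
    out <- drop(outer(b, seq_along(map$coef) - 1L, `^`) %*% map$coef)
  } else if (length(map$x) == 1L) {
    out <- rep.int(map$y, length(b))
  } else {
    out <- stats::approx(map$x, map$y, xout = b, rule = 2, ties = mean)$y
  }
  pmin(1, pmax(0, out))
}

#' @rdname calibrate_b
#' @param calibration A `"cner_calibration"` object.
#' @param b B-statistic values to map.
#' @export
calib_pc <- function(calibration, b) {
  .calib_eval(calibration$pc, b, calibration$method)
}

#' @rdname calibrate_b
#' @export
calib_pnc <- function(calibration, b) {
  .calib_eval(calibration$pnc, b, calibration$method)
}

#' @export
print.cner_calibration <- function(x, ...) {
  cat(sprintf("B-statistic calibration (%s, %d bins)\n", x$method, x$bins))
  cat(sprintf("  Pc : %d support points over B in [%.3f, %.3f]\n",
              length(x$pc$x), min(x$pc$x), max(x$pc$x)))
  cat(sprintf("  Pnc: %d support points over B in [%.3f, %.3f]\n",
              length(x$pnc$x), min(x$pnc$x), max(x$pnc$x)))
  invisible(x)
}

#' @export
plot.cner_calibration <- function(x, ...) {
  grid <- seq(-1, 1, length.out = 401L)
  graphics::plot(grid, calib_pc(x, grid), type = "l", col = "forestgreen",
                 lwd = 2, xlab = "B-statistic", ylab = "calibrated probability",
                 ylim = c(0, 1), main = "Pc / Pnc calibration", ...)
  graphics::lines(grid, calib_pnc(x, grid), col = "firebrick", lwd = 2)
  graphics::legend("left", legend = c("Pc (vs B_CNE)", "Pnc (vs B_NON_CNE)"),
                   col = c("forestgreen", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}
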