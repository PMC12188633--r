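#' Window specification
#'
#' The window function gathers query intensity in the vicinity of a reference
#' peak position into a single captured value. Two kernels are supported: a
#' rectangular window of full width `sigma` (weight 1 for
#' `|x - xi| <= sigma/2`, boundary inclusive) and a Gaussian window
#' `exp(-(x - xi)^2 / (2 sigma^2))`. The default, a Gaussian with
#' `sigma = 0.5` m/z, is wide enough to absorb sub-unit calibration shifts
#' while keeping neighbouring integer m/z channels nearly separated.
#'
#' @param kind `"gaussian"` or `"rectangular"`.
#' @param sigma Window width in m/z units, > 0.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(kind = c("gaussian", "rectangular"), sigma = 0.5) {
  kind <- match.arg(kind)
  sigma <- as.numeric(sigma)[1L]
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  structure(list(kind = kind, sigma = sigma), class = "window_spec")
}

#' Evaluate a window function
#'
#' @param w A `window_spec`.
#' @param x Query m/z position(s); vectorized.
#' @param xi Reference peak position (scalar or recycled).
#' @return Weight(s) in \[0, 1\].
#' @export
window_weight <- function(w, x, xi) {
  stopifnot(inherits(w, "window_spec"))
  if (w$kind == "rectangular") {
    (abs(x - xi) <= w$sigma / 2) + 0  # keeps dim when x is a matrix
  } else {
    exp(-(x - xi)^2 / (2 * w$sigma^2))
  }
}

#' Reduce a query spectrum onto a reference's peak positions
#'
#' For each reference peak position `x_i`, the captured intensity is
#' `Y_i = dx * sum_k I_k w(x_k | x_i)` for a grid query (rectangle-rule
#' quadrature of the window integral, `dx` the grid spacing) or
#' `Y_i = sum_k I_k w(x_k | x_i)` for a peak-list query. Overlapping windows
#' each capture shared query intensity in full (no deduplication). Captured
#' intensities are then normalized to percent,
#' `ytilde_i = 100 Y_i / sum_j Y_j`, giving the query's intensity
#' distribution on the reference's support.
#'
#' @param query A `grid_spectrum` or `peak_list`.
#' @param ref A `peak_list` of reference peak positions (normalization of the
#'   reference does not affect the reduction).
#' @param w A `window_spec`.
#' @param cutoff For Gaussian windows, evaluate each window only within
#'   `cutoff * sigma` of its centre (`Inf`, the default, evaluates over the
#'   whole query). A cutoff of 8 changes captured intensities by less than
#'   1e-8 relative while making library-scale scans much cheaper.
#' @return An object of class `reduced_spectrum` with fields `raw` (captured
#'   intensities `Y_i`), `normalized` (`ytilde_i`, percent; `NULL` when no
#'   intensity was captured), `total` (`sum Y_j`), and `defined`
#'   (`total > 0`).
#' @export
reduce_query <- function(query, ref, w = window_spec(), cutoff = Inf) {
  stopifnot(inherits(ref, "peak_list"), inherits(w, "window_spec"))
  xr <- ref$mz
  n <- length(xr)
  if (inherits(query, "grid_spectrum")) {
    Iq <- query$intensities
    dx <- grid_dx(query)
    if (w$kind == "gaussian" && is.finite(cutoff)) {
      Y <- dx * gaussian_capture_grid(query$mz_start, dx, Iq, xr,
                                      w$sigma, cutoff)
    } else {
      W <- window_weight(w, outer(grid_mz(query), xr, "-"), 0)
      Y <- dx * colSums(Iq * W)
    }
  } else if (inherits(query, "peak_list")) {
    xq <- query$mz
    Iq <- query$intensity
    if (w$kind == "gaussian" && is.finite(cutoff)) {
      half <- cutoff * w$sigma
      lo <- findInterval(xr - half, xq) + 1L
      hi <- findInterval(xr + half, xq)
      Y <- numeric(n)
      for (i in seq_len(n)) {
        if (lo[i] <= hi[i]) {
          k <- lo[i]:hi[i]
          Y[i] <- sum(Iq[k] * exp(-(xq[k] - xr[i])^2 / (2 * w$sigma^2)))
        }
      }
    } else {
      W <- window_weight(w, outer(xq, xr, "-"), 0)
      Y <- colSums(Iq * W)
    }
  } else {
    stop("'query' must be a grid_spectrum or a peak_list")
  }
  total <- sum(Y)
  structure(list(raw = Y,
                 normalized = if (total > 0) 100 * (Y / total) else NULL,
                 total = total,
                 defined = total > 0),
            class = "reduced_spectrum")
}

# Vectorized Gaussian capture on a uniform grid: for every reference peak,
# sum I_k * w over the grid indices within cutoff*sigma of the peak centre.
gaussian_capture_grid <- function(x0, dx, Iq, xr, sigma, cutoff) {
  m <- length(Iq)
  n <- length(xr)
  half <- cutoff * sigma
  k_half <- ceiling(half / dx)
  ctr <- as.integer(round((xr - x0) / dx))        # 0-based nearest grid index
  idx <- outer(ctr, (-k_half):k_half, "+") + 1L   # n x (2k+1)
  ok <- idx >= 1L & idx <= m
  idxc <- idx
  idxc[idxc < 1L] <- 1L
  idxc[idxc > m] <- m
  xk <- x0 + (idxc - 1L) * dx
  wts <- exp(-(xk - xr)^2 / (2 * sigma^2))        # xr recycles down columns
  wts[!ok | abs(xk - xr) > half] <- 0
  rowSums(array(Iq[idxc], dim = dim(idxc)) * wts)
}

#' @export
print.reduced_spectrum <- function(x, ...) {
  cat(sprintf("Reduced spectrum: %d reference positions, captured total %.6g%s\n",
              length(x$raw), x$total,
              if (x$defined) "" else " (no intensity captured)"))
  invisible(x)
}
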