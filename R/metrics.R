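#' Count reference lines present in the query
#'
#' A reference line counts as present when its reduced normalized intensity
#' exceeds a small threshold `c` (strictly: a value exactly equal to `c` does
#' not count). The fraction `P = N / N(ref)` enters the metametric as a
#' penalty for references whose lines are largely missing from the query.
#'
#' @param reduced A `reduced_spectrum` with defined normalized intensities.
#' @param c Presence threshold on the percent intensities (default `1e-15`,
#'   a numerical floor rather than a physical cut).
#' @return List with `n` (matched line count) and `p` (matched fraction).
#' @export
count_matched_lines <- function(reduced, c = 1e-15) {
  stopifnot(inherits(reduced, "reduced_spectrum"))
  if (is.null(reduced$normalized))
    stop("normalized intensities are undefined (no captured intensity)")
  if (!is.numeric(c) || c <= 0) stop("'c' must be > 0")
  n <- sum(reduced$normalized > c)
  list(n = as.integer(n), p = n / length(reduced$normalized))
}

#' Kullback-Leibler divergence between percent-normalized spectra
#'
#' `D_KL = sum_i q_i * ln(q_i / r_i)` with the convention `0 ln 0 = 0`,
#' where `q` is the reduced query and `r` the reference, both summing to 100.
#' Because the vectors carry the percent scale, the value is in units of
#' percent x nats.
#'
#' @param ref_y Reference intensities (percent), all > 0.
#' @param query_y Reduced query intensities (percent), >= 0, same support.
#' @return Non-negative divergence.
#' @export
kl_divergence <- function(ref_y, query_y) {
  if (length(ref_y) != length(query_y))
    stop("intensity vectors must have the same length")
  if (any(ref_y <= 0))
    stop("reference intensities must be strictly positive")
  pos <- query_y > 0
  sum(query_y[pos] * log(query_y[pos] / ref_y[pos]))
}

#' Bhattacharyya coefficient between percent-normalized spectra
#'
#' `BC = (1/100) * sum_i sqrt(q_i * r_i)`; the factor 1/100 converts from the
#' percent scale to the unit-normalized distributions for which BC is
#' defined. The result is clamped to \[0, 1\] to absorb floating-point
#' overshoot.
#'
#' @inheritParams kl_divergence
#' @return Coefficient in \[0, 1\]; 1 for identical distributions.
#' @export
bhattacharyya_coefficient <- function(ref_y, query_y) {
  if (length(ref_y) != length(query_y))
    stop("intensity vectors must have the same length")
  bc <- sum(sqrt(ref_y * query_y)) / 100
  min(max(bc, 0), 1)
}

#' Bhattacharyya distance
#'
#' `D_B = -ln(BC)`. Undefined (returns `NA`) at `BC = 0`, i.e. disjoint
#' supports; upstream code maps that case to an undefined metric set.
#'
#' @param bc Bhattacharyya coefficient in (0, 1\].
#' @return Non-negative distance, or `NA_real_` when `bc <= 0`.
#' @export
bhattacharyya_distance <- function(bc) {
  if (bc <= 0) return(NA_real_)
  -log(min(bc, 1))
}

#' Hellinger distance
#'
#' `D_H = sqrt(1 - BC)`, bounded in \[0, 1\]. Strictly decreasing in BC, so
#' it always ranks library entries identically to the Bhattacharyya
#' distance.
#'
#' @param bc Bhattacharyya coefficient in \[0, 1\].
#' @return Distance in \[0, 1\].
#' @export
hellinger_distance <- function(bc) {
  sqrt(1 - min(max(bc, 0), 1))
}

#' Cosine distance between intensity vectors
#'
#' `D_C = 1 - <r, q> / (|r| |q|)`, clamped to \[0, 1\].
#'
#' @inheritParams kl_divergence
#' @return Distance in \[0, 1\], or `NA_real_` for a zero-norm query.
#' @export
cosine_distance <- function(ref_y, query_y) {
  if (length(ref_y) != length(query_y))
    stop("intensity vectors must have the same length")
  nr <- sqrt(sum(ref_y^2))
  nq <- sqrt(sum(query_y^2))
  if (nr == 0 || nq == 0) return(NA_real_)
  min(max(1 - sum(ref_y * query_y) / (nr * nq), 0), 1)
}

#' Compute the full metric set for one library entry
#'
#' Bundles the matched-line count/fraction and the four distances between a
#' normalized reference and the reduced query. When the reduction captured no
#' intensity, or no reference line is present above the threshold, the
#' distances are undefined (`defined = FALSE`) -- the interpretation is that
#' the reference species is absent from the query.
#'
#' @param ref A normalized `peak_list` (reference spectrum).
#' @param reduced The `reduced_spectrum` of the query on `ref`'s positions.
#' @param c Presence threshold, see [count_matched_lines()].
#' @return An object of class `metric_set` with fields `n_matched`,
#'   `p_matched`, `bc`, `d_kl`, `d_b`, `d_h`, `d_c`, `total`, `defined`.
#' @export
compute_metric_set <- function(ref, reduced, c = 1e-15) {
  stopifnot(inherits(ref, "peak_list"), inherits(reduced, "reduced_spectrum"))
  undefined <- function(n = 0L, p = 0) {
    structure(list(n_matched = n, p_matched = p, bc = NA_real_,
                   d_kl = NA_real_, d_b = NA_real_, d_h = NA_real_,
                   d_c = NA_real_, total = reduced$total, defined = FALSE),
              class = "metric_set")
  }
  if (!reduced$defined) return(undefined())
  m <- count_matched_lines(reduced, c)
  if (m$n == 0L) return(undefined(m$n, m$p))
  q <- reduced$normalized
  r <- ref$intensity
  bc <- bhattacharyya_coefficient(r, q)
  structure(list(n_matched = m$n,
                 p_matched = m$p,
                 bc = bc,
                 d_kl = kl_divergence(r, q),
                 d_b = bhattacharyya_distance(bc),
                 d_h = hellinger_distance(bc),
                 d_c = cosine_distance(r, q),
                 total = reduced$total,
                 defined = TRUE),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  if (x$defined) {
    cat(sprintf(
      "Metric set: N = %d (P = %.3f), D_KL = %.4f, D_B = %.5f, D_H = %.5f, D_C = %.5f\n",
      x$n_matched, x$p_matched, x$d_kl, x$d_b, x$d_h, x$d_c))
  } else {
    cat("Metric set: undefined (species not present in the query)\n")
  }
  invisible(x)
}
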