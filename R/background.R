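#' Iterative sigma-clipping background removal
#'
#' Strips the noise floor from a profile spectrum under two assumptions: true
#' peaks occupy only a minor part of the m/z range, and the baseline is zero.
#' Starting from the root-mean-square of all intensities about zero
#' (`SD_0 = sqrt(mean(I_k^2))`), the algorithm repeatedly keeps only the
#' values strictly below `q * SD_j` and recomputes the RMS over the survivors.
#' Iteration stops when the surviving set stops shrinking, becomes empty or
#' has zero RMS, or after `p` passes. Finally, every intensity of the
#' original spectrum strictly below the final threshold `q * SD_final` is set
#' to zero; all other values are returned unchanged.
#'
#' @param s A `grid_spectrum`.
#' @param q Selectivity coefficient, >= 1 (default 1.5). Larger values clip
#'   more aggressively.
#' @param p Maximum number of clipping iterations, >= 1 (default 3).
#' @return List with `cleaned` (the thresholded `grid_spectrum`) and
#'   `threshold` (the final intensity threshold `q * SD_final`).
#' @export
remove_background <- function(s, q = 1.5, p = 3) {
  stopifnot(inherits(s, "grid_spectrum"))
  if (!is.numeric(q) || q < 1) stop("'q' must be >= 1")
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("'p' must be >= 1")
  I <- s$intensities
  cur <- I
  sd_j <- sqrt(mean(cur^2))
  for (j in seq_len(p)) {
    if (sd_j == 0) break
    nxt <- cur[cur < q * sd_j]
    if (length(nxt) == length(cur)) break  # set size constant: converged
    cur <- nxt
    sd_j <- if (length(cur)) sqrt(mean(cur^2)) else 0
  }
  threshold <- q * sd_j
  out <- I
  out[out < threshold] <- 0
  s$intensities <- out
  list(cleaned = s, threshold = threshold)
}
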