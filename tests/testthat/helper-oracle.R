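# Straight-line reference implementation of the whole scoring pipeline
# (reduction -> metrics -> spreads -> metametric), written with plain loops
# and independent of the package internals. Used to cross-check the
# production code on small instances.
#
# query_x / query_I: the query points; is_grid switches between quadrature
# (with grid spacing factor) and plain summation. refs: list of
# list(mz=, int=) with int normalized to 100.

naive_window <- function(x, xi, kind, sigma) {
  if (kind == "rectangular") {
    if (abs(x - xi) <= sigma / 2) 1 else 0
  } else {
    exp(-(x - xi)^2 / (2 * sigma^2))
  }
}

naive_pipeline <- function(query_x, query_I, is_grid, refs,
                           kind = "gaussian", sigma = 0.5, cthr = 1e-15) {
  dxq <- if (is_grid) {
    (query_x[length(query_x)] - query_x[1]) / (length(query_x) - 1)
  } else 1
  per <- lapply(refs, function(ref) {
    n_ref <- length(ref$mz)
    Y <- numeric(n_ref)
    for (i in seq_len(n_ref)) {
      acc <- 0
      for (k in seq_along(query_x))
        acc <- acc + query_I[k] * naive_window(query_x[k], ref$mz[i], kind, sigma)
      Y[i] <- dxq * acc
    }
    tot <- sum(Y)
    if (tot <= 0) return(list(defined = FALSE, total = tot))
    yt <- 100 * Y / tot
    n_match <- 0
    for (i in seq_len(n_ref)) if (yt[i] > cthr) n_match <- n_match + 1
    if (n_match == 0) return(list(defined = FALSE, total = tot))
    d_kl <- 0
    for (i in seq_len(n_ref))
      if (yt[i] > 0) d_kl <- d_kl + yt[i] * log(yt[i] / ref$int[i])
    bc <- 0
    for (i in seq_len(n_ref)) bc <- bc + sqrt(yt[i] * ref$int[i])
    bc <- bc / 100
    d_c <- 1 - sum(ref$int * yt) / sqrt(sum(ref$int^2) * sum(yt^2))
    list(defined = TRUE, total = tot, p = n_match / n_ref,
         d_kl = d_kl, d_b = -log(bc), d_h = sqrt(1 - bc), d_c = d_c)
  })
  def <- Filter(function(m) m$defined, per)
  pop_sd <- function(v) sqrt(mean(v^2) - mean(v)^2)
  s_kl <- pop_sd(sapply(def, `[[`, "d_kl"))
  s_b <- pop_sd(sapply(def, `[[`, "d_b"))
  s_h <- pop_sd(sapply(def, `[[`, "d_h"))
  s_c <- pop_sd(sapply(def, `[[`, "d_c"))
  vapply(per, function(m) {
    if (!m$defined) return(Inf)
    (m$d_kl / s_kl + m$d_b / s_b + m$d_h / s_h + m$d_c / s_c) /
      (m$p * m$total)
  }, 0)
}
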