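#' Database-wide metric spreads
#'
#' The four distances live on incomparable scales, so before fusing them each
#' is divided by its spread across the library for the query at hand: the
#' population standard deviation `sqrt(<D^2> - <D>^2)` of the metric over all
#' entries with a defined metric set. Spreads are recomputed per query.
#'
#' @param metric_sets List of `metric_set` objects, one per library entry.
#' @return An object of class `spread_set` with fields `s_kl`, `s_b`, `s_h`,
#'   `s_c` and `n_defined`.
#' @export
compute_spreads <- function(metric_sets) {
  def <- Filter(function(m) isTRUE(m$defined), metric_sets)
  if (length(def) < 2L)
    stop("need at least two library entries with defined metrics to compute spreads")
  pop_sd <- function(field) {
    v <- vapply(def, `[[`, 0, field)
    sqrt(max(mean(v^2) - mean(v)^2, 0))
  }
  s <- structure(list(s_kl = pop_sd("d_kl"), s_b = pop_sd("d_b"),
                      s_h = pop_sd("d_h"), s_c = pop_sd("d_c"),
                      n_defined = length(def)),
                 class = "spread_set")
  if (any(unlist(s[1:4]) == 0))
    warning("one or more metric spreads are zero (degenerate library); the affected terms are skipped in the metametric")
  s
}

#' Metametric score for one library entry
#'
#' The combined dissimilarity
#' `D_meta = (1 / (P * sum_j Y_j)) * (D_KL/s_KL + D_B/s_B + D_H/s_H + D_C/s_C)`
#' where `P` is the matched-line fraction and `sum Y_j` the total captured
#' intensity. It tends to zero for a reference similar to the query and grows
#' with dissimilarity. Entries whose metric set is undefined (species absent)
#' score `+Inf` and therefore rank last. A term whose spread is zero
#' (degenerate library) is skipped.
#'
#' @param m A `metric_set`.
#' @param s A `spread_set`.
#' @param total Total captured intensity `sum Y_j` for the entry; defaults to
#'   the value stored in `m`.
#' @return Non-negative score, or `Inf` when undefined.
#' @export
metametric_score <- function(m, s, total = m$total) {
  stopifnot(inherits(m, "metric_set"), inherits(s, "spread_set"))
  if (!isTRUE(m$defined) || !is.finite(total) || total <= 0 ||
      m$p_matched <= 0)
    return(Inf)
  term <- function(d, sig) if (sig > 0) d / sig else 0
  num <- term(m$d_kl, s$s_kl) + term(m$d_b, s$s_b) +
    term(m$d_h, s$s_h) + term(m$d_c, s$s_c)
  num / (m$p_matched * total)
}

# Score a query against every entry: reductions, metric sets, spreads,
# metametric. Returns the unsorted per-entry table used by ranking and by the
# benchmark.
score_against_database <- function(query, db, w = window_spec(),
                                   c = 1e-15, cutoff = Inf) {
  stopifnot(inherits(db, "ms_database"))
  reds <- lapply(db$entries, function(e) reduce_query(query, e$peaks, w, cutoff))
  mets <- mapply(function(e, r) compute_metric_set(e$peaks, r, c),
                 db$entries, reds, SIMPLIFY = FALSE)
  spreads <- compute_spreads(mets)
  d_meta <- vapply(mets, metametric_score, 0, s = spreads)
  num <- function(field) vapply(mets, `[[`, 0, field)
  tab <- data.frame(
    id = vapply(db$entries, `[[`, "", "id"),
    class = vapply(db$entries, `[[`, "", "class_label"),
    formula = vapply(db$entries, `[[`, "", "formula"),
    name = vapply(db$entries, `[[`, "", "name"),
    n_matched = vapply(mets, function(m) as.integer(m$n_matched), 0L),
    p_matched = num("p_matched"),
    total = num("total"),
    d_kl = num("d_kl"),
    d_b = num("d_b"),
    d_h = num("d_h"),
    d_c = num("d_c"),
    d_meta = d_meta,
    stringsAsFactors = FALSE)
  attr(tab, "spreads") <- spreads
  tab
}

#' Rank all library entries against a query spectrum
#'
#' Runs the full matching pipeline for one query: reduce the query onto every
#' entry's peak positions, compute the metric set per entry, derive the
#' database-wide spreads, score every entry with the metametric, and sort
#' ascending by score. Ties are broken lexicographically (byte-wise) by entry
#' id so that the ranking is fully reproducible; undefined entries carry
#' `D_meta = Inf` and always rank after all defined entries.
#'
#' @param query A `grid_spectrum` or `peak_list`.
#' @param db An `ms_database`.
#' @param w A `window_spec` (default Gaussian, sigma 0.5).
#' @param c Presence threshold, see [count_matched_lines()].
#' @param cutoff Gaussian window evaluation cutoff in sigmas, see
#'   [reduce_query()].
#' @return A data frame sorted by `d_meta` with columns `rank`, `id`,
#'   `class`, `formula`, `name`, `n_matched`, `p_matched`, `total`, `d_kl`,
#'   `d_b`, `d_h`, `d_c`, `d_meta` (distances are `NA` for undefined
#'   entries). The per-metric spreads are attached as attribute `"spreads"`.
#' @export
rank_against_database <- function(query, db, w = window_spec(),
                                  c = 1e-15, cutoff = Inf) {
  tab <- score_against_database(query, db, w, c, cutoff)
  ord <- order(tab$d_meta, tab$id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

# 1-based rank of entry `true_id` in score table `tab` when entries are
# ordered by column `criterion` (NA/undefined last), ties broken byte-wise by
# id -- the same ordering contract as rank_against_database().
rank_of_entry <- function(tab, true_id, criterion = "d_meta") {
  v <- tab[[criterion]]
  v[is.na(v)] <- Inf
  o <- order(v, tab$id, method = "radix")
  match(true_id, tab$id[o])
}
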