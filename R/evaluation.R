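#' Retrieval scores for a set of identification trials
#'
#' Given the 1-based rank of the true compound in each trial, computes:
#' top-K accuracy (percentage of trials with the true compound among the best
#' K candidates), mean reciprocal rank (`MRR = 100/Ntrials * sum 1/R_i`, in
#' percent), and mean rank (`MR = mean(R_i)`, >= 1). An ideal identifier
#' scores 100 percent top-1 and MRR, and MR = 1.
#'
#' @param ranks Integer vector of true-compound ranks, all >= 1.
#' @param ks K values for the top-K accuracies (default 1, 3, 5, 10).
#' @return An object of class `rank_scores`: list with `top_k` (named
#'   percentage vector), `mrr`, `mr`, and `n_trials`.
#' @export
score_ranks <- function(ranks, ks = c(1, 3, 5, 10)) {
  ranks <- as.numeric(ranks)
  if (!length(ranks)) stop("'ranks' must contain at least one trial")
  if (any(!is.finite(ranks)) || any(ranks < 1))
    stop("ranks must be finite and >= 1")
  ks <- sort(unique(as.integer(ks)))
  top_k <- vapply(ks, function(k) 100 * mean(ranks <= k), 0)
  names(top_k) <- paste0("top", ks)
  structure(list(top_k = top_k,
                 mrr = 100 * mean(1 / ranks),
                 mr = mean(ranks),
                 n_trials = length(ranks)),
            class = "rank_scores")
}

#' @export
print.rank_scores <- function(x, ...) {
  cat(sprintf("Retrieval scores over %d trials:\n", x$n_trials))
  for (nm in names(x$top_k))
    cat(sprintf("  %-6s %6.2f %%\n", nm, x$top_k[[nm]]))
  cat(sprintf("  %-6s %6.2f %%\n", "MRR", x$mrr))
  cat(sprintf("  %-6s %6.3f\n", "MR", x$mr))
  invisible(x)
}
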