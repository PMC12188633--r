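#' Monte-Carlo identification benchmark
#'
#' Repeats the full identification pipeline on synthetic noisy mixtures: per
#' trial a target species is drawn uniformly from the library, a mixture
#' query is synthesized ([synthesize_query()]), background-removed
#' ([remove_background()]), and ranked against the library. The rank of the
#' true species is recorded under the metametric and, independently, under
#' each single distance, and each repeat is scored with [score_ranks()].
#' Repeat r seeds R's random stream with `cfg$seed + r - 1`, so a result is
#' fully determined by (seed, configuration, library).
#'
#' @param db An `ms_database` (must resolve the background species).
#' @param cfg A `simulation_config`.
#' @param criteria Ranking criteria to score; any of `"d_meta"`, `"d_kl"`,
#'   `"d_b"`, `"d_h"`, `"d_c"`.
#' @param w A `window_spec` used in the reduction.
#' @param c Presence threshold.
#' @param cutoff Gaussian evaluation cutoff in sigmas (default 8; see
#'   [reduce_query()]).
#' @param clean Run background removal on each query before ranking
#'   (default `TRUE`, as in the production pipeline).
#' @param q,p Background-removal parameters.
#' @param ks K values for the top-K accuracies.
#' @param backgrounds Optional background peak-list overrides, see
#'   [synthesize_query()].
#' @return An object of class `benchmark_result`: list with `per_repeat`
#'   (data frame: repeat, criterion, one column per score), `summary` (data
#'   frame: criterion, score, mean, sd across repeats), `ranks` (matrix of
#'   all trial ranks per criterion), and `config`.
#' @export
run_benchmark <- function(db, cfg,
                          criteria = c("d_meta", "d_kl", "d_b", "d_h", "d_c"),
                          w = window_spec(), c = 1e-15, cutoff = 8,
                          clean = TRUE, q = 1.5, p = 3,
                          ks = c(1, 3, 5, 10), backgrounds = NULL) {
  stopifnot(inherits(db, "ms_database"), inherits(cfg, "simulation_config"))
  criteria <- match.arg(criteria, several.ok = TRUE)
  n_entries <- length(db$entries)
  ids <- db_ids(db)
  per_repeat <- list()
  all_ranks <- matrix(NA_integer_,
                      nrow = cfg$n_repeats * cfg$n_trials,
                      ncol = length(criteria),
                      dimnames = list(NULL, criteria))
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(cfg$seed + r - 1L)
    ranks <- matrix(NA_integer_, nrow = cfg$n_trials, ncol = length(criteria),
                    dimnames = list(NULL, criteria))
    for (t in seq_len(cfg$n_trials)) {
      ti <- sample.int(n_entries, 1L)
      qry <- synthesize_query(db, db$entries[[ti]], cfg, backgrounds)
      if (clean) qry <- remove_background(qry, q = q, p = p)$cleaned
      tab <- score_against_database(qry, db, w, c, cutoff)
      for (cr in criteria)
        ranks[t, cr] <- rank_of_entry(tab, ids[ti], cr)
    }
    all_ranks[(r - 1L) * cfg$n_trials + seq_len(cfg$n_trials), ] <- ranks
    for (cr in criteria) {
      sc <- score_ranks(ranks[, cr], ks = ks)
      per_repeat[[length(per_repeat) + 1L]] <-
        data.frame(rep = r, criterion = cr, as.list(sc$top_k),
                   mrr = sc$mrr, mr = sc$mr, stringsAsFactors = FALSE)
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  score_cols <- setdiff(names(per_repeat), c("rep", "criterion"))
  summary <- do.call(rbind, lapply(criteria, function(cr) {
    sub <- per_repeat[per_repeat$criterion == cr, score_cols, drop = FALSE]
    data.frame(criterion = cr, score = score_cols,
               mean = vapply(sub, mean, 0),
               sd = vapply(sub, stats::sd, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(per_repeat = per_repeat, summary = summary,
                 ranks = all_ranks, config = cfg),
            class = "benchmark_result")
}

#' Mean of one benchmark score for one criterion
#'
#' Convenience accessor for `benchmark_result$summary`.
#'
#' @param bench A `benchmark_result`.
#' @param criterion Ranking criterion, e.g. `"d_meta"`.
#' @param score Score name, e.g. `"top1"`, `"mrr"`, `"mr"`.
#' @return The mean of the score across repeats.
#' @export
benchmark_mean <- function(bench, criterion, score) {
  stopifnot(inherits(bench, "benchmark_result"))
  s <- bench$summary
  v <- s$mean[s$criterion == criterion & s$score == score]
  if (!length(v)) stop(sprintf("no score '%s' for criterion '%s'", score, criterion))
  v
}

#' @export
print.benchmark_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Identification benchmark: %d repeats x %d trials (S/N %g-%g, intensity jitter +/-%g%%, m/z jitter +/-%g)\n",
    cfg$n_repeats, cfg$n_trials, cfg$snr_range[1], cfg$snr_range[2],
    100 * cfg$intensity_jitter, cfg$mz_jitter))
  wide <- stats::reshape(x$summary, idvar = "criterion", timevar = "score",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  keep <- !grepl("^sd\\.", names(wide))
  print(format(wide[, keep, drop = FALSE], digits = 3), row.names = FALSE)
  cat("(mean over repeats; top-K and MRR in %, MR is a mean rank)\n")
  invisible(x)
}
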