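#' Simulation configuration for synthetic noisy mixtures
#'
#' Describes how synthetic query spectra are generated for the Monte-Carlo
#' identification benchmark: the target species' peak list is rendered as
#' Gaussian-shaped peaks on a uniform m/z grid, mixed with renderings of five
#' ubiquitous background species, and buried under additive uniform noise.
#'
#' Two standard condition sets are used. The *basic* conditions (the
#' defaults) draw the signal-to-noise ratio uniformly from 100-1000 with no
#' peak jitter. The *extended* conditions ([extended_noise_config()]) lower
#' S/N to 5-100 and additionally jitter every peak's intensity by +/-50
#' percent and its position by +/-0.2 m/z.
#'
#' @param mz_min,mz_max m/z bounds of the rendering grid (default 0-500).
#' @param n_points Number of grid points (default 2000).
#' @param peak_sigma_range Bounds for the per-peak Gaussian width, drawn
#'   uniformly per peak (default 0.05-0.1 m/z).
#' @param background_names Names of the five background species; each must
#'   resolve to a library entry by name (or be supplied as an override peak
#'   list).
#' @param background_amount_range Bounds for the relative amount of each
#'   background species (default 0.1-0.2); the amount scales the background's
#'   rendered base peak relative to the target's rendered base peak.
#' @param snr_range Bounds for the per-trial signal-to-noise ratio. S/N is
#'   defined as (maximum rendered signal)/(noise amplitude upper bound), with
#'   noise drawn per grid point from `U(0, max(signal)/SN)`. Non-finite
#'   bounds disable noise.
#' @param intensity_jitter Relative half-width of the per-peak intensity
#'   jitter (0.5 = +/-50 percent; default 0).
#' @param mz_jitter Half-width of the per-peak position jitter in m/z
#'   (default 0).
#' @param n_trials Queries per benchmark repeat (default 500).
#' @param n_repeats Benchmark repeats (default 48).
#' @param seed Base random seed for the benchmark; repeat r uses
#'   `seed + r - 1`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mz_min = 0, mz_max = 500, n_points = 2000,
                              peak_sigma_range = c(0.05, 0.1),
                              background_names = c("benzene", "oxygen",
                                                   "nitrogen",
                                                   "carbon_dioxide",
                                                   "farnesene"),
                              background_amount_range = c(0.1, 0.2),
                              snr_range = c(100, 1000),
                              intensity_jitter = 0, mz_jitter = 0,
                              n_trials = 500, n_repeats = 48, seed = 1L) {
  stopifnot(mz_max > mz_min, n_points >= 2,
            length(peak_sigma_range) == 2L,
            peak_sigma_range[1] > 0,
            peak_sigma_range[1] <= peak_sigma_range[2],
            length(background_amount_range) == 2L,
            background_amount_range[1] >= 0,
            background_amount_range[1] <= background_amount_range[2],
            length(snr_range) == 2L, snr_range[1] <= snr_range[2],
            intensity_jitter >= 0, intensity_jitter < 1, mz_jitter >= 0,
            n_trials >= 1, n_repeats >= 1)
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 n_points = as.integer(n_points),
                 peak_sigma_range = as.numeric(peak_sigma_range),
                 background_names = as.character(background_names),
                 background_amount_range = as.numeric(background_amount_range),
                 snr_range = as.numeric(snr_range),
                 intensity_jitter = intensity_jitter,
                 mz_jitter = mz_jitter,
                 n_trials = as.integer(n_trials),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Extended-noise simulation conditions
#'
#' The harder benchmark conditions: S/N drawn from 5-100, peak intensities
#' jittered by +/-50 percent, and peak positions shifted by +/-0.2 m/z.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
extended_noise_config <- function(...) {
  simulation_config(snr_range = c(5, 100), intensity_jitter = 0.5,
                    mz_jitter = 0.2, ...)
}

#' Render a peak list as a Gaussian-peak profile spectrum
#'
#' Each peak contributes `a_i * exp(-(x - x_i')^2 / (2 s_i^2))` on the grid,
#' with the width `s_i` drawn uniformly from `cfg$peak_sigma_range` per peak.
#' With `jitter = TRUE`, the centre is shifted by `U(-mz_jitter, +mz_jitter)`
#' and the amplitude scaled by `1 + U(-intensity_jitter, +intensity_jitter)`.
#' Peaks near the grid edge contribute their in-range tail. Uses R's global
#' random stream; rendering is fully determined by the stream state.
#'
#' @param pl A `peak_list` (normalized or not; amplitudes follow its scale).
#' @param cfg A `simulation_config`.
#' @param jitter Apply position/intensity jitter? (default `TRUE`; with the
#'   basic conditions the jitter amplitudes are 0, so this is a no-op there).
#' @return A `grid_spectrum`.
#' @export
render_spectrum <- function(pl, cfg, jitter = TRUE) {
  stopifnot(inherits(pl, "peak_list"), inherits(cfg, "simulation_config"))
  n <- length(pl$mz)
  sig <- stats::runif(n, cfg$peak_sigma_range[1], cfg$peak_sigma_range[2])
  ctr <- pl$mz
  amp <- pl$intensity
  if (jitter) {
    ctr <- ctr + stats::runif(n, -cfg$mz_jitter, cfg$mz_jitter)
    amp <- amp * (1 + stats::runif(n, -cfg$intensity_jitter,
                                   cfg$intensity_jitter))
  }
  x <- seq(cfg$mz_min, cfg$mz_max, length.out = cfg$n_points)
  d2 <- outer(x, ctr, "-")^2
  vals <- as.vector(exp(sweep(d2, 2L, -2 * sig^2, "/")) %*% amp)
  grid_spectrum(cfg$mz_min, cfg$mz_max, pmax(vals, 0), label = pl$label)
}

# Resolve the configured background species to peak lists, by entry name in
# the library or from the `backgrounds` override list.
resolve_backgrounds <- function(db, cfg, backgrounds = NULL) {
  names_in_db <- vapply(db$entries, `[[`, "", "name")
  lapply(cfg$background_names, function(nm) {
    if (!is.null(backgrounds) && !is.null(backgrounds[[nm]])) {
      bl <- backgrounds[[nm]]
      stopifnot(inherits(bl, "peak_list"))
      return(bl)
    }
    hit <- which(names_in_db == nm)
    if (!length(hit))
      stop(sprintf(
        "background species '%s' not found in the library and no override supplied",
        nm))
    db$entries[[hit[1L]]]$peaks
  })
}

#' Synthesize a noisy mixture query for one target species
#'
#' Renders the target, adds the five background species (each rendered the
#' same way, rescaled so its base peak equals a random fraction
#' `U(background_amount_range)` of the target's base peak), then adds uniform
#' noise `U(0, max(mixture)/SN)` per grid point with
#' `SN ~ U(snr_range)`.
#'
#' @param db An `ms_database` resolving the background species.
#' @param true_entry The `database_entry` of the target species.
#' @param cfg A `simulation_config`.
#' @param backgrounds Optional named list of `peak_list` overrides for
#'   background species missing from the library.
#' @return A `grid_spectrum`.
#' @export
synthesize_query <- function(db, true_entry, cfg, backgrounds = NULL) {
  stopifnot(inherits(db, "ms_database"), inherits(true_entry, "database_entry"),
            inherits(cfg, "simulation_config"))
  bg <- resolve_backgrounds(db, cfg, backgrounds)
  target <- render_spectrum(true_entry$peaks, cfg, jitter = TRUE)
  vals <- target$intensities
  tmax <- max(vals)
  for (b in bg) {
    amount <- stats::runif(1, cfg$background_amount_range[1],
                           cfg$background_amount_range[2])
    bv <- render_spectrum(b, cfg, jitter = TRUE)$intensities
    bmax <- max(bv)
    if (bmax > 0 && amount > 0) vals <- vals + (amount * tmax / bmax) * bv
  }
  if (all(is.finite(cfg$snr_range))) {
    sn <- stats::runif(1, cfg$snr_range[1], cfg$snr_range[2])
    vals <- vals + stats::runif(length(vals), 0, max(vals) / sn)
  }
  grid_spectrum(cfg$mz_min, cfg$mz_max, vals,
                label = paste0("mixture:", true_entry$id))
}

#' Class layout of a realistic chemical-threat spectral library
#'
#' Per-class entry counts typical of a curated library of chemical-warfare
#' agents, explosives, and environmental pollutants (400 entries across 17
#' classes). Useful for generating a library-scale synthetic database with
#' [make_fixture_database()].
#'
#' @return Named integer vector of entries per class; sums to 400.
#' @export
reference_library_layout <- function() {
  c(AcidContaminants = 9L, Bisphenols = 3L, BlisterAgents = 15L,
    BloodAgents = 6L, Chlorophenols = 7L, ChokingAgents = 9L,
    Dioxines = 15L, Explosives = 59L, Herbicides = 7L, Lachrymators = 5L,
    Miscellaneous = 169L, NerveAgents = 43L, PAHs = 16L, PCBs = 2L,
    Pesticydes = 31L, PFASs = 2L, Phthalates = 2L)
}

# Synthetic stand-ins for the five background species: (formula, name,
# maximum fragment m/z). Peak patterns are generated randomly; only the
# names/formulas and rough mass ranges mimic the real species.
background_species_specs <- function() {
  list(list(formula = "C6H6", name = "benzene", mmax = 78L),
       list(formula = "O2", name = "oxygen", mmax = 32L),
       list(formula = "N2", name = "nitrogen", mmax = 28L),
       list(formula = "CO2", name = "carbon_dioxide", mmax = 44L),
       list(formula = "C15H24", name = "farnesene", mmax = 204L))
}

random_fixture_peaks <- function(n_peaks, mz_lo, mz_hi, label = "") {
  mz <- sort(sample(mz_lo:mz_hi, n_peaks))
  intensity <- 10^stats::runif(n_peaks, -1, 2)  # log-uniform over 3 decades
  normalize_intensities(peak_list(mz, intensity, label = label))
}

#' Generate a synthetic fixture library
#'
#' Builds a fully synthetic spectral library for testing and benchmarking:
#' each entry gets 5-40 peaks at integer m/z in 20-450 with log-uniform
#' intensities (normalized to 100 percent), plus synthetic stand-ins named
#' for the five benchmark background species (benzene, oxygen, nitrogen,
#' carbon dioxide, farnesene) with peaks confined below each species'
#' molecular mass. All spectra are random; only names, formulas, and mass
#' ranges mimic real compounds.
#'
#' @param n_entries Total entries including the 5 background stand-ins,
#'   >= 6. Ignored when `class_layout` is given.
#' @param seed Optional seed for reproducibility (`set.seed` is called when
#'   non-`NULL`).
#' @param class_layout Optional named integer vector of entries per class
#'   (e.g. [reference_library_layout()]); its sum defines the library size.
#'   The 5 background stand-ins are placed inside the largest class.
#' @param dir Optional path: when given, the library is also written in the
#'   on-disk layout via [write_database()].
#' @return An `ms_database`.
#' @export
make_fixture_database <- function(n_entries = 50, seed = NULL,
                                  class_layout = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bg_specs <- background_species_specs()
  n_bg <- length(bg_specs)
  if (is.null(class_layout)) {
    n_entries <- as.integer(n_entries)
    if (n_entries < n_bg + 1L)
      stop(sprintf("need at least %d entries (%d background species + 1 target)",
                   n_bg + 1L, n_bg))
    classes <- rep("Synthetic", n_entries - n_bg)
    bg_class <- "Background"
  } else {
    stopifnot(!is.null(names(class_layout)), all(class_layout >= 0))
    bg_class <- names(class_layout)[which.max(class_layout)]
    if (class_layout[[bg_class]] < n_bg)
      stop("largest class must hold the 5 background stand-ins")
    counts <- class_layout
    counts[bg_class] <- counts[bg_class] - n_bg
    classes <- rep(names(counts), counts)
    n_entries <- sum(class_layout)
  }
  entries <- vector("list", n_entries)
  for (i in seq_along(bg_specs)) {
    sp <- bg_specs[[i]]
    pl <- random_fixture_peaks(sample(3:10, 1L), 12L, sp$mmax, sp$name)
    entries[[i]] <- database_entry(bg_class, sp$formula, sp$name, pl,
                                   info = "synthetic stand-in spectrum")
  }
  for (j in seq_along(classes)) {
    name <- sprintf("substance%04d", j)
    formula <- sprintf("C%dH%d", sample(3:30, 1L), sample(4:40, 1L))
    pl <- random_fixture_peaks(sample(5:40, 1L), 20L, 450L, name)
    entries[[n_bg + j]] <- database_entry(classes[j], formula, name, pl,
                                          info = "synthetic spectrum")
  }
  db <- ms_database(entries)
  if (!is.null(dir)) write_database(db, dir)
  db
}
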