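test_that("rendering is deterministic given the random stream state", {
  cfg <- simulation_config()
  pl <- normalize_intensities(peak_list(c(100, 150), c(3, 1)))
  set.seed(61)
  g1 <- render_spectrum(pl, cfg)
  set.seed(61)
  g2 <- render_spectrum(pl, cfg)
  expect_identical(g1$intensities, g2$intensities)
})

test_that("a rendered peak tops out at the grid point nearest its position", {
  cfg <- simulation_config()
  pl <- peak_list(100, 100)
  set.seed(62)
  g <- render_spectrum(pl, cfg, jitter = FALSE)
  x <- grid_mz(g)
  expect_equal(which.max(g$intensities), which.min(abs(x - 100)))
})

test_that("intensity jitter stays within its +/-50 percent bounds", {
  # 2001 points over 0-500 puts a grid point exactly at m/z 250, so with no
  # position jitter the grid maximum equals the jittered amplitude
  cfg <- simulation_config(n_points = 2001, intensity_jitter = 0.5)
  pl <- peak_list(250, 100)
  set.seed(63)
  for (i in 1:50) {
    g <- render_spectrum(pl, cfg, jitter = TRUE)
    m <- max(g$intensities)
    expect_gte(m, 50)
    expect_lte(m, 150)
  }
})

test_that("synthetic mixtures respect the background amount and S/N construction", {
  set.seed(64)
  db <- make_fixture_database(12, seed = 64)
  target <- db$entries[[match("Synthetic", vapply(db$entries, `[[`, "",
                                                  "class_label"))]]
  # degenerate config: no backgrounds, no noise -> pure target rendering
  cfg0 <- simulation_config(background_amount_range = c(0, 0),
                            snr_range = c(Inf, Inf))
  set.seed(65)
  q0 <- synthesize_query(db, target, cfg0)
  set.seed(65)
  r0 <- render_spectrum(target$peaks, cfg0, jitter = TRUE)
  expect_equal(q0$intensities, r0$intensities, tolerance = 1e-12)

  # with backgrounds at amount a, each background's base peak is a * target's
  cfg1 <- simulation_config(background_amount_range = c(0.2, 0.2),
                            snr_range = c(Inf, Inf))
  set.seed(66)
  q1 <- synthesize_query(db, target, cfg1)
  set.seed(66)
  t1 <- render_spectrum(target$peaks, cfg1, jitter = TRUE)
  expect_gte(max(q1$intensities), max(t1$intensities))
  # total added background is bounded by 5 species x 0.2 x target base peak each
  expect_lte(max(q1$intensities - t1$intensities),
             5 * 0.2 * max(t1$intensities) + 1e-9)

  # same seed reproduces the same trial bitwise
  set.seed(67)
  qa <- synthesize_query(db, target, extended_noise_config())
  set.seed(67)
  qb <- synthesize_query(db, target, extended_noise_config())
  expect_identical(qa$intensities, qb$intensities)

  # unresolvable background species is a configuration error
  cfg_bad <- simulation_config(background_names = c("unobtainium"))
  expect_error(synthesize_query(db, target, cfg_bad), "unobtainium")
})

test_that("fixture library generation is reproducible, normalized, and round-trips", {
  d1 <- make_fixture_database(20, seed = 68)
  d2 <- make_fixture_database(20, seed = 68)
  expect_identical(db_ids(d1), db_ids(d2))
  expect_identical(d1$entries[[7]]$peaks$intensity,
                   d2$entries[[7]]$peaks$intensity)
  expect_equal(length(d1), 20)
  for (e in d1$entries)
    expect_equal(sum(e$peaks$intensity), 100, tolerance = 1e-9)
  # all five background species resolvable by name
  nms <- vapply(d1$entries, `[[`, "", "name")
  expect_true(all(c("benzene", "oxygen", "nitrogen", "carbon_dioxide",
                    "farnesene") %in% nms))
  # directory round-trip
  root <- withr::local_tempdir()
  write_database(d1, root)
  expect_identical(db_ids(load_database(root)), db_ids(d1))
})

test_that("a class layout controls library size and per-class counts", {
  layout <- c(Alpha = 3L, Beta = 8L, Gamma = 2L)
  db <- make_fixture_database(seed = 69, class_layout = layout)
  expect_equal(length(db), 13)
  counts <- db_class_counts(db)
  expect_equal(counts$n[match(names(layout), counts$class)],
               unname(layout))
})

test_that("benchmark under perfect conditions scores 100 percent top-1 for every criterion", {
  # noise, backgrounds, and jitter disabled, and a fixed peak width: a
  # uniform width cancels in the percent normalization, so the reduced query
  # reproduces the reference distribution exactly
  db <- make_fixture_database(12, seed = 70)
  cfg <- simulation_config(background_amount_range = c(0, 0),
                           snr_range = c(Inf, Inf),
                           peak_sigma_range = c(0.08, 0.08),
                           n_trials = 8, n_repeats = 1, seed = 71)
  b <- run_benchmark(db, cfg)
  for (cr in c("d_meta", "d_kl", "d_b", "d_h")) {
    expect_equal(benchmark_mean(b, cr, "top1"), 100)
    expect_equal(benchmark_mean(b, cr, "mr"), 1)
  }
  # cosine is excluded: entries sharing the query's dominant fragment are
  # cosine-indistinguishable even without noise, so its top-1 need not be
  # perfect -- it must however never beat the metametric
  expect_lte(benchmark_mean(b, "d_c", "top1"),
             benchmark_mean(b, "d_meta", "top1"))
})

test_that("benchmark is deterministic and scores Bhattacharyya and Hellinger identically", {
  db <- make_fixture_database(10, seed = 72)
  cfg <- extended_noise_config(n_trials = 10, n_repeats = 2, seed = 73)
  b1 <- run_benchmark(db, cfg)
  b2 <- run_benchmark(db, cfg)
  expect_identical(b1$ranks, b2$ranks)
  expect_identical(b1$ranks[, "d_b"], b1$ranks[, "d_h"])
  expect_equal(b1$summary[b1$summary$criterion == "d_b", c("mean", "sd")],
               b1$summary[b1$summary$criterion == "d_h", c("mean", "sd")],
               ignore_attr = TRUE)
})
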