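metric_stub <- function(d_kl, d_b, d_h, d_c, p = 1, total = 1, defined = TRUE) {
  structure(list(n_matched = if (defined) 1L else 0L, p_matched = p,
                 bc = NA_real_, d_kl = d_kl, d_b = d_b, d_h = d_h, d_c = d_c,
                 total = total, defined = defined),
            class = "metric_set")
}

test_that("spreads are population standard deviations over defined entries", {
  ms <- lapply(c(1, 1, 1), function(v) metric_stub(v, v, v, v))
  expect_warning(s <- compute_spreads(ms), "zero")  # constant metric: zero spread
  expect_equal(s$s_kl, 0)

  ms <- lapply(c(0, 2), function(v) metric_stub(v, v, v, v))
  s <- compute_spreads(ms)
  expect_equal(s$s_b, 1)

  vals <- c(75 * log(1.5) + 25 * log(0.5), 100 * log(2), 0)
  ms <- lapply(vals, function(v) metric_stub(v, 1, 1, 1))
  expect_warning(s <- compute_spreads(ms), "zero")  # the three constant metrics
  expect_equal(s$s_kl, sqrt(mean(vals^2) - mean(vals)^2), tolerance = 1e-12)

  # undefined entries are excluded; fewer than two defined entries aborts
  ms <- c(lapply(c(0, 2), function(v) metric_stub(v, v, v, v)),
          list(metric_stub(99, 99, 99, 99, defined = FALSE)))
  s2 <- compute_spreads(ms)
  expect_equal(s2$s_kl, 1)
  expect_equal(s2$n_defined, 2L)
  expect_error(compute_spreads(list(metric_stub(1, 1, 1, 1))),
               "at least two")
})

test_that("the metametric combines spread-scaled distances with the 1/(P * total) factor", {
  s <- structure(list(s_kl = 2, s_b = 0.5, s_h = 0.25, s_c = 0.1,
                      n_defined = 3L), class = "spread_set")
  m <- metric_stub(4, 1, 0.5, 0.05, p = 1, total = 2)
  expect_equal(metametric_score(m, s), (4/2 + 1/0.5 + 0.5/0.25 + 0.05/0.1) / 2)
  # halving P doubles the score
  m2 <- metric_stub(4, 1, 0.5, 0.05, p = 0.5, total = 2)
  expect_equal(metametric_score(m2, s), 2 * metametric_score(m, s))
  # undefined or zero-capture entries score +Inf
  expect_equal(metametric_score(metric_stub(1, 1, 1, 1, defined = FALSE), s), Inf)
  expect_equal(metametric_score(metric_stub(1, 1, 1, 1, total = 0), s), Inf)
  # a zero spread skips its term
  s0 <- structure(list(s_kl = 0, s_b = 0.5, s_h = 0.25, s_c = 0.1,
                       n_defined = 3L), class = "spread_set")
  expect_equal(metametric_score(m, s0), (1/0.5 + 0.5/0.25 + 0.05/0.1) / 2)
})

test_that("a noiseless self-query ranks its own entry first", {
  set.seed(31)
  db <- tiny_db(20)
  for (i in c(1, 7, 20)) {
    tab <- rank_against_database(db$entries[[i]]$peaks, db)
    expect_equal(tab$id[1], db$entries[[i]]$id)
    expect_lt(tab$d_meta[1], tab$d_meta[2])
  }
})

test_that("ranking is invariant under scaling the query intensities", {
  set.seed(32)
  db <- tiny_db(15)
  q <- db$entries[[3]]$peaks
  q <- peak_list(q$mz + runif(length(q$mz), -0.2, 0.2), q$intensity)
  t1 <- rank_against_database(q, db)
  q1000 <- peak_list(q$mz, q$intensity * 1000)
  t2 <- rank_against_database(q1000, db)
  expect_identical(t1$id, t2$id)
  # every finite score scales uniformly by 1/1000
  fin <- is.finite(t1$d_meta)
  expect_equal(t2$d_meta[fin] * 1000, t1$d_meta[fin], tolerance = 1e-9)
})

test_that("undefined entries rank after all defined entries, ties break by id", {
  set.seed(33)
  db <- tiny_db(6, mz_pool = seq(25, 100, by = 5))
  # query covering only some entries: others are undefined
  q <- db$entries[[2]]$peaks
  tab <- rank_against_database(q, db)
  inf_ranks <- tab$rank[!is.finite(tab$d_meta)]
  fin_ranks <- tab$rank[is.finite(tab$d_meta)]
  if (length(inf_ranks)) expect_true(min(inf_ranks) > max(fin_ranks))
  # undefined block is ordered lexicographically by id
  expect_identical(tab$id[!is.finite(tab$d_meta)],
                   sort(tab$id[!is.finite(tab$d_meta)], method = "radix"))
})

test_that("production scoring matches the straight-line reference pipeline", {
  set.seed(34)
  for (i in 1:10) {
    inst <- random_instance()
    tab <- rank_against_database(inst$query, inst$db)
    got <- tab$d_meta[match(inst$ids, tab$id)]
    want <- naive_pipeline(inst$qx, inst$qy, FALSE, inst$refs)
    fin <- is.finite(want)
    expect_identical(is.finite(got), fin)
    expect_equal(got[fin], want[fin], tolerance = 1e-9)
  }
})

test_that("Bhattacharyya and Hellinger distances induce the same entry ranking", {
  set.seed(35)
  for (i in 1:20) {
    inst <- random_instance(max_entries = 6, max_query = 25)
    tab <- rank_against_database(inst$query, inst$db)
    ord_b <- order(ifelse(is.na(tab$d_b), Inf, tab$d_b), tab$id,
                   method = "radix")
    ord_h <- order(ifelse(is.na(tab$d_h), Inf, tab$d_h), tab$id,
                   method = "radix")
    expect_identical(tab$id[ord_b], tab$id[ord_h])
  }
})
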