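# Small in-code fixtures shared across tests.

# A tiny library of `n` well-separated entries with simple integer peaks.
tiny_db <- function(n = 5, peaks_each = 4, mz_pool = seq(25, 245, by = 5)) {
  entries <- lapply(seq_len(n), function(i) {
    mz <- sort(sample(mz_pool, peaks_each))
    y <- runif(peaks_each, 1, 10)
    database_entry("Test", sprintf("E%02d", i), sprintf("entry%02d", i),
                   peak_list(mz, y))
  })
  ms_database(entries)
}

# Random instance for oracle-equivalence checks: a small library plus a
# peak-list query whose points cover every entry's support (so all metric
# sets are defined). Returns the instance in both package form and the plain
# form the naive oracle consumes.
random_instance <- function(max_entries = 10, max_query = 50) {
  n_entries <- sample(2:max_entries, 1)
  refs <- list()
  entries <- list()
  for (i in seq_len(n_entries)) {
    n <- sample(2:6, 1)
    mz <- sort(sample(seq(20, 200, by = 0.25), n))
    y <- runif(n, 0.5, 10)
    y <- 100 * y / sum(y)
    refs[[i]] <- list(mz = mz, int = y)
    entries[[i]] <- database_entry("T", sprintf("E%02d", i),
                                   sprintf("entry%02d", i),
                                   peak_list(mz, y))
  }
  qx <- unlist(lapply(refs, `[[`, "mz")) + runif(
    length(unlist(lapply(refs, `[[`, "mz"))), -0.3, 0.3)
  qy <- runif(length(qx), 0.1, 5)
  if (length(qx) > max_query) {
    keep <- sort(sample(length(qx), max_query))
    # keep at least one point near every entry so all stay defined
    first_of <- cumsum(c(1, head(lengths(lapply(refs, `[[`, "mz")), -1)))
    keep <- sort(unique(c(keep, first_of)))
    qx <- qx[keep]
    qy <- qy[keep]
  }
  o <- order(qx)
  qx <- qx[o]
  qy <- qy[o]
  dup <- duplicated(qx)
  qx <- qx[!dup]
  qy <- qy[!dup]
  list(db = ms_database(entries), refs = refs,
       query = peak_list(qx, qy), qx = qx, qy = qy,
       ids = sprintf("T/E%02d_entry%02d", seq_len(n_entries), seq_len(n_entries)))
}

# Write a small on-disk library tree for reader tests.
write_fixture_tree <- function(root) {
  dir.create(file.path(root, "Solvents", "CH4O_methanol"), recursive = TRUE)
  dir.create(file.path(root, "Solvents", "C2H6O_ethanol"), recursive = TRUE)
  dir.create(file.path(root, "Gases", "N2_nitrogen"), recursive = TRUE)
  writeLines(c("31 100", "29 72", "32 67"),
             file.path(root, "Solvents", "CH4O_methanol", "ref.ms"))
  writeLines(c("31 100", "45 52", "46 22"),
             file.path(root, "Solvents", "C2H6O_ethanol", "ref.ms"))
  writeLines(c("28 100", "14 14"),
             file.path(root, "Gases", "N2_nitrogen", "ref.ms"))
  writeLines("synthetic fixture entry",
             file.path(root, "Gases", "N2_nitrogen", "INFO.txt"))
  root
}
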