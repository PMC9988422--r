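make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

base_rows <- function() {
  data.frame(substrate = "digoxin", direction = "A2B", experiment = "exp1",
             replicate = "r1", insert_condition = "cells",
             time_min = c(15, 30, 45, 60),
             donor_conc = c(9.9, 9.8, 9.7, 9.6),
             receiver_conc = c(0.1, 0.2, 0.3, 0.4))
}

test_that("a tidy 4-row file parses into one 4-sample timecourse", {
  tcs <- read_timecourses(make_csv(base_rows()))
  expect_length(tcs, 1)
  tc <- tcs[[1]]
  expect_s3_class(tc, "timecourse")
  expect_equal(tc$samples$time_min, c(15, 30, 45, 60))
  expect_equal(tc$samples$receiver_conc, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(tc$insert_condition, "cells")
  expect_length(tc$flags, 0)
})

test_that("rows out of time order are sorted ascending on read", {
  df <- base_rows()[c(3, 1, 4, 2), ]
  tc <- read_timecourses(make_csv(df))[[1]]
  expect_equal(tc$samples$time_min, c(15, 30, 45, 60))
  expect_equal(tc$samples$receiver_conc, c(0.1, 0.2, 0.3, 0.4))
})

test_that("reader is invariant to row permutation", {
  df <- rbind(base_rows(),
              transform(base_rows(), direction = "B2A",
                        receiver_conc = c(0.2, 0.4, 0.6, 0.8)))
  set.seed(42)
  shuffled <- df[sample(nrow(df)), ]
  a <- read_timecourses(make_csv(df))
  b <- read_timecourses(make_csv(shuffled))
  key <- function(tc) paste(tc$substrate, tc$direction, tc$replicate)
  a <- a[order(vapply(a, key, ""))]
  b <- b[order(vapply(b, key, ""))]
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
})

test_that("schema violations fail loudly with the offending detail", {
  df <- base_rows()
  expect_error(read_timecourses(make_csv(df[, setdiff(names(df), "direction")])),
               "`direction`")
  bad <- df
  bad$receiver_conc <- as.character(bad$receiver_conc)
  bad$receiver_conc[3] <- "oops"
  expect_error(read_timecourses(make_csv(bad)), "row 3")
  dup <- rbind(df, df[2, ])
  expect_error(read_timecourses(make_csv(dup)), "duplicate")
  badlvl <- df
  badlvl$direction[1] <- "AB"
  expect_error(read_timecourses(make_csv(badlvl)), "direction")
})

test_that("groups with fewer than 2 timepoints are flagged, not dropped", {
  df <- rbind(base_rows(), data.frame(
    substrate = "digoxin", direction = "B2A", experiment = "exp1",
    replicate = "r1", insert_condition = "cells", time_min = 15,
    donor_conc = 9.9, receiver_conc = 0.1))
  tcs <- read_timecourses(make_csv(df))
  expect_length(tcs, 2)
  short <- Filter(function(tc) tc$direction == "B2A", tcs)[[1]]
  expect_true("too_few_timepoints" %in% short$flags)
})

test_that("empty donor_conc cells fall back to the dosing concentration", {
  df <- base_rows()
  df$donor_conc <- NA
  tc <- read_timecourses(make_csv(df), dosing = c(digoxin = 10))[[1]]
  expect_true(all(is.na(tc$samples$donor_conc)))
  expect_equal(tc$donor_initial, 10)
})

test_that("timecourse write/read round-trips field-for-field", {
  cfg <- simulation_config(seed = 7)
  sim <- simulate_bidirectional_experiment(cfg, n_experiments = 2)
  path <- tempfile(fileext = ".csv")
  write_timecourses(sim$timecourses, path)
  back <- read_timecourses(path, dosing = cfg$dosing_concentration)
  key <- function(tc) paste(tc$substrate, tc$direction, tc$experiment,
                            tc$replicate, tc$insert_condition)
  orig <- sim$timecourses[order(vapply(sim$timecourses, key, ""))]
  back <- back[order(vapply(back, key, ""))]
  expect_equal(length(orig), length(back))
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$samples, orig[[i]]$samples, tolerance = 1e-12)
    expect_equal(back[[i]]$direction, orig[[i]]$direction)
  }
})

test_that("efflux results round-trip through write_results", {
  res <- bbb_reference_efflux()[c("digoxin", "SASP")]
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  back <- read_efflux_results(path)
  for (s in names(res)) {
    expect_equal(back[[s]]$er_mean, res[[s]]$er_mean, tolerance = 1e-12)
    expect_equal(back[[s]]$er_sd, res[[s]]$er_sd, tolerance = 1e-12)
    expect_equal(back[[s]]$n, res[[s]]$n)
    expect_equal(vapply(back[[s]]$experiments, `[[`, 0, "er"),
                 vapply(res[[s]]$experiments, `[[`, 0, "er"),
                 tolerance = 1e-12)
  }
  expect_error(write_results(list(), tempfile()), "nothing to write")
})

test_that("assay config YAML is parsed with defaults filled in", {
  path <- tempfile(fileext = ".yml")
  writeLines(c(
    "geometry:",
    "  area_cm2: 0.7",
    "  luminal_uL: 400",
    "  abluminal_uL: 800",
    "substrates:",
    "  digoxin:",
    "    transporter: P-gp",
    "    dosing_concentration: 5",
    "alpha: 0.01"), path)
  cfg <- read_assay_config(path)
  expect_equal(cfg$geometry$membrane_area_cm2, 0.7)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$donor_mode, "measured")
  expect_equal(cfg$substrates$transporter[1], "P-gp")
})
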