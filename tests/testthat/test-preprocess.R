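# Unit conversion, log transform, slot averaging with the completeness
# filter, vertical interpolation, night labelling, and the insect GMM.

test_that("reflectivity converts to density by the 11 cm^2 cross section", {
  expect_equal(reflectivity_to_density(11), 1)
  expect_equal(reflectivity_to_density(0), 0)
  expect_equal(reflectivity_to_density(55), 5)
  expect_error(reflectivity_to_density(-1), "non-negative")
})

test_that("log transform is log10(x+1) with an exact inverse", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(9), 1)
  for (x in c(0, 1, 100)) expect_equal(log_inverse(log_transform(x)), x)
  expect_error(log_transform(-0.1), "non-negative")
  expect_true(all(diff(log_transform(seq(0, 50, 0.5))) > 0))
})

# build a complete raw night for one radar: value_fun(alt, sub) gives density
raw_night <- function(value_fun, night = as.Date("2020-03-05"),
                      radar = "R01", alts = mig_altitudes()) {
  slots <- c(20, 23, 2)
  rows <- list()
  for (h in slots) {
    day <- if (h == 2) night + 1 else night
    for (sub in 0:2) {
      t <- as.POSIXct(sprintf("%s %02d:%02d:00", day, h, sub * 15), tz = "UTC")
      rows[[length(rows) + 1]] <- data.frame(
        radar = radar, datetime = t, height = alts,
        dens = value_fun(alts, sub)
      )
    }
  }
  do.call(rbind, rows)
}

test_that("nine complete sub-profiles yield three 13-bin hourly profiles", {
  raw <- raw_night(function(alt, sub) 10 + alt / 100)
  panel <- build_nightly_profiles(raw)
  expect_identical(nrow(panel$values), 3L)
  expect_identical(ncol(panel$values), 13L)
  expect_setequal(panel$meta$slot, c("early", "mid", "late"))
  expect_true(all(panel$valid))
  expect_identical(unique(panel$meta$night), as.Date("2020-03-05"))
})

test_that("late-night profiles are assigned to the previous date's night", {
  t <- as.POSIXct("2020-03-06 02:15:00", tz = "UTC")
  raw <- data.frame(radar = "R01", datetime = t, height = mig_altitudes(),
                    dens = 5)
  panel <- build_nightly_profiles(raw)
  expect_identical(panel$meta$night, as.Date("2020-03-05"))
  expect_identical(panel$meta$slot, "late")
})

test_that("sub-profiles with fewer than five valid bins are excluded", {
  # early slot: two clean sub-profiles at density 10, one 4-bin sub-profile
  # at density 1000 which must not contaminate the average
  raw <- raw_night(function(alt, sub) rep(10, length(alt)))
  bad <- data.frame(radar = "R01",
                    datetime = as.POSIXct("2020-03-05 20:30:00", tz = "UTC"),
                    height = mig_altitudes()[1:4], dens = 1000)
  raw <- rbind(raw[!(format(raw$datetime, "%H:%M") == "20:30"), ], bad)
  panel <- build_nightly_profiles(raw)
  early <- panel$values[panel$meta$slot == "early", ]
  expect_equal(unname(early), rep(log_transform(10), 13), tolerance = 1e-12)
  # a whole slot below the filter disappears
  raw2 <- raw_night(function(alt, sub) rep(10, length(alt)))
  is_mid <- format(raw2$datetime, "%H") == "23"
  raw2 <- rbind(raw2[!is_mid, ],
                transform(raw2[is_mid & raw2$height <= 750, ]))
  panel2 <- build_nightly_profiles(raw2)
  expect_false("mid" %in% panel2$meta$slot)
  expect_setequal(panel2$meta$slot, c("early", "late"))
})

test_that("slot averaging of identical sub-profiles returns that sub-profile", {
  prof <- 3 * exp(-mig_altitudes() / 800)
  raw <- raw_night(function(alt, sub) prof)
  panel <- build_nightly_profiles(raw)
  for (i in 1:3) {
    expect_equal(unname(panel$values[i, ]), unname(log_transform(prof)),
                 tolerance = 1e-12)
  }
})

test_that("linear ramps are interpolated exactly onto the 13-bin grid", {
  # raw profiles on a coarser grid; log-density linear in altitude
  alts_in <- seq(0, 3000, by = 500)
  ramp <- log_inverse(0.1 + alts_in / 4000)
  t <- as.POSIXct("2020-03-05 23:00:00", tz = "UTC")
  raw <- data.frame(radar = "R01", datetime = t, height = alts_in, dens = ramp)
  panel <- build_nightly_profiles(raw)
  expect_equal(unname(panel$values[1, ]),
               0.1 + mig_altitudes() / 4000, tolerance = 1e-10)
})

test_that("timestamps outside the nine sampling points are rejected with a warning", {
  good <- raw_night(function(alt, sub) 10)
  bad <- data.frame(radar = "R01",
                    datetime = as.POSIXct("2020-03-05 21:00:00", tz = "UTC"),
                    height = mig_altitudes(), dens = 99)
  expect_warning(panel <- build_nightly_profiles(rbind(good, bad)),
                 "outside the 9 sampling points")
  expect_identical(nrow(panel$values), 3L)
  expect_lt(max(panel$values), log_transform(11))
})

test_that("masked altitude ranges stay masked instead of being extrapolated", {
  t <- as.POSIXct("2020-03-05 20:00:00", tz = "UTC")
  alts_in <- mig_altitudes()[3:10]
  raw <- data.frame(radar = "R01", datetime = t, height = alts_in, dens = 7)
  panel <- build_nightly_profiles(raw)
  expect_true(all(is.na(panel$values[1, c(1:2, 11:13)])))
  expect_true(all(!is.na(panel$values[1, 3:10])))
})

test_that("the airspeed mixture separates planted insects from birds", {
  set.seed(42)
  n <- 500
  insect <- runif(n) < 0.12
  meta <- data.frame(radar = "R01",
                     night = as.Date("2020-03-01") + seq_len(n),
                     slot = "mid",
                     airspeed = ifelse(insect, rnorm(n, 2, 0.5),
                                       rnorm(n, 10, 0.5)))
  panel <- profile_panel(meta, matrix(1, n, 13))
  labels <- classify_insect_events(panel)
  expect_gte(mean((labels == "insect") == insect), 0.99)
  filtered <- filter_insects(panel, labels)
  expect_identical(nrow(filtered$values), sum(labels == "bird"))
})

test_that("a single airspeed cluster yields no insect flags (BIC gate)", {
  set.seed(43)
  meta <- data.frame(radar = "R01", night = as.Date("2020-03-01") + 1:400,
                     slot = "mid", airspeed = rnorm(400, 10, 1))
  panel <- profile_panel(meta, matrix(1, 400, 13))
  expect_identical(sum(classify_insect_events(panel) == "insect"), 0L)
})

test_that("panels without insects planted come back almost untouched", {
  ds <- generate_dataset(tiny_config(insect_rate = 0, seed = 17))
  panel <- build_nightly_profiles(ds$raw)
  labels <- classify_insect_events(panel)
  expect_lte(mean(labels == "insect"), 0.01)
})

test_that("missing airspeed skips the insect stage with a warning", {
  meta <- data.frame(radar = "R01", night = as.Date("2020-03-01") + 1:30,
                     slot = "mid", airspeed = NA_real_)
  panel <- profile_panel(meta, matrix(1, 30, 13))
  expect_warning(labels <- classify_insect_events(panel), "airspeed")
  expect_true(all(labels == "bird"))
})
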