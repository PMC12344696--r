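test_that("read_spectrum parses, sorts, and rejects bad files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,0.1", "410,0.2", "420,0.15"), f)
  s <- read_spectrum(f, kind = "absorbance")
  expect_s3_class(s, "spectrum")
  expect_length(s$wavelengths, 3)
  expect_equal(s$values, c(0.1, 0.2, 0.15))

  # out-of-order input comes back sorted
  writeLines(c("420,0.15", "400,0.1", "410,0.2"), f)
  s2 <- read_spectrum(f, kind = "absorbance")
  expect_equal(s2$wavelengths, c(400, 410, 420))
  expect_equal(s2$values, c(0.1, 0.2, 0.15))

  writeLines(c("400,0.1", "410,0.2", "410,0.3", "420,0.15"), f)
  expect_error(read_spectrum(f, "absorbance"), "duplicated wavelength")

  writeLines(c("400,0.1", "410,abc", "420,0.15"), f)
  expect_error(read_spectrum(f, "absorbance"), "row 2")

  writeLines(c("400,0.1", "410,0.2"), f)
  expect_error(read_spectrum(f, "absorbance"), "insufficient|3 point")

  writeLines(c("400,0.1", "410,NaN", "420,0.15"), f)
  expect_error(read_spectrum(f, "absorbance"))
})

test_that("write/read spectrum round trip is identity to 1e-12", {
  s <- spectrum(seq(350, 600, 2.5), exp(sin(seq(350, 600, 2.5) / 40)),
                kind = "emission", label = "rt")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, kind = "emission")
  expect_rel_equal(s2$wavelengths, s$wavelengths, 1e-12)
  expect_rel_equal(s2$values, s$values, 1e-12)
})

test_that("read_titration handles wide and long dialects identically", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength,0.5,0.1,1.5",
               "400,0.10,0.20,0.30",
               "410,0.15,0.25,0.35",
               "420,0.12,0.22,0.32"), wide)
  ts_w <- read_titration(wide, unit = "mg/mL")
  expect_length(ts_w$entries, 3)
  # sorted ascending even though file columns were 0.5, 0.1, 1.5
  expect_equal(ts_w$concentrations, c(0.1, 0.5, 1.5))
  expect_equal(ts_w$entries[[1]]$values, c(0.20, 0.25, 0.22))

  long <- withr::local_tempfile(fileext = ".csv")
  rows <- c("concentration,wavelength,value")
  for (cc in c(0.5, 0.1, 1.5)) {
    for (i in 1:3) {
      w <- c(400, 410, 420)[i]
      v <- switch(as.character(cc),
                  "0.5" = c(0.10, 0.15, 0.12),
                  "0.1" = c(0.20, 0.25, 0.22),
                  "1.5" = c(0.30, 0.35, 0.32))[i]
      rows <- c(rows, sprintf("%g,%g,%g", cc, w, v))
    }
  }
  writeLines(rows, long)
  ts_l <- read_titration(long, unit = "mg/mL")
  expect_equal(ts_l$concentrations, ts_w$concentrations)
  for (i in 1:3) {
    expect_equal(ts_l$entries[[i]]$wavelengths, ts_w$entries[[i]]$wavelengths)
    expect_equal(ts_l$entries[[i]]$values, ts_w$entries[[i]]$values)
  }

  # wide file without a header row is rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,0.1,0.2,0.4,0.5", "410,0.15,0.25,0.45,0.55",
               "420,0.12,0.22,0.42,0.52"), bad)
  expect_error(read_titration(bad, unit = "mg/mL"),
               "missing concentration header")
})

test_that("titration round trip preserves values", {
  tit <- gen_absorbance_titration(noise_sd = 0.005, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration(tit, f)
  back <- read_titration(f, unit = "mg/mL")
  expect_equal(back$concentrations, tit$concentrations)
  for (i in seq_along(tit$entries)) {
    expect_rel_equal(back$entries[[i]]$values, tit$entries[[i]]$values,
                     1e-12)
  }
})

test_that("read_decay validates the grid and counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 64
  t <- (0:(n - 1)) * 0.0122
  counts <- rpois(n, 50)
  writeLines(c("time,counts", paste(format(t, digits = 17),
                                    counts, sep = ",")), f)
  d <- read_decay(f)
  expect_equal(d$channel_width, 0.0122, tolerance = 1e-9)

  counts2 <- counts; counts2[5] <- -1
  writeLines(c("time,counts", paste(format(t, digits = 17),
                                    counts2, sep = ",")), f)
  expect_error(read_decay(f), "negative counts")

  t2 <- t; t2[10] <- t2[10] * 1.01
  writeLines(c("time,counts", paste(format(t2, digits = 17),
                                    counts, sep = ",")), f)
  expect_error(read_decay(f), "not uniform")
})

test_that("decay and height-map round trips preserve values", {
  d <- gen_decay(channels = 256, channel_width = 0.4, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_decay(d, f)
  d2 <- read_decay(f)
  expect_rel_equal(d2$counts, d$counts, 1e-12)
  expect_rel_equal(d2$irf, d$irf, 1e-12)

  hm <- gen_height_map(grid_size = 16, seed = 4)
  g <- withr::local_tempfile(fileext = ".csv")
  write_height_map(hm, g)
  hm2 <- read_height_map(g)
  expect_rel_equal(as.vector(hm2$heights), as.vector(hm$heights), 1e-12)
})
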