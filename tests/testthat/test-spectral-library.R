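test_that("CSV round trip is the identity up to print precision", {
  lib <- toy_library(n = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(back$samples$sample_id, lib$samples$sample_id)
  expect_identical(back$samples$variety, lib$samples$variety)
  expect_identical(back$samples$year, lib$samples$year)
  expect_equal(back$samples$brix, round(lib$samples$brix, 2))
  expect_equal(back$wavelengths, lib$wavelengths)
  expect_equal(unname(back$spectra), unname(lib$spectra), tolerance = 1e-10)

  big <- generate_library(generator_config(n_per_variety = 50, varieties = "Syrah",
                                           seed = 5))
  write_library(big, path)
  back <- read_library(path)
  expect_equal(unname(back$spectra), unname(big$spectra), tolerance = 1e-10)
  expect_equal(back$samples$brix, round(big$samples$brix, 2))
})

test_that("empty and single-record libraries survive the round trip", {
  wl <- seq(400, 440, 10)
  empty <- spectral_library(matrix(0, 0, 5), wl, numeric(0), character(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(empty, path)
  expect_identical(length(readLines(path)), 1L)  # header only
  one <- spectral_library(matrix(0.5, 1, 5), wl, 12, "A")
  write_library(one, path)
  expect_identical(length(readLines(path)), 2L)
  expect_equal(n_samples(read_library(path)), 1)
})

test_that("reader rejects malformed files with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,variety,year,bunch_label,brix,350,340,360",
               "A,Syrah,2020,B1,12,0.5,0.5,0.5"), path)
  expect_error(read_library(path), "non-monotone grid")

  writeLines(c("sample_id,variety,year,bunch_label,brix,350,360",
               "A,Syrah,2020,B1,12,0.5,0.5",
               "A,Syrah,2020,B1,13,0.6,0.6"), path)
  expect_error(read_library(path), "duplicate sample_id: A")

  writeLines(c("sample_id,variety,year,bunch_label,brix,350,360",
               "A,Syrah,2020,B1,45,0.5,0.5"), path)
  expect_error(read_library(path), "plausibility window.*rows: 1")

  writeLines(c("sample_id,variety,year,bunch_label,brix,350,360",
               "A,Syrah,2020,B1,12,0.5,oops"), path)
  expect_error(read_library(path), "non-numeric reflectance")
})

test_that("a hand-written fixture file parses to exactly the typed values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,variety,year,bunch_label,brix,400,410,420,430,440",
               "G1,Syrah,2020,B07,14.20,0.41,0.39,0.44,0.52,0.50",
               "G2,Malagouzia,2021,B02,22.60,0.35,0.33,0.40,0.49,0.48"), path)
  lib <- read_library(path)
  expect_equal(lib$wavelengths, c(400, 410, 420, 430, 440))
  expect_identical(lib$samples$sample_id, c("G1", "G2"))
  expect_identical(lib$samples$variety, c("Syrah", "Malagouzia"))
  expect_identical(lib$samples$year, c(2020L, 2021L))
  expect_identical(lib$samples$bunch_label, c("B07", "B02"))
  expect_equal(lib$samples$brix, c(14.2, 22.6))
  expect_equal(unname(lib$spectra[1, ]), c(0.41, 0.39, 0.44, 0.52, 0.50))
  expect_equal(unname(lib$spectra[2, ]), c(0.35, 0.33, 0.40, 0.49, 0.48))
})

test_that("downsampling averages centered windows and hits the canonical grid", {
  # native 1-nm grid -> 216-band canonical grid
  wl <- vnir_swir_grid(1)
  expect_length(wl, 2151)
  lib <- spectral_library(matrix(0.5, 2, length(wl)), wl, c(10, 20))
  ds <- downsample(lib, 10)
  expect_equal(ds$wavelengths, vnir_swir_grid(10))
  expect_length(ds$wavelengths, 216)
  expect_true(all(ds$spectra == 0.5))  # mean of constants

  # brute-force window-averaging oracle on a toy grid
  wl <- 350:379
  set.seed(4)
  x <- runif(length(wl), 0.2, 0.8)
  lib <- spectral_library(matrix(x, 1, length(wl)), wl, 15)
  ds <- downsample(lib, 10)
  expect_equal(ds$wavelengths, c(350, 360, 370))
  oracle <- sapply(c(350, 360, 370), function(centre) {
    mean(x[wl >= centre - 5 & wl < centre + 5])
  })
  expect_equal(unname(ds$spectra[1, ]), oracle)
})

test_that("downsampling is idempotent at the target step and preserves brix", {
  lib <- toy_library(n = 4)
  ds <- downsample(lib, 10)
  expect_equal(ds$spectra, lib$spectra)  # already on a 10-nm grid
  expect_identical(ds$samples$brix, lib$samples$brix)
  expect_identical(ds$samples, lib$samples)
  expect_error(downsample(lib, 5), "smaller than input resolution")
  expect_error(downsample(lib, 15), "does not divide evenly")
  dec <- downsample(toy_library(n = 2), 20, method = "decimate")
  expect_equal(dec$spectra[, "400"], toy_library(n = 2)$spectra[, "400"])
})

test_that("library summary reproduces the linear-interpolation quartiles", {
  wl <- seq(400, 440, 10)
  lib <- spectral_library(matrix(0.5, 4, 5), wl, brix = c(1, 2, 3, 4),
                          variety = "Syrah")
  s <- summary(lib)
  expect_equal(s$mean, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$median, 2.5)
  expect_equal(s$q3, 3.25)
  expect_true(s$min <= s$q1 && s$q1 <= s$median && s$median <= s$q3 &&
                s$q3 <= s$max)

  single <- spectral_library(matrix(0.5, 1, 5), wl, brix = 17)
  s1 <- summary(single)
  expect_equal(s1$sd, 0)
  expect_equal(unlist(s1[c("min", "q1", "median", "q3", "max")], use.names = FALSE),
               rep(17, 5))

  two <- toy_library(n = 6)
  expect_identical(sort(summary(two)$variety), c("Malagouzia", "Syrah"))
  expect_equal(nrow(summary(two)), 2)
})

test_that("constructor enforces the grid and brix invariants", {
  wl <- seq(400, 440, 10)
  expect_error(spectral_library(matrix(0.5, 1, 5), rev(wl), 12), "non-monotone")
  expect_error(spectral_library(matrix(0.5, 1, 5), wl + 3000, 12), "within")
  expect_error(spectral_library(matrix(0.5, 1, 4), wl, 12), "does not match grid")
  expect_error(spectral_library(matrix(0.5, 1, 5), wl, 40), "plausibility window")
  expect_error(spectral_library(matrix(0.5, 2, 5), wl, c(12, 13),
                                sample_id = c("A", "A")), "duplicate")
  sub <- toy_library(n = 6)[c(2, 4)]
  expect_equal(n_samples(sub), 2)
  expect_identical(rownames(sub$spectra), sub$samples$sample_id)
})
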