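test_that("small Laplacian subtracts the neighbour mean", {
  times <- epochAxis()
  n <- length(times)
  mont <- defaultMontage()

  same <- makeEpochSet(matrix(1, n, 2), fillValue = 1)
  expect_equal(smallLaplacian(same, "Cz"), matrix(0, n, 2))

  # constant centre 5 with neighbours 1, 2, 3, 4 -> 5 - 2.5
  eeg <- array(0, c(17, n, 1), dimnames = list(channelNames(mont), NULL, NULL))
  eeg["Cz", , 1] <- 5
  nb <- laplacianNeighbors(mont)$Cz
  for (i in seq_along(nb)) eeg[nb[i], , 1] <- i
  ep <- makeEpochSet(matrix(0, n, 1))
  ep@eeg <- eeg
  expect_equal(smallLaplacian(ep, "Cz"), matrix(2.5, n, 1))

  # centre = s(t) + common(t), neighbours = common(t) -> recovers s exactly
  set.seed(9)
  s <- rnorm(n); common <- rnorm(n)
  eeg2 <- array(rep(common, each = 17), c(17, n, 1),
                dimnames = list(channelNames(mont), NULL, NULL))
  eeg2["Cz", , 1] <- s + common
  ep2 <- makeEpochSet(matrix(0, n, 1)); ep2@eeg <- eeg2
  expect_equal(smallLaplacian(ep2, "Cz")[, 1], s)

  badMont <- defaultMontage(laplacianNeighbors = list(
    Cz = c("C3", "C4", "Fz", "Pz"), FC1 = c("F3", "Fz", "C3", "Cz"),
    FC2 = c("F4", "Fz", "C4", "Cz")))
  expect_error(smallLaplacian(ep, "P3"), "no Laplacian neighbours")
})

test_that("small Laplacian is linear", {
  times <- epochAxis()
  set.seed(10)
  a <- makeEpochSet(matrix(rnorm(length(times)), ncol = 1))
  a@eeg[] <- rnorm(length(a@eeg))
  b <- a; b@eeg[] <- rnorm(length(b@eeg))
  ab <- a; ab@eeg <- 2 * a@eeg - 0.5 * b@eeg
  expect_equal(smallLaplacian(ab, "FC1"),
               2 * smallLaplacian(a, "FC1") - 0.5 * smallLaplacian(b, "FC1"),
               tolerance = 1e-12)
})

test_that("Morlet power localizes sinusoid ridges on the frequency grid", {
  rate <- 250
  t <- seq(0, 8, by = 1 / rate)[-1]
  tfr0 <- morletTFR(numeric(length(t)), rate, channel = "Cz")
  expect_true(all(tfrPower(tfr0) == 0))

  x <- sin(2 * pi * 20 * t)
  tfr <- morletTFR(x, rate, times = t - 4)
  interior <- tfrTimes(tfr) > -2 & tfrTimes(tfr) < 2
  prof <- rowMeans(tfrPower(tfr)[, interior])
  expect_equal(tfrFreqs(tfr)[which.max(prof)], 20)

  x2 <- sin(2 * pi * 6 * t) + sin(2 * pi * 30 * t)
  prof2 <- rowMeans(tfrPower(morletTFR(x2, rate, times = t - 4))[, interior])
  # two ridges = the two most prominent local maxima of the profile
  lm <- which(diff(sign(diff(prof2))) == -2) + 1
  top2 <- sort(tfrFreqs(tfr)[lm[order(prof2[lm], decreasing = TRUE)[1:2]]])
  expect_lte(abs(top2[1] - 6), 1)
  expect_lte(abs(top2[2] - 30), 1)

  expect_error(morletTFR(numeric(100), 250), "shorter")
})

test_that("time and frequency resolution trade off with frequency", {
  rate <- 250
  t <- seq(0, 12, by = 1 / rate)[-1]
  fwhm <- function(v) {
    above <- which(v >= max(v) / 2)
    diff(range(above))
  }
  # frequency width from a pure sinusoid's spectral profile
  interiorCols <- function(tfr) tfrTimes(tfr) > 4 & tfrTimes(tfr) < 8
  p10 <- morletTFR(sin(2 * pi * 10 * t), rate, times = t)
  p40 <- morletTFR(sin(2 * pi * 40 * t), rate, times = t)
  fw10 <- fwhm(rowMeans(tfrPower(p10)[, interiorCols(p10)]))
  fw40 <- fwhm(rowMeans(tfrPower(p40)[, interiorCols(p40)]))
  expect_lt(fw10, fw40)
  # time width from an impulse response
  imp <- numeric(length(t)); imp[length(t) / 2] <- 1
  pi10 <- morletTFR(imp, rate, times = t)
  tw10 <- fwhm(tfrPower(pi10)[10, ])
  tw40 <- fwhm(tfrPower(pi10)[40, ])
  expect_gt(tw10, tw40)
})

test_that("ERD maps are baseline-zero, scale-invariant and near zero for null data", {
  trials <- oscTrials(50, pct = 0, seed = 12)
  times <- epochAxis()
  maps <- lapply(seq_len(ncol(trials)), function(j)
    morletTFR(trials[, j], 250, freqs = seq(5, 30, by = 1), times = times,
              decim = 8, channel = "Cz"))
  erd <- erdErs(maps)
  expect_s4_class(erd, "ERDMap")
  expect_equal(nTrials(erd), 50)

  # null data: small mean percent change in the reported window
  rep50 <- erdValues(erd)[, tfrTimes(erd) >= -2 & tfrTimes(erd) < 4]
  expect_lt(abs(mean(rep50)), 6)

  # baseline-zero by construction (over the edge-valid baseline columns)
  ev <- edgeValid(maps[[1]])
  bas <- tfrTimes(erd) >= -4 & tfrTimes(erd) <= -2
  for (fi in seq_along(tfrFreqs(erd))) {
    cols <- bas & ev[fi, ]
    expect_lt(abs(mean(erdValues(erd)[fi, cols])), 1e-6)
  }

  # multiplying all trial powers by 4 leaves the map unchanged
  arr <- array(0, c(dim(tfrPower(maps[[1]])), 50))
  for (j in 1:50) arr[, , j] <- tfrPower(maps[[j]])
  e1 <- erdErs(arr, times = tfrTimes(maps[[1]]), freqs = tfrFreqs(maps[[1]]),
               edgeValid = ev)
  e4 <- erdErs(4 * arr, times = tfrTimes(maps[[1]]),
               freqs = tfrFreqs(maps[[1]]), edgeValid = ev)
  expect_identical(erdValues(e1), erdValues(e4))
  expect_equal(erdValues(e1), erdValues(erd))
})

test_that("zero baseline power names the offending frequency", {
  arr <- array(1, c(3, 100, 5))
  arr[2, , ] <- 0
  times <- seq(-4, 3.9, length.out = 100)
  expect_error(erdErs(arr, times = times, freqs = 1:3),
               "frequency row 2")
})

test_that("band summaries partition the spectrum independently", {
  freqs <- 1:50
  times <- seq(-2, 3.98, by = 0.02)
  bands <- bandDefinitions()
  lb <- bands[bands$name == "low_beta", ]
  hb <- bands[bands$name == "high_beta", ]

  uni <- new("ERDMap", channel = "Cz", freqs = as.numeric(freqs),
             times = times, erd = matrix(-30, 50, length(times)),
             baselineWindow = c(-4, -2),
             significanceMask = matrix(logical(), 0, 0), nTrials = 10L)
  expect_equal(bandSummary(uni, lb, c(-2, 4)), -30)

  part <- uni
  part@erd <- matrix(0, 50, length(times))
  part@erd[freqs >= 13 & freqs <= 20, ] <- -40
  expect_equal(bandSummary(part, lb, c(-2, 4)), -40)
  expect_equal(bandSummary(part, hb, c(-2, 4)), 0)

  # modifying 21-35 Hz leaves the 13-20 Hz summary bit-identical
  before <- bandSummary(part, lb, c(0, 2))
  part@erd[freqs >= 21 & freqs <= 35, ] <- 99
  expect_identical(bandSummary(part, lb, c(0, 2)), before)

  # the alternative preset draws the boundary at 12/21 Hz
  alt <- bandDefinitions("split1221")
  expect_equal(alt$low_hz[alt$name == "low_beta"], 12)
  expect_equal(alt$high_hz[alt$name == "low_beta"], 21)
})

test_that("long-format export carries every pixel once", {
  arr <- array(runif(3 * 4 * 2, 1, 2), c(3, 4, 2))
  times <- c(-3, -2.5, -2, -1)
  erd <- erdErs(arr, times = times, freqs = c(5, 10, 15),
                baselineWindow = c(-3, -2))
  df <- erdLongFormat(erd)
  expect_equal(nrow(df), 12)
  expect_equal(df$erd_pct[df$freq_hz == 10 & df$time_s == -1],
               erdValues(erd)[2, 4])
})
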