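times <- epochAxis()

test_that("peak negativity finds the minimum and breaks ties early", {
  x <- -10 * cos(2 * pi * times / 5)   # minimum -10 at t = 0
  pk <- peakNegativity(x, times)
  expect_equal(pk$amplitude_uv, -10)
  expect_equal(pk$time_ms, 0)

  flat <- rep(-3, length(times))
  pkF <- peakNegativity(flat, times)
  expect_equal(pkF$amplitude_uv, -3)
  expect_equal(pkF$time_ms, -1000)     # earliest sample of the window

  # the peak is the lowest value of the whole search window
  sel <- times >= -1 & times <= 1.5
  expect_true(all(x[sel] >= pk$amplitude_uv))
})

test_that("NS1, NS2 and rebound follow their defining difference quotients", {
  ramp <- -3 * (times + 1)             # slope -3 through the NS1 window
  expect_equal(ns1(ramp, times, peakTimeS = 0), -3)
  expect_equal(ns1(rep(2, length(times)), times, 0), 0)

  # 4 microvolt drop over the final 0.4 s
  x2 <- ifelse(times < -0.4, 0, (times + 0.4) * -10)
  expect_equal(ns2(x2, times, 0, x2[times == 0]), -10)
  expect_equal(ns2(rep(1, length(times)), times, 0, 1), 0)

  v <- ifelse(times < 0, -3 * (times + 1), -3 + 3 * times)  # V at t=0
  expect_equal(reboundRate(v, times, 0, -3), 3)
  expect_equal(reboundRate(rep(0, length(times)), times, 0, 0), 0)
  expect_true(is.na(reboundRate(v, times, 3, -3)))  # 3 + 1.5 s > epoch end
})

test_that("the outlier rule is the closed window [-1.5, 2] s", {
  expect_false(flagOutlier(0))
  expect_false(flagOutlier(-1500))
  expect_false(flagOutlier(2000))
  expect_true(flagOutlier(2100))
  expect_true(flagOutlier(-1501))
})

test_that("MRCP-EMG latency is a signed difference", {
  expect_equal(latencyMrcpEmg(300, 350), -50)
  expect_equal(latencyMrcpEmg(120, 120), 0)
})

test_that("features on noiseless templates match injected values exactly", {
  # knots on the 250 Hz grid so nearest-sample reads are exact
  cases <- list(c(-16, -3, -12, 3), c(-13.7, -0.6, -18.6, 2.5),
                c(-10.5, -1.7, -10.4, 2.8))
  for (cs in cases) {
    x <- mrcpTemplate(times, peak = cs[1], ns1 = cs[2], ns2 = cs[3],
                      rebound = cs[4], peakTime = 0.4)
    pk <- peakNegativity(x, times)
    expect_equal(pk$amplitude_uv, cs[1], tolerance = 1e-12)
    expect_equal(pk$time_ms, 400, tolerance = 1e-12)
    expect_equal(ns1(x, times, 0.4), cs[2], tolerance = 1e-10)
    expect_equal(ns2(x, times, 0.4, pk$amplitude_uv), cs[3],
                 tolerance = 1e-10)
    expect_equal(reboundRate(x, times, 0.4, pk$amplitude_uv), cs[4],
                 tolerance = 1e-10)
  }
})

test_that("slopes are offset-invariant while the peak shifts with the offset", {
  x <- mrcpTemplate(times, peakTime = 0.4)
  y <- x + 5
  pkX <- peakNegativity(x, times); pkY <- peakNegativity(y, times)
  expect_equal(pkY$amplitude_uv, pkX$amplitude_uv + 5)
  expect_equal(pkY$time_ms, pkX$time_ms)
  expect_equal(ns1(y, times, 0.4), ns1(x, times, 0.4))
  expect_equal(ns2(y, times, 0.4, pkY$amplitude_uv),
               ns2(x, times, 0.4, pkX$amplitude_uv))
  expect_equal(reboundRate(y, times, 0.4, pkY$amplitude_uv),
               reboundRate(x, times, 0.4, pkX$amplitude_uv))
})

test_that("the feature table flags outliers and conserves trial counts", {
  good <- templateTrials(4, noiseSd = 0.5, seed = 2)
  late <- mrcpTemplate(times, peakTime = 2.5)   # trough outside [-1.5, 2]
  ep <- makeEpochSet(cbind(good, late))
  f <- mrcpFeatures(ep)
  expect_equal(nrow(f), 5)
  expect_equal(sum(f$outlier), 1)
  expect_true(f$outlier[5])
  expect_equal(sum(f$outlier) + sum(!f$outlier), nTrials(ep))
})

test_that("grand averages behave like means", {
  one <- templateTrials(1, noiseSd = 0)
  gaOne <- grandAverage(makeEpochSet(one))
  expect_equal(gaOne$mean, as.numeric(one))
  expect_equal(gaOne$sd, numeric(length(times)))
  expect_equal(gaOne$n, 1)

  x <- templateTrials(1, noiseSd = 0)
  both <- makeEpochSet(cbind(x, -x))
  expect_equal(grandAverage(both, excludeOutliers = FALSE)$mean,
               numeric(length(times)))

  # CLT bound: 100 noisy copies, pointwise mean within 3 SE nearly always
  noisy <- templateTrials(100, noiseSd = 2, seed = 3)
  ga <- grandAverage(makeEpochSet(noisy))
  tmpl <- mrcpTemplate(times, peakTime = 0.4)
  se <- 2 / sqrt(ga$n)
  expect_gte(mean(abs(ga$mean - tmpl) <= 3 * se), 0.99)
})

test_that("coefficient of variation matches a direct-formula oracle", {
  identical5 <- templateTrials(5, noiseSd = 0)
  expect_equal(coefficientOfVariation(makeEpochSet(identical5)), 0)

  tmpl <- mrcpTemplate(times, peak = -30, ns1 = -8, ns2 = -30,
                       rebound = 10, peakTime = 0.4)
  c0 <- 0.5
  trials <- sapply(c(-2, -1, 0, 1, 2) * c0, function(d) tmpl + d)
  got <- coefficientOfVariation(makeEpochSet(trials), eps = 0.1)
  # direct evaluation on the construction
  sel <- times >= -2 & times < 4
  sdT <- apply(trials[sel, ], 1, sd)
  expected <- mean(sdT / pmax(abs(tmpl[sel]), 0.1))
  expect_equal(got, expected, tolerance = 1e-12)

  # monotone in noise at equal template
  lo <- coefficientOfVariation(makeEpochSet(
    templateTrials(30, noiseSd = 1, peak = -30, seed = 4)))
  hi <- coefficientOfVariation(makeEpochSet(
    templateTrials(30, noiseSd = 4, peak = -30, seed = 4)))
  expect_gt(hi, lo)
})

test_that("the topographic table reads grand averages at 13 default times", {
  const <- makeEpochSet(matrix(5, length(times), 3), fillValue = 5)
  tab <- topoSeries(const, excludeOutliers = FALSE)
  expect_equal(dim(tab), c(17, 13))
  expect_true(all(tab == 5))

  ep <- makeEpochSet(templateTrials(3, noiseSd = 0, peakTime = 0.5))
  tab2 <- topoSeries(ep)
  # Cz column extremum at the time point nearest the injected trough
  expect_equal(colnames(tab2)[which.min(tab2["Cz", ])], "+0.5s")
  expect_equal(unname(tab2["Pz", ]), rep(0, 13))
})
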