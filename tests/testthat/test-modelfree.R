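test_that("spectral density matches closed forms and the frozen oracle", {
  ## J(0) with S2 = 1 is 0.4 * tauC regardless of tauI
  p1 <- motionParams(1, s2 = 1)
  expect_equal(spectralDensity(p1, 8.4e-9, 0), 0.4 * 8.4e-9)
  ## S2 = 0 with vanishing internal time: J -> 0 at all frequencies
  p0 <- motionParams(2, s2 = 0, tauI = 1e-15)
  expect_lt(max(spectralDensity(p0, 8.4e-9, c(0, 1e8, 1e9))), 1e-13)
  ## high-precision oracle point
  p <- motionParams(2, s2 = 0.85, tauI = 50e-12)
  expect_equal(spectralDensity(p, 9.4e-9, 2 * pi * 60.8e6), J_ORACLE,
               tolerance = 1e-12)
})

test_that("predicted relaxation matches the frozen rigid-case oracle", {
  r <- predictRelaxation(motionParams(1, s2 = 1), 9.4e-9, FC)
  expect_equal(unname(r["r1"]), RIGID_R1, tolerance = 1e-12)
  expect_equal(unname(r["r2"]), RIGID_R2, tolerance = 1e-12)
  expect_equal(unname(r["noe"]), RIGID_NOE, tolerance = 1e-12)
})

test_that("Rex adds to R2 only, exactly", {
  base <- predictRelaxation(motionParams(1, s2 = 0.85), 9.4e-9, FC)
  shifted <- predictRelaxation(motionParams(3, s2 = 0.85, rex = 5), 9.4e-9, FC)
  expect_equal(unname(shifted["r2"] - base["r2"]), 5, tolerance = 1e-12)
  expect_equal(unname(shifted["r1"]), unname(base["r1"]))
  expect_equal(unname(shifted["noe"]), unname(base["noe"]))
})

test_that("the NOE approaches its extreme-narrowing value as tauC -> 0", {
  r <- predictRelaxation(motionParams(1, s2 = 1), 1e-13, FC)
  expect_equal(unname(r["noe"]), NOE_NARROWING, tolerance = 1e-4)
})

test_that("R2/R1 is strictly increasing in tauC for the rigid spin", {
  taus <- seq(1, 20, by = 0.5) * 1e-9
  ratio <- vapply(taus, function(tc) {
    r <- predictRelaxation(motionParams(1, s2 = 1), tc, FC)
    unname(r["r2"] / r["r1"])
  }, 1)
  expect_true(all(diff(ratio) > 0))
})

test_that("exponential fits recover the printed decay constants exactly", {
  f1 <- fitExponentialDecay(T1_DELAYS, 100 * exp(-T1_DELAYS / 475.7))
  expect_equal(f1$T, 475.7, tolerance = 1e-6)
  expect_true(f1$ok)
  f2 <- fitExponentialDecay(T2_DELAYS, 50 * exp(-T2_DELAYS / 155.3))
  expect_equal(f2$T, 155.3, tolerance = 1e-6)
})

test_that("non-decaying intensity series are flagged, not fitted", {
  f <- fitExponentialDecay(T1_DELAYS, seq(100, 170, length.out = 8))
  expect_false(f$ok)
  expect_true(is.na(f$T))
})

test_that("noisy exponential fits recover the truth on average", {
  set.seed(71)
  Ts <- replicate(500, {
    y <- 100 * exp(-T1_DELAYS / 475.7)
    y <- y + rnorm(8, 0, 0.02 * y)
    fitExponentialDecay(T1_DELAYS, y, error = 0.02 * y)$T
  })
  expect_lt(abs(mean(Ts) - 475.7) / 475.7, 0.01)
  ## covariance-based errors agree with the observed spread
  set.seed(72)
  y <- 100 * exp(-T1_DELAYS / 475.7)
  yn <- y + rnorm(8, 0, 0.02 * y)
  f <- fitExponentialDecay(T1_DELAYS, yn, error = 0.02 * y)
  expect_gt(f$error, sd(Ts) / 3)
  expect_lt(f$error, sd(Ts) * 3)
})

test_that("global tauC is recovered from a rigid dataset and is immune to exchange", {
  r <- predictRelaxation(motionParams(1, s2 = 1), 9.4e-9, FC)
  n <- 30
  tab <- relaxationTable(1:n, rep(1000 / r[["r1"]], n), rep(5, n),
                         rep(1000 / r[["r2"]], n), rep(2, n),
                         rep(r[["noe"]], n), rep(0.02, n))
  expect_equal(estimateGlobalTauC(tab, FC), 9.4, tolerance = 0.01)
  ## three residues given large Rex, then excluded: identical estimate
  d <- tab@data
  rex <- predictRelaxation(motionParams(3, s2 = 1, rex = 8), 9.4e-9, FC)
  d$t2[1:3] <- 1000 / rex[["r2"]]
  tabx <- relaxationTable(d$residue, d$t1, d$t1err, d$t2, d$t2err, d$noe,
                          d$noeerr)
  expect_equal(estimateGlobalTauC(tabx, FC, exclude = 1:3),
               estimateGlobalTauC(tab, FC), tolerance = 1e-9)
})

test_that("tauC estimation refuses a table with no NOE above the cutoff", {
  tab <- relaxationTable(1:10, rep(500, 10), rep(5, 10), rep(150, 10),
                         rep(2, 10), rep(0.5, 10), rep(0.02, 10))
  expect_error(estimateGlobalTauC(tab, FC), "insufficient")
})

test_that("noiseless single-residue fits select the generating model", {
  ## model 1 truth: exact S2 recovery
  rec <- makeRecord(motionParams(1, s2 = 0.85), 9.4e-9)
  fit <- fitResidueModels(rec, 9.4e-9, FC)
  expect_equal(fit@params@model, 1L)
  expect_equal(fit@params@s2, 0.85, tolerance = 1e-4)
  ## flexible terminus: low NOE, model with tauI, S2 < 0.6
  rec2 <- makeRecord(motionParams(2, s2 = 0.5, tauI = 600e-12), 9.4e-9,
                     noise = 0.02, seed = 5)
  fit2 <- fitResidueModels(rec2, 9.4e-9, FC)
  expect_true(fit2@params@model %in% c(2L, 4L, 5L))
  expect_gt(fit2@params@tauI, 0)
  expect_lt(fit2@params@s2, 0.6)
})

test_that("model 3 is selected in >= 90% of noisy replicates", {
  hits <- vapply(1:100, function(s) {
    rec <- makeRecord(motionParams(3, s2 = 0.85, rex = 4), 9.4e-9,
                      noise = 0.02, seed = s)
    fitResidueModels(rec, 9.4e-9, FC)@params@model == 3L
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("Monte-Carlo uncertainties scale with the measurement noise", {
  rec <- makeRecord(motionParams(1, s2 = 0.85), 9.4e-9, noise = 0.02,
                    seed = 3)
  set.seed(9)
  fit <- fitResidueModels(rec, 9.4e-9, FC, mcDraws = 200)
  expect_true("s2" %in% names(fit@uncertainties))
  expect_gt(fit@uncertainties[["s2"]], 0.001)
  expect_lt(fit@uncertainties[["s2"]], 0.05)
})

test_that("fitting noiseless forward predictions recovers parameters (all models)", {
  set.seed(123)
  cases <- list(
    motionParams(1, s2 = 0.92),
    motionParams(2, s2 = 0.62, tauI = 120e-12),
    motionParams(3, s2 = 0.81, rex = 6.5),
    motionParams(4, s2 = 0.71, tauI = 80e-12, rex = 2.5),
    motionParams(5, sf2 = 0.88, ss2 = 0.64, tauI = 900e-12))
  for (p in cases) {
    rec <- makeRecord(p, 9.4e-9)
    fit <- fitResidueModels(rec, 9.4e-9, FC)
    expect_equal(fit@params@model, p@model)
    expect_equal(fit@params@s2, p@s2, tolerance = 1e-4)
    if (p@tauI > 0) expect_equal(fit@params@tauI, p@tauI, tolerance = 1e-4)
    if (p@rex > 0) expect_equal(fit@params@rex, p@rex, tolerance = 1e-4)
  }
})

test_that("chi-square nesting holds across the model ladder", {
  set.seed(42)
  for (i in 1:12) {
    m <- sample(1:5, 1)
    p <- switch(m,
      motionParams(1, s2 = runif(1, 0.3, 0.97)),
      motionParams(2, s2 = runif(1, 0.3, 0.9), tauI = runif(1, 1e-11, 2e-9)),
      motionParams(3, s2 = runif(1, 0.3, 0.9), rex = runif(1, 0.5, 10)),
      motionParams(4, s2 = runif(1, 0.3, 0.9), tauI = runif(1, 1e-11, 1e-9),
                   rex = runif(1, 0.5, 10)),
      motionParams(5, sf2 = runif(1, 0.7, 0.99), ss2 = runif(1, 0.4, 0.95),
                   tauI = runif(1, 5e-11, 2e-9)))
    rec <- makeRecord(p, 9.4e-9, noise = if (i %% 2) 0.02 else 0,
                      seed = 1000 + i)
    fit <- fitResidueModels(rec, 9.4e-9, FC)
    chi <- fit@modelTable$chisq
    tol <- 1e-8 * max(1, max(chi[is.finite(chi)]))
    expect_lte(chi[2], chi[1] + tol)
    expect_lte(chi[3], chi[1] + tol)
    expect_lte(chi[4], chi[2] + tol)
    expect_lte(chi[4], chi[3] + tol)
    expect_lte(chi[5], chi[2] + tol)
  }
})

test_that("the full analysis alternates tauC and per-residue fits to convergence", {
  sim <- simulateRelaxationDataset(seed = 11)
  fit <- runModelFree(sim$table, FC)
  expect_true(fit@converged)
  expect_equal(tauC(fit), 9.4, tolerance = 0.03)
  res <- resultsTable(fit)
  tr <- sim$truth$profile
  expect_lte(sqrt(mean((res$s2 - tr$s2)^2)), 0.03)
  ## noiseless dataset: fixed point reached immediately
  sim0 <- simulateRelaxationDataset(noise = 0, seed = 2)
  fit0 <- runModelFree(sim0$table, FC)
  expect_lte(length(fit0@history), 2L)
  expect_equal(tauC(fit0), 9.4, tolerance = 1e-6)
})

test_that("NOE-filtered averages use a strict cutoff and match brute force", {
  tab <- relaxationTable(1:3, c(480, 500, 460), rep(5, 3),
                         c(150, 160, 140), rep(2, 3),
                         noe = c(0.8, 0.6, 0.4), noeerr = rep(0.02, 3))
  avg <- averageWithNoeFilter(tab, 0.6)
  expect_equal(avg$n, 1L)         # 0.6 itself is excluded
  expect_equal(avg$meanT1, 480)
  ## all above cutoff: plain mean/sd
  tab2 <- relaxationTable(1:3, c(480, 500, 460), rep(5, 3),
                          c(150, 160, 140), rep(2, 3),
                          noe = c(0.8, 0.7, 0.9), noeerr = rep(0.02, 3))
  avg2 <- averageWithNoeFilter(tab2)
  expect_equal(avg2$meanT1, mean(c(480, 500, 460)))
  expect_equal(avg2$sdT2, sd(c(150, 160, 140)))
  ## random tables match an independent brute-force recomputation exactly
  set.seed(19)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    t1 <- runif(n, 300, 700); t2 <- t1 * runif(n, 0.1, 0.5)
    noe <- runif(n, 0.2, 1.0)
    tab <- relaxationTable(1:n, t1, rep(1, n), t2, rep(1, n), noe,
                           rep(0.01, n))
    avg <- averageWithNoeFilter(tab, 0.6)
    keep <- noe > 0.6
    if (!any(keep)) next
    expect_identical(avg$meanT1, mean(t1[keep]))
    expect_identical(avg$meanT2, mean(t2[keep]))
    expect_identical(avg$n, sum(keep))
  }
  ## everything filtered: empty-average error
  tabE <- relaxationTable(1:3, c(480, 500, 460), rep(5, 3),
                          c(150, 160, 140), rep(2, 3),
                          noe = c(0.1, 0.2, 0.3), noeerr = rep(0.02, 3))
  expect_error(averageWithNoeFilter(tabE), "filtered")
})
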