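test_that("composite CSP matches closed forms and its invariances", {
  expect_equal(computeCsp(8, 120, 8, 120), 0)
  expect_equal(computeCsp(8, 120, 9, 120), 1)
  expect_equal(computeCsp(8, 120, 8.5, 122), sqrt(0.25 + 0.16),
               tolerance = 1e-12)
  ## swap and global reference offset invariance
  set.seed(8)
  for (i in 1:20) {
    a <- c(runif(1, 6, 10), runif(1, 100, 135))
    b <- c(runif(1, 6, 10), runif(1, 100, 135))
    off <- c(runif(1, -1, 1), runif(1, -5, 5))
    expect_equal(computeCsp(a[1], a[2], b[1], b[2]),
                 computeCsp(b[1], b[2], a[1], a[2]))
    expect_equal(computeCsp(a[1], a[2], b[1], b[2]),
                 computeCsp(a[1] + off[1], a[2] + off[2],
                            b[1] + off[1], b[2] + off[2]),
                 tolerance = 1e-12)
  }
})

test_that("fraction bound obeys its closed form, limits and monotonicity", {
  expect_equal(fractionBound(1, 0, 1), 0)
  expect_equal(fractionBound(1, 1, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  ## stoichiometric limit Kd -> 0
  expect_equal(fractionBound(1, 0.4, 1e-12), 0.4, tolerance = 1e-6)
  expect_equal(fractionBound(1, 2.5, 1e-12), 1, tolerance = 1e-6)
  L <- seq(0, 5, by = 0.1)
  f1 <- fractionBound(1, L, 0.5)
  expect_true(all(diff(f1) >= 0))
  expect_true(all(f1 >= 0 & f1 <= 1))
  kds <- c(0.01, 0.1, 1, 10)
  fk <- vapply(kds, function(k) fractionBound(1, 1, k), 1)
  expect_true(all(diff(fk) < 0))
})

test_that("a drifting peak is tracked as one continuous trajectory", {
  ratios <- c(0, 1, 2, 3, 4)
  mk <- function(dH, dN) peakList("R10N-H", dH, dN, 100)
  pls <- lapply(seq_along(ratios), function(k)
    mk(8 + 0.02 * (k - 1), 120 + 0.08 * (k - 1)))
  ser <- titrationSeries(ratios, pls)
  tr <- trackPeaks(ser)
  expect_length(tr, 1L)
  expect_false(tr[[1]]@ambiguous)
  expect_equal(sum(!is.na(tr[[1]]@points$dH)), 5L)
  expect_true(all(is.na(tr[[1]]@points$dH2)))
})

test_that("a fading original plus a growing distant peak forms a two-peak trajectory", {
  ratios <- c(0, 1, 2, 3)
  pls <- list(
    peakList("R7N-H", 8.0, 120, 100),
    peakList(c("a", NA), c(8.0, 8.5), c(120, 121), c(70, 30)),
    peakList(c("a", NA), c(8.0, 8.5), c(120, 121), c(40, 60)),
    peakList(c("a", NA), c(8.0, 8.5), c(120, 121), c(10, 90)))
  ser <- titrationSeries(ratios, pls)
  tr <- trackPeaks(ser)
  expect_equal(sum(!is.na(tr[[1]]@points$dH2)), 3L)
  out <- classifyExchangeRegime(tr[[1]])
  expect_equal(regime(out), "slow")
})

test_that("crossing trajectories within tolerance are flagged ambiguous, not guessed", {
  ## two peaks converge to within the jump tolerance and cross
  ratios <- c(0, 1, 2, 3, 4)
  dH1 <- c(8.00, 8.02, 8.04, 8.06, 8.08)
  dH2 <- c(8.08, 8.06, 8.04, 8.02, 8.00)
  pls <- lapply(1:5, function(k)
    peakList(if (k == 1) c("R1N-H", "R2N-H") else c(NA, NA),
             c(dH1[k], dH2[k]), c(120, 120), c(100, 100)))
  ser <- titrationSeries(ratios, pls)
  tr <- trackPeaks(ser)
  expect_true(tr[["1"]]@ambiguous)
  expect_true(tr[["2"]]@ambiguous)
  expect_equal(regime(classifyExchangeRegime(tr[["1"]])), "ambiguous")
  ## brute force over the two possible matchings at the crossing point:
  ## their costs coincide, so no nearest-neighbour rule can decide
  costA <- abs(dH1[2] - dH1[3]) + abs(dH2[2] - dH2[3])
  costB <- abs(dH1[2] - dH2[3]) + abs(dH2[2] - dH1[3])
  expect_lt(abs(costA - costB), 0.05)
})

test_that("noiseless synthetic series classify to the generating regimes", {
  for (seed in c(2, 7, 13)) {
    sim <- simulateTitrationSeries(kd = 3, jitter = 0, seed = seed)
    tr <- lapply(trackPeaks(sim$series), classifyExchangeRegime)
    lab <- vapply(tr, regime, "")
    truth <- setNames(sim$truth$layout$regime,
                      as.character(sim$truth$layout$residue))
    expect_equal(unname(lab[names(truth)]), unname(truth))
  }
})

test_that("doubling appears below the 1:1 molar ratio for a tight binder", {
  sim <- simulateTitrationSeries(kd = 3, jitter = 0, seed = 2)
  tr <- trackPeaks(sim$series)
  slowRes <- sim$truth$layout$residue[sim$truth$layout$regime == "slow"]
  for (r in as.character(slowRes)) {
    pts <- tr[[r]]@points
    firstDouble <- min(pts$ratio[!is.na(pts$dH2)])
    expect_lt(firstDouble, 1)
  }
})

test_that("noiseless fast-exchange fits recover the generating Kd to <= 1%", {
  sim <- simulateTitrationSeries(kd = 3, jitter = 0, seed = 2)
  tr <- lapply(trackPeaks(sim$series), classifyExchangeRegime)
  fit <- fitKdFastExchange(tr, sim$series)
  expect_true(fit@identifiable)
  expect_equal(kdValue(fit), 3, tolerance = 0.01)
  ## the fitted curve passes through the free position at ratio 0
  expect_equal(fit@details$fractionBound[1], 0)
})

test_that("Kd recovery holds across its identifiable range", {
  ## truth within [0.1, 10] x the maximum ligand concentration
  for (kd in c(400, 3200, 10000)) {
    sim <- simulateTitrationSeries(kd = kd, jitter = 0, seed = 5)
    tr <- lapply(trackPeaks(sim$series), classifyExchangeRegime)
    fit <- fitKdFastExchange(tr, sim$series)
    expect_equal(kdValue(fit), kd, tolerance = 0.01)
  }
})

test_that("a nanomolar site at millimolar protein is flagged unidentifiable", {
  sim <- simulateTitrationSeries(kd = 0.008, jitter = 0, seed = 2)
  tr <- lapply(trackPeaks(sim$series), classifyExchangeRegime)
  fit <- fitKdFastExchange(tr, sim$series)
  expect_false(fit@identifiable)
  expect_lt(fit@kdCI[1] / fit@kdCI[2], 0.01)   # CI spans orders of magnitude
})

test_that("binding maps to lobes correctly", {
  csp <- data.frame(residue = c(10, 20, 30, 95, 150),
                    csp = c(0.3, 0.2, 0.1, 0.01, 0.02))
  m <- mapBindingSite(csp, boundary = 88, seqLength = 158, threshold = 0.05)
  s <- m$summary
  expect_equal(s$fractionOfPerturbed[s$lobe == "N"], 1.0)
  expect_gt(s$meanCsp[s$lobe == "N"], s$meanCsp[s$lobe == "C"])
  expect_error(mapBindingSite(data.frame(residue = 300, csp = 1)),
               "out of range")
  ## uniform random perturbations split between lobes as residue counts do
  set.seed(21)
  res <- sample(1:158, 120, replace = FALSE)
  u <- mapBindingSite(data.frame(residue = res, csp = runif(120, 0.1, 1)),
                      threshold = 0)
  nN <- u$summary$n[u$summary$lobe == "N"]
  p <- binom.test(nN, 120, p = 88 / 158)$p.value
  expect_gt(p, 0.001)
})
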