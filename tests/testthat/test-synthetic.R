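test_that("generators are pure functions of truth and seed", {
  a <- simulateRelaxationDataset(seed = 7)
  b <- simulateRelaxationDataset(seed = 7)
  expect_identical(a$table@data, b$table@data)
  c <- simulateRelaxationDataset(seed = 8)
  expect_false(identical(a$table@data, c$table@data))
  t1 <- simulateTitrationSeries(seed = 7)
  t2 <- simulateTitrationSeries(seed = 7)
  expect_identical(peaks(t1$series@peakLists[[3]]),
                   peaks(t2$series@peakLists[[3]]))
  g1 <- generateToyTemplateAndTarget(seed = 7)
  g2 <- generateToyTemplateAndTarget(seed = 7)
  expect_identical(g1$targetSeq, g2$targetSeq)
  expect_identical(atoms(g1$template), atoms(g2$template))
})

test_that("a noiseless relaxation table equals the forward model exactly", {
  sim <- simulateRelaxationDataset(noise = 0, seed = 1)
  prof <- sim$truth$profile
  for (i in c(1, 40, 75, 150)) {
    p <- with(prof[i, ], switch(model,
      motionParams(1, s2 = s2),
      motionParams(2, s2 = s2, tauI = tauI),
      motionParams(3, s2 = s2, rex = rex)))
    r <- predictRelaxation(p, 9.4e-9, FC)
    expect_equal(sim$table@data$t1[i], 1000 / r[["r1"]], tolerance = 1e-12)
    expect_equal(sim$table@data$t2[i], 1000 / r[["r2"]], tolerance = 1e-12)
    expect_equal(sim$table@data$noe[i], unname(r[["noe"]]), tolerance = 1e-12)
  }
})

test_that("a rigid residue at the holo correlation time passes the NOE filter", {
  r <- predictRelaxation(motionParams(1, s2 = 1), 9.4e-9, FC)
  expect_gt(unname(r["noe"]), 0.6)
})

test_that("the first titration point is the free-state peak list", {
  sim <- simulateTitrationSeries(kd = 3, jitter = 0, seed = 4)
  p1 <- peaks(sim$series@peakLists[[1]])
  lay <- sim$truth$layout
  m <- merge(p1, lay, by = "residue")
  expect_equal(m$dH, m$dHfree, tolerance = 1e-12)
  expect_equal(m$dN, m$dNfree, tolerance = 1e-12)
})

test_that("slow residues double with intensities partitioned by fraction bound", {
  ## with a negligible Kd, ratio 0.5 gives exactly half-bound protein
  sim <- simulateTitrationSeries(kd = 1e-4, jitter = 0,
                                 ratios = c(0, 0.5, 1), seed = 4)
  lay <- sim$truth$layout
  p2 <- peaks(sim$series@peakLists[[2]])
  slow <- lay[lay$regime == "slow", ]
  for (i in seq_len(nrow(slow))) {
    free <- p2[abs(p2$dH - slow$dHfree[i]) < 1e-6 &
                 abs(p2$dN - slow$dNfree[i]) < 1e-6, ]
    bound <- p2[abs(p2$dH - slow$dHbound[i]) < 1e-6 &
                  abs(p2$dN - slow$dNbound[i]) < 1e-6, ]
    expect_equal(free$height, bound$height, tolerance = 1e-3)
  }
})

test_that("the titration generator and Kd fitter close the loop", {
  sim <- simulateTitrationSeries(kd = 3, jitter = 0, seed = 6)
  tr <- lapply(trackPeaks(sim$series), classifyExchangeRegime)
  fit <- fitKdFastExchange(tr, sim$series)
  expect_equal(kdValue(fit), 3, tolerance = 0.01)
})

test_that("toy template/target pairs round-trip through the alignment", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(4), seed = 13)
  aln <- alignWithInsertions(toy$targetSeq, toy$templateSeq)
  expect_length(aln$insertions, 1L)
  expect_equal(aln$insertions[[1]]@anchor, toy$specs[[1]]@anchor)
  expect_equal(nchar(aln$insertions[[1]]@sequence), 4L)
  ## zero insertions: target equals template
  toy0 <- generateToyTemplateAndTarget(insertionLens = integer(0), seed = 13)
  expect_identical(toy0$targetSeq, toy0$templateSeq)
})
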