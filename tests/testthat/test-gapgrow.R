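test_that("ideal backbones have helical and extended geometry", {
  h <- idealBackbone(strrep("A", 10), strrep("H", 10))
  ca <- as.matrix(atoms(h)[atoms(h)$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  rise <- diff(range(prcomp(ca)$x[, 1])) / 9
  expect_equal(rise, 1.5, tolerance = 0.15)
  ## a single residue builds its three mandatory backbone atoms plus O
  one <- idealBackbone("G", "C")
  expect_true(all(c("N", "CA", "C") %in% atoms(one)$elety))
  ## extended chains are longer end-to-end than helices
  ee <- function(m) {
    ca <- as.matrix(atoms(m)[atoms(m)$elety == "CA", c("x", "y", "z")])
    sqrt(sum((ca[1, ] - ca[nrow(ca), ])^2))
  }
  expect_gt(ee(idealBackbone(strrep("A", 10), strrep("C", 10))), ee(h))
  expect_error(idealBackbone("AA", "HX"), "unknown secondary structure")
})

test_that("SASA matches the analytic sphere and is occlusion-free at distance", {
  one <- data.frame(elety = "CA", x = 0, y = 0, z = 0)
  s <- computeSasa(one)
  expect_equal(s$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  two <- data.frame(elety = c("CA", "N"), x = c(0, 100), y = 0, z = 0)
  s2 <- computeSasa(two)
  expect_equal(s2$total, 4 * pi * 3.1^2 + 4 * pi * 2.95^2, tolerance = 0.01)
  expect_error(computeSasa(data.frame(elety = "ZZ", x = 0, y = 0, z = 0)),
               "radius")
})

test_that("SASA agrees with an independent Monte-Carlo dot oracle", {
  set.seed(3)
  df <- data.frame(elety = sample(c("N", "CA", "C", "O"), 20, replace = TRUE),
                   x = runif(20, 0, 8), y = runif(20, 0, 8),
                   z = runif(20, 0, 8))
  sr <- computeSasa(df)$total
  mc <- mcSasa(df, dots = 1e5, seed = 41)
  expect_equal(sr, mc, tolerance = 0.02)
})

test_that("SASA is invariant under rotation, translation and atom permutation", {
  m <- idealBackbone(strrep("A", 12), strrep("H", 12))
  a <- atoms(m)
  ref <- computeSasa(a)$total
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a
  b[, c("x", "y", "z")] <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% R,
                                 2, c(12, -7, 3), "+")
  expect_equal(computeSasa(b)$total, ref, tolerance = 0.01)
  set.seed(5)
  p <- sample(nrow(a))
  expect_equal(computeSasa(a[p, ])$total, ref, tolerance = 1e-9)
})

test_that("alignment recovers planted insertions exactly", {
  ## identical sequences: no insertions
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  a0 <- alignWithInsertions(s, s)
  expect_length(a0$insertions, 0L)
  expect_false(grepl("-", a0$target))
  ## a GSGS block planted after position 20
  tgt <- paste0(substr(s, 1, 20), "GSGS", substr(s, 21, nchar(s)))
  a1 <- alignWithInsertions(tgt, s)
  expect_length(a1$insertions, 1L)
  expect_equal(a1$insertions[[1]]@anchor, 20L)
  expect_equal(a1$insertions[[1]]@sequence, "GSGS")
  ## three planted insertions in a toy pair
  toy <- generateToyTemplateAndTarget(insertionLens = c(3, 4, 5), seed = 5)
  a3 <- alignWithInsertions(toy$targetSeq, toy$templateSeq)
  expect_length(a3$insertions, 3L)
  for (i in 1:3) {
    expect_equal(a3$insertions[[i]]@anchor, toy$specs[[i]]@anchor)
    expect_equal(a3$insertions[[i]]@sequence, toy$specs[[i]]@sequence)
  }
})

test_that("base-model threading copies template coordinates", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(4), seed = 3)
  ## self-alignment: identity threading, RMSD 0
  aln0 <- alignWithInsertions(toy$templateSeq, toy$templateSeq)
  bm0 <- buildBaseModel(aln0, toy$template)
  expect_equal(as.matrix(atoms(bm0)[, c("x", "y", "z")]),
               as.matrix(atoms(toy$template)[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  ## insertion-bearing target: aligned residues still match the template
  aln <- alignWithInsertions(toy$targetSeq, toy$templateSeq)
  bm <- buildBaseModel(aln, toy$template)
  expect_equal(nrow(atoms(bm)), nrow(atoms(toy$template)))
  expect_equal(bm@breaks$afterResno, aln$insertions[[1]]@anchor)
  ## a deletion: model lacks that residue, break declared
  tpl <- toy$templateSeq
  del <- paste0(substr(tpl, 1, 9), substr(tpl, 11, nchar(tpl)))
  alnD <- alignWithInsertions(del, tpl)
  bmD <- buildBaseModel(alnD, toy$template)
  expect_equal(length(unique(atoms(bmD)$resno)), nchar(del))
  expect_equal(bmD@breaks$afterResno, 9L)
})

test_that("relaxation returns immediately at the reference and flags impossible targets", {
  m <- idealBackbone(strrep("A", 12), strrep("H", 12))
  eng <- engineConfig(seed = 1, maxRounds = 6L)
  s <- computeSasa(m)$total
  rx <- relaxUntilConverged(m, eng, reference = s * 1.01, tol = 0.02)
  expect_true(rx$converged)
  expect_equal(rx$rounds, 0L)
  ## unsatisfiable target: max rounds exhausted, flagged
  rx2 <- relaxUntilConverged(m, eng, reference = s * 0.1, tol = 0.02)
  expect_false(rx2$converged)
})

test_that("SASA decreases monotonically over accepted relaxation rounds", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(3), seed = 7)
  aln <- alignWithInsertions(toy$targetSeq, toy$templateSeq)
  bm <- buildBaseModel(aln, toy$template)
  ref <- computeSasa(bm)$total
  spec <- aln$insertions[[1]]
  gr <- growInsertion(bm, spec, chunk = 3L, engine = engineConfig(seed = 4),
                      sasaRef = ref)
  relaxRows <- gr$trace[gr$trace$event == "none", ]
  expect_true(all(diff(relaxRows$sasa) < 0) || nrow(relaxRows) <= 1)
})

test_that("insertions are introduced in chunks with a smaller remainder", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(4), seed = 3)
  aln <- alignWithInsertions(toy$targetSeq, toy$templateSeq)
  bm <- buildBaseModel(aln, toy$template)
  ref <- computeSasa(bm)$total
  ## length 4, chunk 3 -> chunks {3, 1}: two residues-added events
  gr <- growInsertion(bm, aln$insertions[[1]], chunk = 3L,
                      engine = engineConfig(seed = 4), sasaRef = ref)
  expect_equal(sum(gr$trace$event == "residues-added"), 2L)
  expect_equal(sum(gr$trace$event == "insertion-complete"), 1L)
  ## length 2 -> a single chunk
  toy2 <- generateToyTemplateAndTarget(insertionLens = c(2), seed = 9)
  aln2 <- alignWithInsertions(toy2$targetSeq, toy2$templateSeq)
  bm2 <- buildBaseModel(aln2, toy2$template)
  gr2 <- growInsertion(bm2, aln2$insertions[[1]], chunk = 3L,
                       engine = engineConfig(seed = 4),
                       sasaRef = computeSasa(bm2)$total)
  expect_equal(sum(gr2$trace$event == "residues-added"), 1L)
})

test_that("growing a 5-residue loop insertion restores all invariants", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(5), seed = 3)
  res <- runGapGrowing(list(A = toy$targetSeq), toy$template,
                       config = list(engine = engineConfig(seed = 17)))
  m <- res$model
  ## final sequence equals the target exactly; no residue deleted/reordered
  seq <- paste(vapply(
    sort(unique(atoms(m)$resno)),
    function(r) NMRDynamics:::.aa321(
      atoms(m)$resname[atoms(m)$resno == r][1]), ""), collapse = "")
  expect_equal(seq, toy$targetSeq)
  expect_equal(nrow(m@breaks), 0L)
  expectSoundGeometry(m)
  expect_lte(res$report$conservedCaRmsd, 2.0)
  expect_lte(res$report$sasaRatio, 1.05)
  vt <- sasaValues(res$trace)
  expect_true(all(vt$sasa > 0))
  expect_true(all(diff(vt$step[vt$event != "none"]) > 0))
})

test_that("zero insertions leave the base model untouched", {
  toy <- generateToyTemplateAndTarget(insertionLens = integer(0), seed = 3)
  expect_equal(toy$targetSeq, toy$templateSeq)
  res <- runGapGrowing(list(A = toy$targetSeq), toy$template,
                       config = list(engine = engineConfig(seed = 17),
                                     equilibRounds = 0L))
  expect_equal(nrow(atoms(res$model)), nrow(atoms(toy$template)))
  expect_lt(res$report$conservedCaRmsd, 1e-9)
})

test_that("three insertions are processed C- to N-terminal with a reproducible trace", {
  toy <- generateToyTemplateAndTarget(insertionLens = c(3, 4, 5), seed = 5)
  cfg <- list(engine = engineConfig(seed = 17), chunkRounds = 6L)
  res <- runGapGrowing(list(A = toy$targetSeq), toy$template, config = cfg)
  expect_equal(res$report$insertionOrder, c(3L, 2L, 1L))
  seq <- NMRDynamics:::.chainSeq(res$model, "A")
  expect_equal(seq, toy$targetSeq)
  expect_equal(nrow(NMRDynamics:::.detectBreaks(res$model)), 0L)
  ## identical seed and config give a bitwise-identical trace
  res2 <- runGapGrowing(list(A = toy$targetSeq), toy$template, config = cfg)
  expect_identical(sasaValues(res$trace), sasaValues(res2$trace))
})
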