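## Ground-truth-labelled synthetic data for every pipeline stage. All
## generators are pure functions of (truth, seed) and return their truth
## record alongside the data.

#' Default secondary-structure-aware motional-parameter profile
#'
#' Lays out a 150-residue EF-hand-like architecture (alternating helices
#' and loops, flexible termini) and assigns each residue a model-free
#' ground truth: helices are rigid (model 1, S2 = 0.85), ordinary loops
#' have fast internal motion (model 2, S2 = 0.65, tauI = 50 ps), two of
#' the inter-helix loops exchange (model 3, S2 = 0.8, Rex = 4 s-1;
#' the non-binding EF-hand loops of the real protein motivate this), and
#' the termini decay toward S2 = 0.3 with slower internal motion
#' (model 2, tauI = 300 ps).
#'
#' @param n protein length (default 150)
#' @return data.frame with residue, model, s2, tauI (s), rex (s-1)
#' @export
defaultMotionProfile <- function(n = 150) {
  model <- rep(1L, n); s2 <- rep(0.85, n)
  tauI <- rep(0, n); rex <- rep(0, n)
  ## helix/loop layout scaled to n (fractions of a 150-residue dumbbell)
  loops <- list(c(29, 35), c(56, 65), c(86, 92), c(113, 119))
  exchangeLoops <- c(1, 3)
  sc <- n / 150
  for (li in seq_along(loops)) {
    rng <- round(loops[[li]] * sc)
    idx <- rng[1]:rng[2]
    if (li %in% exchangeLoops) {
      model[idx] <- 3L; s2[idx] <- 0.80; rex[idx] <- 4
    } else {
      model[idx] <- 2L; s2[idx] <- 0.65; tauI[idx] <- 50e-12
    }
  }
  nt <- max(3, round(6 * sc))
  for (k in seq_len(nt)) {
    decay <- 0.3 + (0.85 - 0.3) * (k - 1) / nt
    for (idx in c(k, n - k + 1)) {
      model[idx] <- 2L; s2[idx] <- decay; tauI[idx] <- 300e-12; rex[idx] <- 0
    }
  }
  data.frame(residue = seq_len(n), model = model, s2 = s2, tauI = tauI,
             rex = rex)
}

#' Generate a synthetic relaxation dataset with known ground truth
#'
#' Evaluates the relaxation forward model at the per-residue truth and the
#' shared correlation time, applies multiplicative Gaussian noise, and
#' sets the error columns to the noise level.
#'
#' @param tauC correlation time (ns, default 9.4)
#' @param profile per-residue truth as from [defaultMotionProfile()]
#' @param noise relative noise level (default 0.02)
#' @param constants a [FieldConstants-class]
#' @param seed integer seed (fixed seed => identical dataset)
#' @return list(table = [RelaxationTable-class], truth = list with tauC,
#'   profile, noise, seed, frequencyMHz)
#' @export
simulateRelaxationDataset <- function(tauC = 9.4,
                                      profile = defaultMotionProfile(),
                                      noise = 0.02,
                                      constants = fieldConstants(),
                                      seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(profile)
  rates <- .ratesVec(profile$s2, tauC * 1e-9, profile$tauI, profile$rex,
                     rep(1, n), constants)
  t1 <- 1000 / rates[, 1]; t2 <- 1000 / rates[, 2]; noe <- rates[, 3]
  if (noise > 0) {
    t1 <- t1 * (1 + stats::rnorm(n, 0, noise))
    t2 <- t2 * (1 + stats::rnorm(n, 0, noise))
    noe <- noe * (1 + stats::rnorm(n, 0, noise))
  }
  tab <- relaxationTable(profile$residue, t1, abs(t1) * noise, t2,
                         abs(t2) * noise, noe, abs(noe) * noise)
  list(table = tab,
       truth = list(tauC = tauC, profile = profile, noise = noise,
                    seed = seed, frequencyMHz = constants@frequencyMHz))
}

#' Default residue layout for synthetic titrations
#'
#' 30 assigned residues: 10 fast-exchange binders in the N lobe, 8
#' slow-exchange binders in the C lobe, 12 unaffected. Free-state peak
#' positions are drawn from typical amide dispersion (1H 7-9.5 ppm,
#' 15N 105-130 ppm); bound-state offsets are 0.05-0.2 ppm (1H) and
#' 0.3-1.2 ppm (15N) for fast residues, 0.3-0.6 / 1.5-3 ppm for slow.
#'
#' @param seed integer seed
#' @param lobeBoundary last N-lobe residue (default 88)
#' @return data.frame with residue, regime, dHfree, dNfree, dHbound,
#'   dNbound
#' @export
defaultTitrationLayout <- function(seed = 1L, lobeBoundary = 88) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  resF <- sort(sample(5:lobeBoundary, 10))
  resS <- sort(sample((lobeBoundary + 1):155, 8))
  resU <- sort(sample(setdiff(5:155, c(resF, resS)), 12))
  res <- c(resF, resS, resU)
  regime <- c(rep("fast", 10), rep("slow", 8), rep("unaffected", 12))
  n <- length(res)
  dHfree <- stats::runif(n, 7, 9.5)
  dNfree <- stats::runif(n, 105, 130)
  mag <- function(k, lo, hi) stats::runif(k, lo, hi) * sample(c(-1, 1), k, TRUE)
  dHb <- dHfree; dNb <- dNfree
  dHb[regime == "fast"] <- dHfree[regime == "fast"] + mag(10, 0.05, 0.2)
  dNb[regime == "fast"] <- dNfree[regime == "fast"] + mag(10, 0.3, 1.2)
  dHb[regime == "slow"] <- dHfree[regime == "slow"] + mag(8, 0.3, 0.6)
  dNb[regime == "slow"] <- dNfree[regime == "slow"] + mag(8, 1.5, 3)
  data.frame(residue = res, regime = regime, dHfree = dHfree,
             dNfree = dNfree, dHbound = dHb, dNbound = dNb)
}

#' Generate a synthetic HSQC titration series with known ground truth
#'
#' Fast-exchange residues give one peak at the population-weighted
#' position; slow-exchange residues give two peaks whose intensities
#' partition as (1 - fB, fB) (a peak below the intensity floor is not
#' written, mimicking detection limits); unaffected residues sit still.
#' Positions are jittered by Gaussian noise.
#'
#' @param kd dissociation constant (micromolar, default 3)
#' @param layout residue layout as from [defaultTitrationLayout()]
#' @param proteinConcmM protein concentration (mM, default 0.8)
#' @param ratios molar ratio grid (default 0, 0.25, 0.5, 1, 2, 3, 4,
#'   ending at the 1:4 saturating endpoint)
#' @param jitter peak position noise, sd in ppm applied to 1H and (scaled
#'   by 5) 15N (default 0.005)
#' @param jitterRelative when set, overrides \code{jitter} per residue and
#'   axis with \code{jitterRelative} times that residue's own bound-free
#'   response amplitude on the axis (relative position noise)
#' @param intensityFloor minimum relative intensity for a peak to appear
#' @param seed integer seed
#' @return list(series = [TitrationSeries-class], truth = list)
#' @export
simulateTitrationSeries <- function(kd = 3, layout = defaultTitrationLayout(),
                                    proteinConcmM = 0.8,
                                    ratios = c(0, 0.25, 0.5, 1, 2, 3, 4),
                                    jitter = 0.005, jitterRelative = NULL,
                                    intensityFloor = 0.02,
                                    seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  PuM <- proteinConcmM * 1000
  pls <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    fb <- fractionBound(PuM, ratios[k] * PuM, kd)
    rows <- list()
    for (i in seq_len(nrow(layout))) {
      r <- layout[i, ]
      jit <- if (is.null(jitterRelative)) {
        function() stats::rnorm(1, 0, jitter) * c(1, 5)
      } else {
        function() stats::rnorm(2, 0, jitterRelative *
                                  pmax(c(abs(r$dHbound - r$dHfree),
                                         abs(r$dNbound - r$dNfree)), 1e-3))
      }
      if (r$regime == "fast") {
        j <- jit()
        rows[[length(rows) + 1]] <- data.frame(
          assignment = sprintf("R%d", r$residue), residue = r$residue,
          dH = r$dHfree + fb * (r$dHbound - r$dHfree) + j[1],
          dN = r$dNfree + fb * (r$dNbound - r$dNfree) + j[2],
          height = 100)
      } else if (r$regime == "slow") {
        if (1 - fb >= intensityFloor) {
          j <- jit()
          rows[[length(rows) + 1]] <- data.frame(
            assignment = if (k == 1) sprintf("R%d", r$residue) else NA,
            residue = if (k == 1) r$residue else NA,
            dH = r$dHfree + j[1], dN = r$dNfree + j[2],
            height = 100 * (1 - fb))
        }
        if (fb >= intensityFloor) {
          j <- jit()
          rows[[length(rows) + 1]] <- data.frame(
            assignment = NA, residue = NA,
            dH = r$dHbound + j[1], dN = r$dNbound + j[2],
            height = 100 * fb)
        }
      } else {
        j <- jit()
        rows[[length(rows) + 1]] <- data.frame(
          assignment = sprintf("R%d", r$residue), residue = r$residue,
          dH = r$dHfree + j[1], dN = r$dNfree + j[2], height = 100)
      }
    }
    d <- do.call(rbind, rows)
    pls[[k]] <- peakList(d$assignment, d$dH, d$dN, d$height,
                         residue = d$residue)
  }
  series <- titrationSeries(ratios, pls, proteinConcmM = proteinConcmM,
                            maxRatio = max(4, max(ratios)))
  list(series = series,
       truth = list(kd = kd, layout = layout,
                    proteinConcmM = proteinConcmM, ratios = ratios,
                    jitter = jitter, jitterRelative = jitterRelative,
                    seed = seed))
}

## hairpin loop dihedrals: a numerically chosen turn that folds two ideal
## helices into a near-antiparallel hairpin (axis angle ~175 deg, ~11 A
## apart, no interhelix clash)
.HAIRPIN_LOOP <- list(phi = c(-150, -140, 50, 50, 150),
                      psi = c(-100, -100, 130, -100, 150))

#' Generate a toy helix-hairpin template and an insertion-bearing target
#'
#' Builds a two-helix hairpin template from ideal dihedrals (helices at
#' (-60, -45), a fixed loop turn) with a random sequence, then plants the
#' requested insertions into the sequence to form the target. Inserted
#' residues are drawn from G/S/T/N/D so they are distinguishable from the
#' flanking sequence, keeping the alignment recovery unambiguous. Anchors
#' are spread over the loop and the second helix (the first anchor sits in
#' the hairpin loop).
#'
#' @param helixLen residues per helix (default 14)
#' @param insertionLens integer vector of insertion lengths (each in
#'   1..10); may be empty
#' @param seed integer seed
#' @param chain chain id
#' @return list(template = [StructureModel-class], templateSeq, targetSeq,
#'   specs = list of planted [InsertionSpec-class])
#' @export
generateToyTemplateAndTarget <- function(helixLen = 14,
                                         insertionLens = c(4),
                                         seed = 1L, chain = "A") {
  stopifnot(all(insertionLens >= 1), all(insertionLens <= 10))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nl <- length(.HAIRPIN_LOOP$phi)
  n <- 2 * helixLen + nl
  ss <- paste0(strrep("H", helixLen), strrep("C", nl), strrep("H", helixLen))
  ## hydrophobic-rich helices, no G/S/T/N/D (reserved for insertions)
  pool <- c("A", "L", "V", "I", "F", "E", "K", "R", "Q", "M", "W", "Y")
  tseq <- paste(sample(pool, n, replace = TRUE), collapse = "")
  phi <- c(rep(-60, helixLen), .HAIRPIN_LOOP$phi, rep(-60, helixLen))
  psi <- c(rep(-45, helixLen), .HAIRPIN_LOOP$psi, rep(-45, helixLen))
  template <- idealBackbone(tseq, ss, phi = phi, psi = psi, chain = chain)
  ## anchors in template numbering: loop midpoint first, then spread into
  ## helix 2; descending processing order then runs C- to N-terminal
  k <- length(insertionLens)
  anchors <- switch(min(k, 3) + 1L,
    integer(0),
    helixLen + 2L,
    c(helixLen + 2L, helixLen + nl + round(helixLen / 2)),
    c(5L, helixLen + 2L, helixLen + nl + round(helixLen / 2)))
  if (k > 3)
    anchors <- sort(sample(5:(n - 5), k))
  anchors <- sort(anchors[seq_len(k)])
  insPool <- c("G", "S", "T", "N", "D")
  target <- strsplit(tseq, "")[[1]]
  specs <- list()
  offset <- 0L
  for (i in seq_len(k)) {
    insSeq <- paste(sample(insPool, insertionLens[i], replace = TRUE),
                    collapse = "")
    at <- anchors[i] + offset
    target <- append(target, strsplit(insSeq, "")[[1]], after = at)
    tmplSS <- strsplit(ss, "")[[1]]
    ssIns <- if (anchors[i] >= 1 && anchors[i] < n &&
                 tmplSS[anchors[i]] == "H" && tmplSS[anchors[i] + 1] == "H")
      "H" else "C"
    specs[[i]] <- insertionSpec(chain = chain, anchor = at,
                                sequence = insSeq,
                                ss = strrep(ssIns, insertionLens[i]),
                                index = i)
    offset <- offset + insertionLens[i]
  }
  list(template = template, templateSeq = tseq,
       targetSeq = paste(target, collapse = ""), specs = specs)
}
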