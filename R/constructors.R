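## Physical constants (SI)
.MU0 <- 4 * pi * 1e-7
.HBAR <- 6.62607015e-34 / (2 * pi)
.GAMMA_H <- 2.6752218744e8
.GAMMA_N <- -2.7126180436e7

.deriveFieldConstants <- function(frequencyMHz, gammaH, gammaN, rNH, deltaSigma) {
  omegaH <- 2 * pi * frequencyMHz * 1e6
  omegaN <- omegaH * abs(gammaN / gammaH)
  d <- .MU0 * .HBAR * abs(gammaH * gammaN) / (4 * pi * (rNH * 1e-10)^3)
  cc <- omegaN * deltaSigma * 1e-6 / sqrt(3)
  list(omegaH = omegaH, omegaN = omegaN, d = d, c = cc)
}

#' Construct spectrometer/spin-pair constants
#'
#' The defaults are the conventional values for backbone amide 15N
#' relaxation analyses: rNH = 1.02 Angstrom, 15N CSA of -160 ppm, and a
#' 600.13 MHz proton frequency. The dipolar constant d and CSA constant c
#' are derived deterministically from the primary fields.
#'
#' @param frequencyMHz proton spectrometer frequency (MHz)
#' @param rNH N-H bond length (Angstrom)
#' @param deltaSigma 15N chemical shift anisotropy (ppm)
#' @param gammaH,gammaN gyromagnetic ratios (rad s-1 T-1)
#' @return a [FieldConstants-class] object
#' @examples
#' fc <- fieldConstants()
#' fc@d   # dipolar interaction constant, s-1
#' @export
fieldConstants <- function(frequencyMHz = 600.13, rNH = 1.02,
                           deltaSigma = -160,
                           gammaH = .GAMMA_H, gammaN = .GAMMA_N) {
  der <- .deriveFieldConstants(frequencyMHz, gammaH, gammaN, rNH, deltaSigma)
  new("FieldConstants", frequencyMHz = frequencyMHz, gammaH = gammaH,
      gammaN = gammaN, rNH = rNH, deltaSigma = deltaSigma,
      omegaH = der$omegaH, omegaN = der$omegaN, d = der$d, c = der$c)
}

#' Construct motional parameters
#'
#' Parameters not belonging to the requested model are forced to their null
#' values so that each model id denotes exactly its own parameter set.
#' For model 5, \code{s2} is derived as \code{sf2 * ss2}.
#'
#' @param model model id in 1..5
#' @param s2 order parameter (ignored for model 5)
#' @param tauI internal correlation time, seconds (models 2, 4, 5)
#' @param rex exchange contribution to R2, s-1 (models 3, 4)
#' @param sf2,ss2 fast and slow order parameters (model 5)
#' @return a [MotionParams-class] object
#' @examples
#' motionParams(3, s2 = 0.85, rex = 4)
#' @export
motionParams <- function(model, s2 = 1, tauI = 0, rex = 0, sf2 = 1, ss2 = 1) {
  model <- as.integer(model)
  if (model %in% c(1L, 3L)) tauI <- 0
  if (model %in% c(1L, 2L, 5L)) rex <- 0
  if (model != 5L) { sf2 <- 1 } else { s2 <- sf2 * ss2 }
  new("MotionParams", model = model, s2 = s2, tauI = tauI, rex = rex,
      sf2 = sf2, ss2 = if (model == 5L) ss2 else s2)
}

#' Construct a relaxation table
#'
#' @param residue integer residue ids
#' @param t1,t1err,t2,t2err relaxation times and uncertainties (ms)
#' @param noe,noeerr heteronuclear NOE and uncertainty (dimensionless)
#' @param valid logical flag; invalid rows are kept but excluded from
#'   analysis (default: rows satisfying the physical sanity bounds)
#' @return a [RelaxationTable-class] object
#' @export
relaxationTable <- function(residue, t1, t1err, t2, t2err, noe, noeerr,
                            valid = NULL) {
  if (is.null(valid))
    valid <- is.finite(t1) & is.finite(t2) & t1 > 0 & t2 > 0 & t2 <= t1 &
      is.finite(noe) & noe <= 1.2
  new("RelaxationTable",
      data = data.frame(residue = as.integer(residue),
                        t1 = t1, t1err = t1err, t2 = t2, t2err = t2err,
                        noe = noe, noeerr = noeerr, valid = valid))
}

#' Construct a peak list
#'
#' @param assignment character labels ("E66N-H" style or arbitrary); NA for
#'   unassigned peaks
#' @param dH,dN peak positions (ppm)
#' @param height peak intensities (arbitrary units)
#' @param residue integer residue ids; parsed from the first integer in the
#'   assignment label when omitted
#' @param metadata list of acquisition metadata (temperatureC, frequencyMHz)
#' @return a [PeakList-class] object
#' @export
peakList <- function(assignment, dH, dN, height = rep(1, length(dH)),
                     residue = NULL, metadata = list()) {
  if (is.null(residue)) {
    residue <- suppressWarnings(
      as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", assignment)))
  }
  new("PeakList",
      peaks = data.frame(assignment = as.character(assignment),
                         residue = as.integer(residue),
                         dH = dH, dN = dN, height = height),
      metadata = metadata)
}

#' Construct a titration series
#'
#' @param ratios ligand:protein molar ratios, strictly increasing from 0
#' @param peakLists list of [PeakList-class], parallel to ratios
#' @param proteinConcmM total protein concentration (mM)
#' @param maxRatio configured maximum final ratio
#' @return a [TitrationSeries-class] object
#' @export
titrationSeries <- function(ratios, peakLists, proteinConcmM = 0.8,
                            maxRatio = 4) {
  new("TitrationSeries", ratios = ratios, peakLists = peakLists,
      proteinConcmM = proteinConcmM, maxRatio = maxRatio)
}

#' Construct a backbone structure model
#'
#' @param atoms data.frame with columns chain, resno, resname, elety, x, y, z
#' @param ss optional named list of per-chain secondary structure strings
#' @param breaks optional data.frame(chain, afterResno) of declared breaks
#' @return a [StructureModel-class] object
#' @export
structureModel <- function(atoms, ss = list(),
                           breaks = data.frame(chain = character(),
                                               afterResno = integer())) {
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, ss = ss, breaks = breaks)
}

#' Construct an insertion specification
#'
#' @param chain chain id
#' @param anchor residue number after which the insertion occurs
#' @param sequence inserted residues, one-letter string
#' @param ss per-residue secondary structure annotation ("H"/"C"); defaults
#'   to all-coil
#' @param index insertion index (1..k, N- to C-terminal)
#' @return an [InsertionSpec-class] object
#' @export
insertionSpec <- function(chain, anchor, sequence,
                          ss = strrep("C", nchar(sequence)), index = 1L) {
  new("InsertionSpec", chain = as.character(chain), anchor = as.integer(anchor),
      sequence = sequence, ss = ss, index = as.integer(index))
}

#' Construct an annealing engine configuration
#'
#' Defaults are in reduced units chosen for backbone-only models at desk
#' scale; see the package vignette for the rationale behind each value.
#' \code{mdMeta} carries, untouched, the configuration an external
#' molecular-dynamics adapter would need (force field, water model,
#' electrostatics, thermostat/barostat, run lengths); the built-in engine
#' ignores it.
#'
#' @param tempStart,tempEnd kick amplitude schedule (Angstrom)
#' @param stepsPerRound minimiser iterations per round
#' @param kBond,kSS,kPos,kRepel,kCompact force constants
#' @param softRadius soft-sphere contact radius (Angstrom)
#' @param maxRounds maximum rounds per relaxation call
#' @param seed integer seed for the kick stream
#' @param mdMeta metadata list for an external MD adapter
#' @return an [EngineConfig-class] object
#' @export
engineConfig <- function(tempStart = 0.5, tempEnd = 0.05, stepsPerRound = 200L,
                         kBond = 100, kSS = 5, kPos = 1, kRepel = 20,
                         kCompact = 0.02, softRadius = 2.8,
                         maxRounds = 40L, seed = 1L,
                         mdMeta = list(
                           forceField = "AMBER99SB-ILDN", water = "Tip3p",
                           electrostatics = "PME", constraints = "LINCS",
                           thermostat = "V-rescale", tauT_ps = 0.1,
                           barostat = "Berendsen", tauP_ps = 1,
                           refPressure_bar = 1, timestep_fs = 2,
                           relaxRun_ns = c(10, 30))) {
  new("EngineConfig", tempStart = tempStart, tempEnd = tempEnd,
      stepsPerRound = as.integer(stepsPerRound), kBond = kBond, kSS = kSS,
      kPos = kPos, kRepel = kRepel, kCompact = kCompact,
      softRadius = softRadius, maxRounds = as.integer(maxRounds),
      seed = as.integer(seed), mdMeta = mdMeta)
}

## ---- accessors -------------------------------------------------------------

#' Accessors for the package's core classes
#'
#' @param x an object of the documented class
#' @return the corresponding slot content (see each method)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("ratios", "TitrationSeries", function(x) x@ratios)

#' @rdname accessors
#' @export
setMethod("tauC", "ModelFreeFit", function(x) x@tauC)

#' @rdname accessors
#' @export
setMethod("regime", "PeakTrajectory", function(x) x@regime)

#' @rdname accessors
#' @export
setMethod("kdValue", "BindingFit", function(x) x@kd)

#' @rdname accessors
#' @export
setMethod("sasaValues", "SasaTrace", function(x) x@trace)

#' @rdname resultsTable
#' @export
setMethod("resultsTable", "ModelFreeFit", function(x, ...) {
  rows <- lapply(x@fits, function(f) {
    p <- f@params
    data.frame(residue = f@residue, model = p@model, s2 = p@s2,
               tauI_ps = p@tauI * 1e12, rex = p@rex,
               sf2 = p@sf2, ss2 = p@ss2, chisq = f@chisq,
               converged = f@converged)
  })
  out <- do.call(rbind, rows)
  unc <- lapply(x@fits, function(f) f@uncertainties)
  if (any(lengths(unc) > 0)) {
    out$s2err <- vapply(unc, function(u) if ("s2" %in% names(u)) u[["s2"]] else NA_real_, 1)
    out$tauIerr_ps <- vapply(unc, function(u) if ("tauI" %in% names(u)) u[["tauI"]] * 1e12 else NA_real_, 1)
    out$rexerr <- vapply(unc, function(u) if ("rex" %in% names(u)) u[["rex"]] else NA_real_, 1)
  }
  rownames(out) <- NULL
  out
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "FieldConstants", function(object) {
  cat(sprintf("FieldConstants: %.2f MHz, rNH %.3f A, CSA %.0f ppm\n",
              object@frequencyMHz, object@rNH, object@deltaSigma))
  cat(sprintf("  d = %.4g s-1, c = %.4g s-1\n", object@d, object@c))
})

setMethod("show", "MotionParams", function(object) {
  cat(sprintf("MotionParams model %d: S2=%.3f tauI=%.1f ps Rex=%.2f s-1",
              object@model, object@s2, object@tauI * 1e12, object@rex))
  if (object@model == 5L)
    cat(sprintf(" (Sf2=%.3f Ss2=%.3f)", object@sf2, object@ss2))
  cat("\n")
})

setMethod("show", "RelaxationTable", function(object) {
  d <- object@data
  cat(sprintf("RelaxationTable: %d residues (%d valid)\n",
              nrow(d), sum(d$valid)))
  if (nrow(d))
    cat(sprintf("  T1 %.0f-%.0f ms, T2 %.0f-%.0f ms, NOE %.2f-%.2f\n",
                min(d$t1), max(d$t1), min(d$t2), max(d$t2),
                min(d$noe), max(d$noe)))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: %d peaks (%d assigned)\n", nrow(object@peaks),
              sum(!is.na(object@peaks$assignment))))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, ratios %s, [P] = %g mM\n",
              length(object@ratios),
              paste(object@ratios, collapse = ", "), object@proteinConcmM))
})

setMethod("show", "PeakTrajectory", function(object) {
  cat(sprintf("PeakTrajectory residue %d: %d points, regime '%s'%s\n",
              object@residue, nrow(object@points), object@regime,
              if (object@ambiguous) " (ambiguous match)" else ""))
})

setMethod("show", "BindingFit", function(object) {
  if (object@identifiable)
    cat(sprintf("BindingFit: Kd = %.3g uM (95%% CI %.3g-%.3g), chisq %.3g\n",
                object@kd, object@kdCI[1], object@kdCI[2], object@chisq))
  else
    cat("BindingFit: Kd unidentifiable (stoichiometric/concentration-limited regime)\n")
})

setMethod("show", "ModelFitResult", function(object) {
  cat(sprintf("ModelFitResult residue %d: ", object@residue))
  show(object@params)
})

setMethod("show", "ModelFreeFit", function(object) {
  cat(sprintf("ModelFreeFit: tauC = %.2f ns, %d residues, %d iterations%s\n",
              object@tauC, length(object@fits), length(object@history),
              if (object@converged) "" else " (NOT converged)"))
  tab <- table(vapply(object@fits, function(f) f@params@model, 1L))
  cat("  model counts:",
      paste(sprintf("m%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  ch <- unique(a$chain)
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s)%s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno")])), length(ch),
              if (nrow(object@breaks)) sprintf(", %d declared break(s)",
                                               nrow(object@breaks)) else ""))
})

setMethod("show", "InsertionSpec", function(object) {
  cat(sprintf("InsertionSpec %d: chain %s, after residue %d, '%s' (%s)\n",
              object@index, object@chain, object@anchor, object@sequence,
              object@ss))
})

setMethod("show", "SasaTrace", function(object) {
  t <- object@trace
  cat(sprintf("SasaTrace: %d steps, SASA %.0f -> %.0f A^2, %d event(s)\n",
              nrow(t), if (nrow(t)) t$sasa[1] else NA,
              if (nrow(t)) t$sasa[nrow(t)] else NA,
              sum(t$event != "none")))
})

setMethod("show", "EngineConfig", function(object) {
  cat(sprintf(
    "EngineConfig: T %g -> %g, %d steps/round, max %d rounds, seed %d\n",
    object@tempStart, object@tempEnd, object@stepsPerRound,
    object@maxRounds, object@seed))
})
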