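#' @import methods
NULL

#' Spectrometer and spin-pair constants for 15N relaxation
#'
#' Bundles the physical constants that determine the dipolar and CSA
#' interaction strengths of a backbone amide 15N-1H spin pair, together with
#' the derived angular frequencies and interaction constants used by the
#' relaxation forward model.
#'
#' @slot frequencyMHz proton spectrometer frequency (MHz)
#' @slot gammaH,gammaN gyromagnetic ratios (rad s-1 T-1); gammaN is negative
#' @slot rNH N-H bond length (Angstrom)
#' @slot deltaSigma 15N chemical shift anisotropy (ppm), conventionally negative
#' @slot omegaH,omegaN Larmor angular frequencies (rad/s, magnitudes)
#' @slot d,c dipolar and CSA interaction constants (s-1)
#'
#' @seealso [fieldConstants()]
#' @export
setClass("FieldConstants",
  representation(
    frequencyMHz = "numeric", gammaH = "numeric", gammaN = "numeric",
    rNH = "numeric", deltaSigma = "numeric",
    omegaH = "numeric", omegaN = "numeric", d = "numeric", c = "numeric"
  )
)

setValidity("FieldConstants", function(object) {
  msg <- character()
  if (object@frequencyMHz <= 0) msg <- c(msg, "frequencyMHz must be > 0")
  if (object@rNH <= 0) msg <- c(msg, "rNH must be > 0")
  ## derived constants must be consistent with the primary fields
  der <- .deriveFieldConstants(object@frequencyMHz, object@gammaH,
                               object@gammaN, object@rNH, object@deltaSigma)
  for (f in names(der)) {
    if (abs(slot(object, f) - der[[f]]) > 1e-6 * abs(der[[f]]))
      msg <- c(msg, sprintf("slot '%s' inconsistent with primary fields", f))
  }
  if (length(msg)) msg else TRUE
})

#' Lipari-Szabo motional parameters for one residue
#'
#' One of the five standard model-free parameterisations of internal motion:
#' model 1 (S2 only), model 2 (S2, tauI), model 3 (S2, Rex),
#' model 4 (S2, tauI, Rex) and model 5 (the extended form with fast and slow
#' order parameters Sf2, Ss2 and tauI, where S2 = Sf2 * Ss2). Parameters not
#' belonging to the stated model are held at their null values
#' (tauI = 0, rex = 0, sf2 = 1).
#'
#' @slot model integer model id in 1..5
#' @slot s2 generalised order parameter (dimensionless, in [0, 1])
#' @slot tauI internal correlation time (seconds)
#' @slot rex chemical exchange contribution to R2 (s-1)
#' @slot sf2,ss2 fast/slow order parameters (model 5 only)
#'
#' @seealso [motionParams()], [spectralDensity()], [predictRelaxation()]
#' @export
setClass("MotionParams",
  representation(model = "integer", s2 = "numeric", tauI = "numeric",
                 rex = "numeric", sf2 = "numeric", ss2 = "numeric")
)

setValidity("MotionParams", function(object) {
  msg <- character()
  m <- object@model
  if (!(length(m) == 1L && m %in% 1:5)) msg <- c(msg, "model must be in 1..5")
  for (f in c("s2", "sf2", "ss2")) {
    v <- slot(object, f)
    if (v < -1e-9 || v > 1 + 1e-9) msg <- c(msg, sprintf("%s must lie in [0,1]", f))
  }
  if (object@tauI < 0) msg <- c(msg, "tauI must be >= 0")
  if (object@rex < 0) msg <- c(msg, "rex must be >= 0")
  if (length(m) == 1L && m %in% 1:5) {
    if (m %in% c(1L, 3L) && object@tauI != 0)
      msg <- c(msg, "tauI must be 0 for models 1 and 3")
    if (m %in% c(1L, 2L, 5L) && object@rex != 0)
      msg <- c(msg, "rex must be 0 for models 1, 2 and 5")
    if (m != 5L && object@sf2 != 1)
      msg <- c(msg, "sf2 must be 1 except in model 5")
    if (m == 5L && abs(object@s2 - object@sf2 * object@ss2) > 1e-9)
      msg <- c(msg, "model 5 requires s2 == sf2 * ss2")
  }
  if (length(msg)) msg else TRUE
})

#' Per-residue 15N relaxation measurements
#'
#' A table of longitudinal (T1) and transverse (T2) relaxation times and
#' steady-state heteronuclear 1H-15N NOEs, with uncertainties, one row per
#' residue. Times are in milliseconds. Rows flagged \code{valid} must satisfy
#' T1 > 0, T2 > 0 and T2 <= T1; NOE is bounded above by 1.2 as a sanity check.
#'
#' @slot data data.frame with columns residue, t1, t1err, t2, t2err,
#'   noe, noeerr, valid
#' @seealso [relaxationTable()], [readRelaxationTable()]
#' @export
setClass("RelaxationTable", representation(data = "data.frame"))

setValidity("RelaxationTable", function(object) {
  d <- object@data
  need <- c("residue", "t1", "t1err", "t2", "t2err", "noe", "noeerr", "valid")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$residue)) return("duplicate residue ids")
  v <- which(d$valid)
  msg <- character()
  if (any(d$t1[v] <= 0) || any(d$t2[v] <= 0))
    msg <- c(msg, "valid rows require T1 > 0 and T2 > 0")
  if (any(d$t2[v] > d$t1[v]))
    msg <- c(msg, "valid rows require T2 <= T1")
  if (any(d$noe[v] > 1.2))
    msg <- c(msg, "NOE exceeds sanity bound 1.2")
  if (length(msg)) msg else TRUE
})

#' An assigned 2-D 1H-15N peak list
#'
#' Peak positions (ppm) and intensities from one HSQC-type spectrum.
#' Assignment labels must be unique within a list unless explicitly
#' unassigned (NA).
#'
#' @slot peaks data.frame with columns assignment (character, NA allowed),
#'   residue (integer, NA allowed), dH, dN (ppm), height
#' @slot metadata list; recognised entries: temperatureC, frequencyMHz
#' @seealso [peakList()], [readPeakList()], [writePeakList()]
#' @export
setClass("PeakList", representation(peaks = "data.frame", metadata = "list"))

setValidity("PeakList", function(object) {
  p <- object@peaks
  need <- c("assignment", "residue", "dH", "dN", "height")
  if (!all(need %in% names(p)))
    return(paste("missing columns:", paste(setdiff(need, names(p)), collapse = ", ")))
  if (nrow(p)) {
    if (!all(is.finite(p$dH)) || !all(is.finite(p$dN)))
      return("ppm values must be finite")
    lab <- p$assignment[!is.na(p$assignment)]
    if (anyDuplicated(lab)) return("assignment labels must be unique")
  }
  TRUE
})

#' An ordered HSQC titration series
#'
#' Peak lists recorded at strictly increasing ligand:protein molar ratios,
#' starting from the free protein (ratio 0).
#'
#' @slot ratios numeric molar ratios, strictly increasing from 0
#' @slot peakLists list of [PeakList-class] objects, parallel to ratios
#' @slot proteinConcmM total protein concentration (mM)
#' @slot maxRatio configured maximum final ratio (default 4, the usual
#'   saturating endpoint for this kind of peptide titration)
#' @seealso [titrationSeries()], [trackPeaks()]
#' @export
setClass("TitrationSeries",
  representation(ratios = "numeric", peakLists = "list",
                 proteinConcmM = "numeric", maxRatio = "numeric"),
  prototype(maxRatio = 4)
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  r <- object@ratios
  if (length(r) != length(object@peakLists))
    msg <- c(msg, "ratios and peakLists must be parallel")
  if (length(r)) {
    if (r[1] != 0) msg <- c(msg, "series must start at molar ratio 0")
    if (any(diff(r) <= 0)) msg <- c(msg, "molar ratios must be strictly increasing")
    if (max(r) > object@maxRatio + 1e-9)
      msg <- c(msg, sprintf("final ratio exceeds configured maximum %g", object@maxRatio))
  }
  if (length(object@proteinConcmM) != 1 || object@proteinConcmM <= 0)
    msg <- c(msg, "proteinConcmM must be a positive scalar")
  if (!all(vapply(object@peakLists, is, logical(1), "PeakList")))
    msg <- c(msg, "peakLists must contain PeakList objects")
  if (length(msg)) msg else TRUE
})

#' One residue's peak trajectory across a titration
#'
#' The matched peak position(s) of one assigned residue at every titration
#' point. At most two peaks per point are stored: the free-form peak and,
#' in slow exchange, the growing bound-form peak. The regime label is set by
#' [classifyExchangeRegime()] only.
#'
#' @slot residue integer residue id
#' @slot points data.frame with columns ratio, dH, dN, height (primary peak;
#'   NA once vanished) and dH2, dN2, height2 (secondary/bound peak or NA)
#' @slot regime one of "fast", "slow", "unaffected", "ambiguous", or
#'   "unclassified" before classification
#' @slot ambiguous logical; TRUE when matching could not be resolved
#' @export
setClass("PeakTrajectory",
  representation(residue = "integer", points = "data.frame",
                 regime = "character", ambiguous = "logical"),
  prototype(regime = "unclassified", ambiguous = FALSE)
)

setValidity("PeakTrajectory", function(object) {
  ok <- c("fast", "slow", "unaffected", "ambiguous", "unclassified")
  if (!(length(object@regime) == 1 && object@regime %in% ok))
    return("invalid regime label")
  need <- c("ratio", "dH", "dN", "height", "dH2", "dN2", "height2")
  if (!all(need %in% names(object@points))) return("points is missing columns")
  TRUE
})

#' A 1:1 binding fit from fast-exchange titration data
#'
#' @slot kd fitted dissociation constant (micromolar)
#' @slot kdCI approximate 95 percent confidence interval for kd (micromolar)
#' @slot perResidue data.frame of per-residue free and bound shifts
#' @slot chisq residual sum of squares of the global fit
#' @slot identifiable FALSE when binding is concentration-limited
#'   (Kd far below the protein concentration) and the curve carries no
#'   information about Kd
#' @slot details list of fit internals (profile grid, fractions bound)
#' @seealso [fitKdFastExchange()]
#' @export
setClass("BindingFit",
  representation(kd = "numeric", kdCI = "numeric", perResidue = "data.frame",
                 chisq = "numeric", identifiable = "logical", details = "list")
)

setValidity("BindingFit", function(object) {
  if (length(object@kd) != 1 || object@kd <= 0) return("kd must be positive")
  TRUE
})

#' Model-free fit for one residue
#'
#' @slot residue integer residue id
#' @slot params selected [MotionParams-class]
#' @slot chisq chi-square of the selected model
#' @slot modelTable per-model table of chisq, parameter count and adequacy
#' @slot uncertainties named numeric of Monte-Carlo parameter uncertainties
#'   (empty when Monte-Carlo draws were not requested)
#' @slot converged logical
#' @export
setClass("ModelFitResult",
  representation(residue = "integer", params = "MotionParams",
                 chisq = "numeric", modelTable = "data.frame",
                 uncertainties = "numeric", converged = "logical")
)

setValidity("ModelFitResult", function(object) {
  if (!is.finite(object@chisq)) return("selected model chisq must be finite")
  if (length(object@uncertainties) && any(object@uncertainties < 0))
    return("uncertainties must be >= 0")
  TRUE
})

#' A complete model-free analysis
#'
#' The result of [runModelFree()]: the shared rotational correlation time
#' under isotropic tumbling, the per-residue model fits, and the iteration
#' history of the global estimate.
#'
#' @slot tauC correlation time (nanoseconds)
#' @slot fits list of [ModelFitResult-class], one per fitted residue
#' @slot history numeric vector of tauC iterates (ns)
#' @slot converged logical; FALSE when the tauC loop hit its iteration cap
#' @slot constants the [FieldConstants-class] used
#' @seealso [runModelFree()], [resultsTable()]
#' @export
setClass("ModelFreeFit",
  representation(tauC = "numeric", fits = "list", history = "numeric",
                 converged = "logical", constants = "FieldConstants")
)

setValidity("ModelFreeFit", function(object) {
  if (length(object@tauC) != 1 || object@tauC <= 0) return("tauC must be > 0")
  TRUE
})

#' A backbone structure model
#'
#' Backbone coordinates (N, CA, C, O, optionally CB) with chain and residue
#' metadata, an optional per-chain secondary structure string, and declared
#' chain breaks. Coordinates are orthogonal Angstroms.
#'
#' @slot atoms data.frame with columns chain, resno, resname, elety, x, y, z
#' @slot ss named list (by chain) of secondary structure strings (H/C per
#'   residue), possibly empty
#' @slot breaks data.frame with columns chain, afterResno declaring chain
#'   breaks (e.g. at unbuilt insertion anchors)
#' @seealso [readStructure()], [writeStructure()], [computeSasa()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", ss = "list", breaks = "data.frame"),
  prototype(ss = list(),
            breaks = data.frame(chain = character(), afterResno = integer()))
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a[, c("chain", "resno", "elety")]))
      return("duplicate (chain, residue number, atom name) triple")
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("coordinates must be finite")
  }
  TRUE
})

#' An insertion to be grown into a base model
#'
#' @slot chain chain id in the base model
#' @slot anchor residue number (target numbering) after which the insertion
#'   occurs; must exist in the base model
#' @slot sequence inserted residues (one-letter string)
#' @slot ss secondary structure annotation per inserted residue, "H" or "C"
#' @slot index insertion index, numbered 1..k from N- to C-terminus
#' @seealso [alignWithInsertions()], [growInsertion()]
#' @export
setClass("InsertionSpec",
  representation(chain = "character", anchor = "integer",
                 sequence = "character", ss = "character", index = "integer")
)

setValidity("InsertionSpec", function(object) {
  n <- nchar(object@sequence)
  if (n < 1) return("inserted sequence must have length >= 1")
  if (nchar(object@ss) != n) return("ss annotation must match sequence length")
  if (grepl("[^HC]", object@ss)) return("ss annotation must use only H and C")
  TRUE
})

#' SASA versus relaxation step
#'
#' The record of total solvent-accessible surface area along a gap-growing
#' run, with markers for residue-addition and insertion-completion events.
#'
#' @slot trace data.frame with columns step, sasa, event; event is one of
#'   "none", "residues-added", "insertion-complete"
#' @export
setClass("SasaTrace", representation(trace = "data.frame"))

setValidity("SasaTrace", function(object) {
  t <- object@trace
  need <- c("step", "sasa", "event")
  if (!all(need %in% names(t))) return("trace is missing columns")
  if (nrow(t)) {
    if (any(t$sasa <= 0)) return("SASA must be > 0")
    ev <- t$step[t$event != "none"]
    if (any(diff(ev) <= 0)) return("events must occur at strictly increasing steps")
    if (!all(t$event %in% c("none", "residues-added", "insertion-complete")))
      return("unknown event label")
  }
  TRUE
})

#' Configuration of the annealing relaxation engine
#'
#' The pluggable relaxation engine used during gap growing is a
#' simulated-annealing scheme over a coarse backbone potential: harmonic
#' bonded restraints (bond, 1-3 angle and peptide-geometry distances),
#' secondary-structure distance restraints, soft-sphere repulsion, weak
#' positional restraints on conserved atoms, and a weak compaction term.
#' Each round applies a temperature-scaled random kick followed by
#' gradient-based minimisation; the temperature decreases along the schedule.
#' An external molecular-dynamics adapter can substitute for this engine; the
#' \code{mdMeta} entry carries pass-through configuration for such an adapter
#' and is ignored by the built-in engine.
#'
#' @slot tempStart,tempEnd annealing temperatures in reduced units
#'   (the kick amplitude scale, Angstrom); tempStart > tempEnd
#' @slot stepsPerRound minimiser iterations per annealing round
#' @slot kBond,kSS,kPos,kRepel,kCompact restraint force constants
#'   (reduced energy / Angstrom^2)
#' @slot softRadius soft-sphere contact radius (Angstrom)
#' @slot maxRounds maximum relaxation rounds per chunk
#' @slot seed integer random seed for the kick stream
#' @slot mdMeta list of metadata for an optional external MD adapter
#' @seealso [engineConfig()], [relaxUntilConverged()]
#' @export
setClass("EngineConfig",
  representation(tempStart = "numeric", tempEnd = "numeric",
                 stepsPerRound = "integer",
                 kBond = "numeric", kSS = "numeric", kPos = "numeric",
                 kRepel = "numeric", kCompact = "numeric",
                 softRadius = "numeric", maxRounds = "integer",
                 seed = "integer", mdMeta = "list")
)

setValidity("EngineConfig", function(object) {
  msg <- character()
  if (object@stepsPerRound <= 0) msg <- c(msg, "stepsPerRound must be > 0")
  if (object@tempEnd > object@tempStart)
    msg <- c(msg, "temperatures must decrease along the schedule")
  if (object@maxRounds < 1) msg <- c(msg, "maxRounds must be >= 1")
  if (length(msg)) msg else TRUE
})
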