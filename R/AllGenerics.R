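#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname accessors
#' @export
setGeneric("tauC", function(x) standardGeneric("tauC"))

#' @rdname accessors
#' @export
setGeneric("regime", function(x) standardGeneric("regime"))

#' @rdname accessors
#' @export
setGeneric("kdValue", function(x) standardGeneric("kdValue"))

#' @rdname accessors
#' @export
setGeneric("sasaValues", function(x) standardGeneric("sasaValues"))

#' Tabulate per-residue results of a model-free analysis
#'
#' @param x a [ModelFreeFit-class] object
#' @param ... unused
#' @return a data.frame with one row per residue: selected model, S2, tauI
#'   (ps), Rex (s-1), Sf2, Ss2, chi-square, convergence flag and, when
#'   Monte-Carlo uncertainties were computed, their standard deviations.
#' @export
setGeneric("resultsTable", function(x, ...) standardGeneric("resultsTable"))
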