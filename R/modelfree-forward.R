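#' Lipari-Szabo spectral density function
#'
#' Evaluates the model-free spectral density under isotropic overall
#' tumbling,
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{(S_f^2 - S^2)\,\tau}{1+(\omega\tau)^2}\right],\qquad
#'   \tau^{-1} = \tau_c^{-1} + \tau_i^{-1},}
#' which reduces to the original two-parameter form when \eqn{S_f^2 = 1}
#' (models 1-4) and to the extended form for model 5 where
#' \eqn{S^2 = S_f^2 S_s^2}. The \eqn{\tau_i = 0} case is handled as the
#' limit in which the internal term vanishes.
#'
#' @param params a [MotionParams-class] object
#' @param tauC overall rotational correlation time (seconds)
#' @param omega angular frequency (rad/s); may be a vector
#' @return J(omega) in s/rad, same length as omega
#' @examples
#' p <- motionParams(1, s2 = 1)
#' spectralDensity(p, tauC = 8.4e-9, omega = 0)  # 0.4 * tauC
#' @export
spectralDensity <- function(params, tauC, omega) {
  stopifnot(tauC > 0, all(omega >= 0))
  .jw(omega, params@s2, tauC, params@tauI, params@sf2)
}

## vectorised core (omega vector; scalar parameters)
.jw <- function(omega, s2, tauC, tauI, sf2 = 1) {
  j <- 0.4 * s2 * tauC / (1 + (omega * tauC)^2)
  if (tauI > 0 && sf2 - s2 != 0) {
    tau <- tauC * tauI / (tauC + tauI)
    j <- j + 0.4 * (sf2 - s2) * tau / (1 + (omega * tau)^2)
  }
  j
}

## J at the five canonical frequencies, as a list
.jfive <- function(s2, tauC, tauI, sf2, fc) {
  wH <- fc@omegaH; wN <- fc@omegaN
  list(j0 = .jw(0, s2, tauC, tauI, sf2),
       jN = .jw(wN, s2, tauC, tauI, sf2),
       jH = .jw(wH, s2, tauC, tauI, sf2),
       jm = .jw(wH - wN, s2, tauC, tauI, sf2),
       jp = .jw(wH + wN, s2, tauC, tauI, sf2))
}

.ratesCore <- function(s2, tauC, tauI, rex, sf2, fc) {
  J <- .jfive(s2, tauC, tauI, sf2, fc)
  d2 <- fc@d^2; c2 <- fc@c^2
  r1 <- d2 / 4 * (J$jm + 3 * J$jN + 6 * J$jp) + c2 * J$jN
  r2 <- d2 / 8 * (4 * J$j0 + J$jm + 3 * J$jN + 6 * J$jH + 6 * J$jp) +
    c2 / 6 * (4 * J$j0 + 3 * J$jN) + rex
  noe <- 1 + (d2 / (4 * pmax(r1, 1e-30))) * (fc@gammaH / fc@gammaN) *
    (6 * J$jp - J$jm)
  c(r1 = r1, r2 = r2, noe = noe)
}

#' Predict 15N relaxation observables from motional parameters
#'
#' Computes the standard 15N autorelaxation rates and heteronuclear NOE
#' from the model-free spectral density:
#' R1 = (d2/4)[J(wH-wN) + 3J(wN) + 6J(wH+wN)] + c2 J(wN);
#' R2 = (d2/8)[4J(0) + J(wH-wN) + 3J(wN) + 6J(wH) + 6J(wH+wN)]
#'   + (c2/6)[4J(0) + 3J(wN)] + Rex;
#' NOE = 1 + (d2/(4 R1))(gammaH/gammaN)[6J(wH+wN) - J(wH-wN)].
#' Rex contributes additively to R2 only.
#'
#' @param params a [MotionParams-class] object
#' @param tauC overall correlation time (seconds)
#' @param constants a [FieldConstants-class] object
#' @return named numeric: r1 (s-1), r2 (s-1), noe (dimensionless)
#' @examples
#' fc <- fieldConstants()
#' predictRelaxation(motionParams(1, s2 = 1), tauC = 9.4e-9, fc)
#' @export
predictRelaxation <- function(params, tauC, constants) {
  stopifnot(is(params, "MotionParams"), is(constants, "FieldConstants"),
            tauC > 0)
  .ratesCore(params@s2, tauC, params@tauI, params@rex, params@sf2, constants)
}

#' Filtered average relaxation times
#'
#' Averages T1 and T2 over residues whose heteronuclear NOE strictly
#' exceeds the cutoff, i.e. residues whose relaxation is not significantly
#' affected by internal motions. The boundary is exclusive: a residue with
#' NOE exactly equal to the cutoff is excluded.
#'
#' @param table a [RelaxationTable-class]
#' @param cutoff NOE cutoff (default 0.6)
#' @return list with meanT1, sdT1, meanT2, sdT2, n (residues retained)
#' @export
averageWithNoeFilter <- function(table, cutoff = 0.6) {
  d <- table@data
  if (!nrow(d)) stop("empty relaxation table")
  keep <- d$valid & d$noe > cutoff
  if (!any(keep))
    stop("all residues filtered out: no NOE above cutoff ", cutoff)
  list(meanT1 = mean(d$t1[keep]), sdT1 = stats::sd(d$t1[keep]),
       meanT2 = mean(d$t2[keep]), sdT2 = stats::sd(d$t2[keep]),
       n = sum(keep))
}
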