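#' Composite chemical shift perturbation
#'
#' Combines amide 1H and 15N shift changes into one ppm-scale value,
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2},}
#' with the conventional nitrogen weight w = 0.2. Vectorised; invariant to
#' swapping the two states and to a global reference offset applied to both.
#'
#' @param dH1,dN1 peak position(s) in state A (ppm)
#' @param dH2,dN2 peak position(s) in state B (ppm)
#' @param w nitrogen weight (default 0.2)
#' @return composite delta-delta (ppm), >= 0
#' @examples
#' computeCsp(8.0, 120, 8.5, 122)   # sqrt(0.25 + 0.16)
#' @export
computeCsp <- function(dH1, dN1, dH2, dN2, w = 0.2) {
  sqrt((dH2 - dH1)^2 + (w * (dN2 - dN1))^2)
}

#' Per-residue CSP between two peak lists
#'
#' Matches assigned residues present in both lists and reports per-axis and
#' composite shift differences.
#'
#' @param a,b [PeakList-class] objects for the two states
#' @param w nitrogen weight for the composite value
#' @return data.frame with residue, dDeltaH, dDeltaN, csp (ppm)
#' @export
cspTable <- function(a, b, w = 0.2) {
  pa <- a@peaks[!is.na(a@peaks$residue), ]
  pb <- b@peaks[!is.na(b@peaks$residue), ]
  if (anyNA(pa$residue) || anyNA(pb$residue)) stop("unassigned peak")
  m <- merge(pa, pb, by = "residue", suffixes = c(".a", ".b"))
  data.frame(residue = m$residue,
             dDeltaH = m$dH.b - m$dH.a,
             dDeltaN = m$dN.b - m$dN.a,
             csp = computeCsp(m$dH.a, m$dN.a, m$dH.b, m$dN.b, w))
}

## weighted ppm distance between peak positions
.ppmDist <- function(dH1, dN1, dH2, dN2, w = 0.2) {
  sqrt((dH1 - dH2)^2 + (w * (dN1 - dN2))^2)
}

#' Track peaks across a titration series
#'
#' Starting from the fully assigned first point (molar ratio 0), each
#' residue's peak is followed by nearest-neighbour matching in weighted ppm
#' distance with a maximum per-step jump. A peak that persists at the
#' original position while a distinct peak appears within the doubling
#' window (slow exchange: free and bound forms co-detected) is stored as a
#' two-peak trajectory. A match is declared ambiguous -- not guessed --
#' when two candidate peaks fall within the jump tolerance of one
#' trajectory, or two trajectories claim the same candidate peak.
#'
#' @param series a [TitrationSeries-class]
#' @param maxJump maximum per-step weighted jump for continuous tracking
#'   (ppm, default 0.05)
#' @param doubleWindow weighted-distance window (ppm) in which an appearing
#'   peak is interpreted as the bound form of a doubling residue
#' @param w nitrogen weight of the distance metric
#' @return named list of [PeakTrajectory-class], one per assigned residue
#' @export
trackPeaks <- function(series, maxJump = 0.05, doubleWindow = c(0.1, 2),
                       w = 0.2) {
  p0 <- series@peakLists[[1]]@peaks
  p0 <- p0[!is.na(p0$residue), ]
  if (!nrow(p0)) stop("first titration point has no assigned peaks")
  npt <- length(series@ratios)
  trajs <- lapply(seq_len(nrow(p0)), function(i) {
    pts <- data.frame(ratio = series@ratios,
                      dH = NA_real_, dN = NA_real_, height = NA_real_,
                      dH2 = NA_real_, dN2 = NA_real_, height2 = NA_real_)
    pts[1, 2:4] <- p0[i, c("dH", "dN", "height")]
    new("PeakTrajectory", residue = as.integer(p0$residue[i]), points = pts)
  })
  names(trajs) <- as.character(p0$residue)
  lastPos <- p0[, c("dH", "dN")]
  lastPos2 <- data.frame(dH = rep(NA_real_, nrow(p0)),
                         dN = rep(NA_real_, nrow(p0)))
  ambig <- rep(FALSE, nrow(p0))
  for (k in 2:npt) {
    pk <- series@peakLists[[k]]@peaks
    primMatch <- rep(NA_integer_, nrow(p0))
    for (i in seq_len(nrow(p0))) {
      d <- .ppmDist(lastPos$dH[i], lastPos$dN[i], pk$dH, pk$dN, w)
      inTol <- which(d <= maxJump)
      if (length(inTol) >= 2) { ambig[i] <- TRUE; inTol <- inTol[which.min(d[inTol])] }
      if (length(inTol) == 1) primMatch[i] <- inTol
    }
    ## two trajectories claiming one peak are both ambiguous
    dup <- primMatch[!is.na(primMatch)][duplicated(primMatch[!is.na(primMatch)])]
    ambig[primMatch %in% dup] <- TRUE
    ## second chance for unmatched trajectories: migration steps on a
    ## coarse ratio grid can exceed the strict per-step cap. A trajectory
    ## with an established drift direction may take a farther unclaimed
    ## peak provided the step continues along that direction (fast-exchange
    ## peaks move on the straight free-to-bound line); without a direction,
    ## only a uniquely nearest peak within twice the cap is taken.
    for (i in which(is.na(primMatch))) {
      d <- .ppmDist(lastPos$dH[i], lastPos$dN[i], pk$dH, pk$dN, w)
      d[stats::na.omit(primMatch)] <- Inf
      u <- c(lastPos$dH[i] - p0$dH[i], w * (lastPos$dN[i] - p0$dN[i]))
      ulen <- sqrt(sum(u^2))
      if (ulen > maxJump / 2) {
        cand <- which(d <= 10 * maxJump)
        if (length(cand)) {
          v <- cbind(pk$dH[cand] - lastPos$dH[i],
                     w * (pk$dN[cand] - lastPos$dN[i]))
          cosang <- (v %*% u) / (pmax(sqrt(rowSums(v^2)), 1e-12) * ulen)
          cand <- cand[cosang > 0.85]
        }
        if (length(cand) >= 2) {
          ## genuinely confusable only when the runner-up sits within the
          ## jump tolerance of the chosen peak
          o <- cand[order(d[cand])][1:2]
          if (.ppmDist(pk$dH[o[1]], pk$dN[o[1]],
                       pk$dH[o[2]], pk$dN[o[2]], w) <= maxJump)
            ambig[i] <- TRUE
        }
        if (length(cand)) primMatch[i] <- cand[which.min(d[cand])]
      } else {
        cand <- which(d <= 2 * maxJump)
        if (length(cand) == 1) primMatch[i] <- cand
      }
    }
    claimed <- stats::na.omit(unique(primMatch))
    for (i in seq_len(nrow(p0))) {
      j <- primMatch[i]
      if (!is.na(j)) {
        trajs[[i]]@points[k, c("dH", "dN", "height")] <-
          pk[j, c("dH", "dN", "height")]
        lastPos[i, ] <- pk[j, c("dH", "dN")]
      }
      ## follow an already-established secondary (bound-form) peak
      if (!is.na(lastPos2$dH[i])) {
        d2 <- .ppmDist(lastPos2$dH[i], lastPos2$dN[i], pk$dH, pk$dN, w)
        d2[claimed] <- Inf
        j2 <- which.min(d2)
        if (length(j2) && is.finite(d2[j2]) && d2[j2] <= maxJump) {
          trajs[[i]]@points[k, c("dH2", "dN2", "height2")] <-
            pk[j2, c("dH", "dN", "height")]
          lastPos2[i, ] <- pk[j2, c("dH", "dN")]
          claimed <- c(claimed, j2)
        }
      }
    }
    ## unclaimed appearing peaks: bound forms of doubling residues. A
    ## receiving trajectory must still hold its original peak (persisting
    ## free form) with fading intensity, and have no bound peak yet.
    rest <- setdiff(seq_len(nrow(pk)), claimed)
    persisting <- !is.na(primMatch) & is.na(lastPos2$dH) &
      .ppmDist(lastPos$dH, lastPos$dN, p0$dH, p0$dN, w) <= maxJump &
      vapply(seq_len(nrow(p0)), function(i) {
        h <- trajs[[i]]@points$height
        !is.na(h[k]) && h[k] < 0.95 * h[1]
      }, TRUE)
    for (j in rest) {
      d0 <- .ppmDist(p0$dH, p0$dN, pk$dH[j], pk$dN[j], w)
      cand <- which(persisting & d0 >= doubleWindow[1] & d0 <= doubleWindow[2])
      if (!length(cand)) next
      i <- cand[which.min(d0[cand])]
      trajs[[i]]@points[k, c("dH2", "dN2", "height2")] <-
        pk[j, c("dH", "dN", "height")]
      lastPos2[i, ] <- pk[j, c("dH", "dN")]
      persisting[i] <- FALSE
    }
  }
  for (i in seq_along(trajs)) trajs[[i]]@ambiguous <- ambig[i]
  trajs
}

#' Classify the exchange regime of a trajectory
#'
#' Labels: \code{"slow"} when peak doubling with intensity transfer is
#' observed (original peak fades, a distinct bound peak grows, both
#' essentially stationary); \code{"fast"} when a single peak migrates by
#' more than the CSP threshold; \code{"unaffected"} when the total motion
#' stays within the jitter threshold; \code{"ambiguous"} otherwise
#' (including unresolved matching). Ambiguous is a valid outcome.
#'
#' @param traj a [PeakTrajectory-class] from [trackPeaks()]
#' @param cspThreshold minimum total composite shift for "fast" (ppm)
#' @param jitter maximum position drift regarded as noise (ppm)
#' @param w nitrogen weight of the composite metric
#' @return the trajectory with its regime slot set
#' @export
classifyExchangeRegime <- function(traj, cspThreshold = 0.05, jitter = 0.02,
                                   w = 0.2) {
  pt <- traj@points
  if (traj@ambiguous) { traj@regime <- "ambiguous"; return(traj) }
  have2 <- which(!is.na(pt$dH2))
  prim <- which(!is.na(pt$dH))
  total <- .ppmDist(pt$dH[prim[1]], pt$dN[prim[1]],
                    pt$dH[prim[length(prim)]], pt$dN[prim[length(prim)]], w)
  if (length(have2)) {
    ## doubling: require intensity transfer and stationary peaks
    drift1 <- max(.ppmDist(pt$dH[prim[1]], pt$dN[prim[1]],
                           pt$dH[prim], pt$dN[prim], w))
    k2 <- have2
    drift2 <- max(.ppmDist(pt$dH2[k2[1]], pt$dN2[k2[1]],
                           pt$dH2[k2], pt$dN2[k2], w))
    h1 <- pt$height[prim]
    h2 <- pt$height2[k2]
    transfer <- h1[length(h1)] < h1[1] &&
      (length(h2) == 1 || h2[length(h2)] >= h2[1])
    if (drift1 <= jitter && drift2 <= jitter && transfer)
      traj@regime <- "slow"
    else traj@regime <- "ambiguous"
    return(traj)
  }
  if (total > cspThreshold) {
    ## migration should be progressive, not a jitter excursion
    path <- sum(.ppmDist(pt$dH[prim[-1]], pt$dN[prim[-1]],
                         pt$dH[prim[-length(prim)]],
                         pt$dN[prim[-length(prim)]], w))
    traj@regime <- if (total >= 0.6 * path) "fast" else "ambiguous"
  } else if (total <= jitter) {
    traj@regime <- "unaffected"
  } else {
    traj@regime <- "ambiguous"
  }
  traj
}

#' Fraction of protein bound in a 1:1 equilibrium
#'
#' Closed-form solution of the 1:1 binding quadratic,
#' \deqn{f_B = \frac{P + L + K_d - \sqrt{(P + L + K_d)^2 - 4PL}}{2P},}
#' monotone nondecreasing in L, nonincreasing in Kd, always in [0, 1].
#' All concentrations share one unit.
#'
#' @param P total protein concentration (> 0)
#' @param L total ligand concentration(s) (>= 0); vectorised
#' @param Kd dissociation constant (> 0)
#' @return fraction bound, same length as L
#' @examples
#' fractionBound(1, 1, 1)   # (3 - sqrt(5)) / 2
#' @export
fractionBound <- function(P, L, Kd) {
  stopifnot(P > 0, all(L >= 0), Kd > 0)
  s <- P + L + Kd
  disc <- pmax(s^2 - 4 * P * L, 0)
  pmin(pmax((s - sqrt(disc)) / (2 * P), 0), 1)
}

#' Fit a shared Kd from fast-exchange trajectories
#'
#' Global 1:1 binding fit: every fast-exchange residue's observed position
#' follows \eqn{\delta_{obs} = \delta_{free} + (\delta_{bound}-\delta_{free})
#' f_B(P, L, K_d)} on both the 1H and 15N axes, with delta-free fixed at the
#' measured ratio-0 position, per-residue bound shifts profiled out
#' linearly, and one Kd shared by all residues (1-D minimisation over log
#' Kd). When the protein concentration far exceeds Kd the binding curve is
#' concentration-limited and carries no information about Kd; this is
#' detected by comparing the best-fit binding curve with its stoichiometric
#' (Kd -> 0) limit and flagged as unidentifiable, with a correspondingly
#' wide confidence interval.
#'
#' @param trajs list of [PeakTrajectory-class] (fast-regime ones are used;
#'   others are ignored with a message)
#' @param series the [TitrationSeries-class] the trajectories came from
#' @param w nitrogen weight used to weight the two axes
#' @param kdRange log10 search range for Kd in micromolar
#' @param identTol maximum absolute difference between the fitted and the
#'   stoichiometric binding curve below which Kd is declared unidentifiable
#' @return a [BindingFit-class]; Kd in micromolar
#' @export
fitKdFastExchange <- function(trajs, series, w = 0.2,
                              kdRange = c(-5, 6), identTol = 0.01) {
  if (length(series@ratios) < 3) stop("need at least 3 titration points")
  fast <- Filter(function(t) t@regime == "fast", trajs)
  if (!length(fast)) {
    unclass_ok <- Filter(function(t) t@regime == "unclassified", trajs)
    if (length(unclass_ok))
      stop("trajectories are unclassified; run classifyExchangeRegime first")
    stop("no fast-exchange trajectories to fit")
  }
  PuM <- series@proteinConcmM * 1000          # micromolar
  LuM <- series@ratios * PuM
  ## response matrix: per residue, per axis, shift from the free position
  Y <- list()
  for (t in fast) {
    pt <- t@points
    ok <- !is.na(pt$dH)
    Y[[length(Y) + 1]] <- list(res = t@residue,
                               dh = pt$dH - pt$dH[1],
                               dn = w * (pt$dN - pt$dN[1]),
                               ok = ok)
  }
  rss <- function(log10kd) {
    fb <- fractionBound(PuM, LuM, 10^log10kd)
    s <- 0
    for (y in Y) {
      f <- fb[y$ok]
      den <- sum(f^2)
      if (den == 0) next
      bh <- sum(y$dh[y$ok] * f) / den
      bn <- sum(y$dn[y$ok] * f) / den
      s <- s + sum((y$dh[y$ok] - bh * f)^2) + sum((y$dn[y$ok] - bn * f)^2)
    }
    s
  }
  opt <- stats::optimize(rss, kdRange, tol = 1e-10)
  ## polish: optimize() can stall on long flat shoulders
  loc <- stats::optimize(rss, pmax(pmin(opt$minimum + c(-0.5, 0.5),
                                        kdRange[2]), kdRange[1]), tol = 1e-12)
  if (loc$objective < opt$objective) opt <- loc
  kd <- 10^opt$minimum
  fb <- fractionBound(PuM, LuM, kd)
  fb0 <- pmin(LuM, PuM) / PuM                 # stoichiometric limit
  identifiable <- max(abs(fb - fb0)) > identTol
  ## per-residue bound shifts at the optimum
  per <- do.call(rbind, lapply(Y, function(y) {
    f <- fb[y$ok]
    bh <- sum(y$dh[y$ok] * f) / sum(f^2)
    bn <- sum(y$dn[y$ok] * f) / sum(f^2) / w
    data.frame(residue = y$res, deltaBoundH = bh, deltaBoundN = bn)
  }))
  ## profile-likelihood CI: chi-square grid over log10 Kd
  grid <- seq(kdRange[1], kdRange[2], length.out = 161)
  prof <- vapply(grid, rss, 1)
  npts <- sum(vapply(Y, function(y) 2 * sum(y$ok), numeric(1)))
  npar <- 2 * length(Y) + 1
  s2 <- max(opt$objective, 1e-20) / max(npts - npar, 1)
  thr <- opt$objective * (1 + 1e-6) + stats::qchisq(0.95, 1) * s2 + 1e-12
  inCI <- prof <= thr
  ci <- 10^range(c(grid[inCI], opt$minimum))
  if (!identifiable) ci[1] <- 10^kdRange[1]
  new("BindingFit", kd = kd, kdCI = ci, perResidue = per,
      chisq = opt$objective, identifiable = identifiable,
      details = list(fractionBound = fb, profileGrid = grid,
                     profileRss = prof, proteinConc_uM = PuM))
}

#' Summarise binding by protein lobe
#'
#' Splits residues at the lobe boundary (N lobe residues 1..boundary, C
#' lobe boundary+1..seqLength) and reports per-lobe counts, mean composite
#' CSP, and the residues above threshold.
#'
#' @param csp data.frame with columns residue and csp (e.g. from
#'   [cspTable()])
#' @param boundary last residue of the N lobe (default 88)
#' @param seqLength protein length (default 158)
#' @param threshold CSP threshold for listing perturbed residues (ppm)
#' @return list with a per-lobe summary data.frame and the above-threshold
#'   residues per lobe
#' @export
mapBindingSite <- function(csp, boundary = 88, seqLength = 158,
                           threshold = 0.05) {
  if (any(csp$residue < 1 | csp$residue > seqLength))
    stop("residue id out of range 1..", seqLength)
  lobe <- ifelse(csp$residue <= boundary, "N", "C")
  agg <- do.call(rbind, lapply(c("N", "C"), function(l) {
    x <- csp$csp[lobe == l]
    data.frame(lobe = l, n = length(x),
               meanCsp = if (length(x)) mean(x) else NA_real_,
               maxCsp = if (length(x)) max(x) else NA_real_,
               nAboveThreshold = sum(x > threshold))
  }))
  above <- split(csp$residue[csp$csp > threshold], lobe[csp$csp > threshold])
  nAb <- sum(agg$nAboveThreshold)
  agg$fractionOfPerturbed <- if (nAb > 0) agg$nAboveThreshold / nAb else NA
  list(summary = agg, perturbed = above)
}
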