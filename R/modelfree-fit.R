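## ---- vectorised forward model over residues -------------------------------

## J(omega) for vectors of parameters (scalar omega, scalar tauC seconds)
.jwVec <- function(omega, s2, tauC, tauI, sf2) {
  tau <- tauC * tauI / (tauC + tauI)   # 0 when tauI == 0
  0.4 * s2 * tauC / (1 + (omega * tauC)^2) +
    0.4 * (sf2 - s2) * tau / (1 + (omega * tau)^2)
}

## n x 3 matrix of (R1, R2, NOE) for parameter vectors
.ratesVec <- function(s2, tauC, tauI, rex, sf2, fc) {
  wH <- fc@omegaH; wN <- fc@omegaN
  j0 <- .jwVec(0, s2, tauC, tauI, sf2)
  jN <- .jwVec(wN, s2, tauC, tauI, sf2)
  jH <- .jwVec(wH, s2, tauC, tauI, sf2)
  jm <- .jwVec(wH - wN, s2, tauC, tauI, sf2)
  jp <- .jwVec(wH + wN, s2, tauC, tauI, sf2)
  d2 <- fc@d^2; c2 <- fc@c^2
  r1 <- d2 / 4 * (jm + 3 * jN + 6 * jp) + c2 * jN
  r2 <- d2 / 8 * (4 * j0 + jm + 3 * jN + 6 * jH + 6 * jp) +
    c2 / 6 * (4 * j0 + 3 * jN) + rex
  ## r1 floored to keep the NOE defined in the degenerate all-J-zero corner
  noe <- 1 + (d2 / (4 * pmax(r1, 1e-30))) * (fc@gammaH / fc@gammaN) *
    (6 * jp - jm)
  cbind(r1, r2, noe)
}

## predicted observables for model `m`, parameter matrix P (tauI column in ns)
.mfPredict <- function(m, P, tauC, fc) {
  n <- nrow(P)
  z <- numeric(n); one <- rep(1, n)
  switch(m,
    .ratesVec(P[, 1], tauC, z, z, one, fc),                      # 1
    .ratesVec(P[, 1], tauC, P[, 2] * 1e-9, z, one, fc),          # 2
    .ratesVec(P[, 1], tauC, z, P[, 2], one, fc),                 # 3
    .ratesVec(P[, 1], tauC, P[, 2] * 1e-9, P[, 3], one, fc),     # 4
    .ratesVec(P[, 1] * P[, 2], tauC, P[, 3] * 1e-9, z, P[, 1], fc)) # 5
}

.mfNpar <- c(1L, 2L, 2L, 3L, 3L)

## tauI bounds are [0, tauC]; zero is admitted so that every richer model
## can embed the simpler ones exactly (chi-square nesting of the ladder)
.mfBounds <- function(m, tauC) {
  tauCns <- tauC * 1e9
  switch(m,
    list(lower = 0, upper = 1),
    list(lower = c(0, 0), upper = c(1, tauCns)),
    list(lower = c(0, 0), upper = c(1, 20)),
    list(lower = c(0, 0, 0), upper = c(1, tauCns, 20)),
    list(lower = c(0, 0, 0), upper = c(1, 1, tauCns)))
}

## deterministic start grids (tauI in ns); the cheap chi-square screen over
## the grid stands in for random multi-starts, the best few rows get polished
.mfStarts <- function(m) {
  g <- function(...) unname(as.matrix(expand.grid(...)))
  switch(m,
    cbind(c(0.98, 0.9, 0.8, 0.65, 0.5, 0.35, 0.2)),
    g(s2 = c(0.9, 0.8, 0.65, 0.5, 0.35),
      ti = c(0.01, 0.03, 0.1, 0.3, 1, 2.5, 5)),
    g(s2 = c(0.95, 0.85, 0.7, 0.5, 0.35), rex = c(0.5, 2, 5, 10, 16)),
    g(s2 = c(0.5, 0.7, 0.85, 0.95), ti = c(0.03, 0.3, 1, 3),
      rex = c(1, 4, 10)),
    g(sf2 = c(0.95, 0.85, 0.7), ss2 = c(0.45, 0.65, 0.9),
      ti = c(0.1, 0.5, 2, 5)))
}

## closed-form solve of (A + lam*diag(A)) d = -g for p in 1..3, vectorised
## A: n x p x p array, g: n x p, lam: n
.solveSmallDamped <- function(A, g, lam, p) {
  n <- dim(A)[1]
  D <- matrix(0, n, p)
  if (p == 1L) {
    a <- A[, 1, 1] * (1 + lam)
    D[, 1] <- -g[, 1] / pmax(a, 1e-300)
  } else if (p == 2L) {
    a <- A[, 1, 1] * (1 + lam); b <- A[, 1, 2]
    d <- A[, 2, 2] * (1 + lam)
    det <- a * d - b * b
    det[abs(det) < 1e-300] <- 1e-300
    D[, 1] <- (-g[, 1] * d + g[, 2] * b) / det
    D[, 2] <- (g[, 1] * b - g[, 2] * a) / det
  } else {
    a11 <- A[, 1, 1] * (1 + lam); a22 <- A[, 2, 2] * (1 + lam)
    a33 <- A[, 3, 3] * (1 + lam)
    a12 <- A[, 1, 2]; a13 <- A[, 1, 3]; a23 <- A[, 2, 3]
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    det[abs(det) < 1e-300] <- 1e-300
    i11 <- (a22 * a33 - a23^2) / det
    i12 <- (a13 * a23 - a12 * a33) / det
    i13 <- (a12 * a23 - a13 * a22) / det
    i22 <- (a11 * a33 - a13^2) / det
    i23 <- (a13 * a12 - a11 * a23) / det
    i33 <- (a11 * a22 - a12^2) / det
    D[, 1] <- -(i11 * g[, 1] + i12 * g[, 2] + i13 * g[, 3])
    D[, 2] <- -(i12 * g[, 1] + i22 * g[, 2] + i23 * g[, 3])
    D[, 3] <- -(i13 * g[, 1] + i23 * g[, 2] + i33 * g[, 3])
  }
  D
}

## Levenberg-Marquardt over all residues at once (projected onto box bounds)
.lmFitVec <- function(m, P, obs, sig, tauC, fc, maxit = 60L) {
  b <- .mfBounds(m, tauC)
  p <- ncol(P); n <- nrow(P)
  clamp <- function(M) {
    for (j in seq_len(p))
      M[, j] <- pmin(pmax(M[, j], b$lower[j]), b$upper[j])
    M
  }
  P <- clamp(P)
  R <- (.mfPredict(m, P, tauC, fc) - obs) / sig
  chi <- rowSums(R * R)
  chi[!is.finite(chi)] <- Inf
  lam <- rep(1e-3, n)
  stall <- 0L
  for (it in seq_len(maxit)) {
    if (it > 1 && all(lam > 1e8)) break
    A <- array(0, c(n, p, p)); G <- matrix(0, n, p)
    J <- vector("list", p)
    for (j in seq_len(p)) {
      h <- pmax(1e-6 * abs(P[, j]), 1e-9)
      over <- P[, j] + h > b$upper[j]
      h[over] <- -h[over]
      Pj <- P; Pj[, j] <- P[, j] + h
      J[[j]] <- ((.mfPredict(m, Pj, tauC, fc) - obs) / sig - R) / h
    }
    for (j in seq_len(p)) {
      G[, j] <- rowSums(J[[j]] * R)
      for (k in j:p) {
        A[, j, k] <- rowSums(J[[j]] * J[[k]])
        if (k > j) A[, k, j] <- A[, j, k]
      }
    }
    D <- .solveSmallDamped(A, G, lam, p)
    Pn <- clamp(P + D)
    Rn <- (.mfPredict(m, Pn, tauC, fc) - obs) / sig
    chin <- rowSums(Rn * Rn)
    better <- is.finite(chin) & chin <= chi
    imp <- ifelse(better, pmax(chi - chin, 0), 0)
    imp[!is.finite(imp)] <- 0
    lam <- ifelse(better, pmax(lam / 4, 1e-12), pmin(lam * 6, 1e10))
    P[better, ] <- Pn[better, , drop = FALSE]
    R[better, ] <- Rn[better, , drop = FALSE]
    chi[better] <- chin[better]
    ## converged when improvements are negligible for a few sweeps
    if (max(imp) <= 1e-10 * max(max(chi), 1e-20)) {
      stall <- stall + 1L
      if (stall >= 3L) break
    } else stall <- 0L
  }
  list(P = P, chisq = chi, iterations = it)
}

## run LM from the best of the start grid, then from optional warm starts;
## keep the per-residue best
.fitModelVec <- function(m, obs, sig, tauC, fc, warm = list(), topK = 3L) {
  S <- .mfStarts(m)
  n <- nrow(obs); p <- ncol(S)
  best <- NULL; bestChi <- rep(Inf, n)
  startChi <- matrix(Inf, n, nrow(S))
  for (s in seq_len(nrow(S))) {
    P <- matrix(S[s, ], n, p, byrow = TRUE)
    R <- (.mfPredict(m, P, tauC, fc) - obs) / sig
    ch <- rowSums(R * R)
    ch[!is.finite(ch)] <- Inf
    startChi[, s] <- ch
  }
  ord <- apply(startChi, 1, order)        # nrow(S) x n
  starts <- lapply(seq_len(min(topK, nrow(S))), function(k)
    S[ord[k, ], , drop = FALSE])
  for (start in c(starts, warm)) {
    fit <- .lmFitVec(m, start, obs, sig, tauC, fc)
    take <- fit$chisq < bestChi
    if (is.null(best)) { best <- fit$P; bestChi <- fit$chisq }
    else {
      best[take, ] <- fit$P[take, , drop = FALSE]
      bestChi[take] <- fit$chisq[take]
    }
  }
  list(P = best, chisq = bestChi)
}

## observables and uncertainties from a relaxation table (valid rows)
.tableToRates <- function(d) {
  obs <- cbind(r1 = 1000 / d$t1, r2 = 1000 / d$t2, noe = d$noe)
  sig <- cbind(1000 * d$t1err / d$t1^2, 1000 * d$t2err / d$t2^2, d$noeerr)
  fallback <- pmax(1e-6 * abs(obs), 1e-12)
  bad <- !(is.finite(sig) & sig > 0)
  sig[bad] <- fallback[bad]
  list(obs = obs, sig = sig)
}

## all five models for all residues; returns per-model params and chisq
.fitAllModels <- function(obs, sig, tauC, fc) {
  ## each richer model is warm-started at the exact embedding of its nested
  ## simpler models, so the chi-square ladder ordering holds by construction
  n <- nrow(obs)
  z <- rep(0, n)
  f1 <- .fitModelVec(1L, obs, sig, tauC, fc)
  w2 <- list(cbind(f1$P[, 1], z))
  f2 <- .fitModelVec(2L, obs, sig, tauC, fc, warm = w2)
  w3 <- list(cbind(f1$P[, 1], z))
  f3 <- .fitModelVec(3L, obs, sig, tauC, fc, warm = w3)
  w4 <- list(cbind(f2$P[, 1], f2$P[, 2], z),
             cbind(f3$P[, 1], z, f3$P[, 2]))
  f4 <- .fitModelVec(4L, obs, sig, tauC, fc, warm = w4)
  w5 <- list(cbind(rep(1, n), f2$P[, 1], f2$P[, 2]))
  f5 <- .fitModelVec(5L, obs, sig, tauC, fc, warm = w5)
  list(f1, f2, f3, f4, f5)
}

## model selection over the chisq matrix (n x 5)
.selectModels <- function(chisq, selection = c("ftest", "aic"), alpha = 0.05) {
  selection <- match.arg(selection)
  n <- nrow(chisq)
  if (selection == "aic") {
    aic <- sweep(chisq, 2, 2 * .mfNpar, "+")
    return(max.col(-aic, ties.method = "first"))
  }
  sel <- integer(n)
  ad1 <- stats::pchisq(chisq[, 1], df = 2, lower.tail = FALSE) > alpha
  ad2 <- stats::pchisq(chisq[, 2], df = 1, lower.tail = FALSE) > alpha
  ad3 <- stats::pchisq(chisq[, 3], df = 1, lower.tail = FALSE) > alpha
  sel[ad1] <- 1L
  two <- !ad1 & (ad2 | ad3)
  pick23 <- ifelse(ad2 & ad3, ifelse(chisq[, 2] <= chisq[, 3], 2L, 3L),
                   ifelse(ad2, 2L, 3L))
  sel[two] <- pick23[two]
  rest <- sel == 0L
  sel[rest] <- ifelse(chisq[rest, 4] <= chisq[rest, 5] + 1e-10, 4L, 5L)
  sel
}

.paramsFromRow <- function(m, prow) {
  prow <- unname(prow)
  switch(m,
    motionParams(1L, s2 = prow[1]),
    motionParams(2L, s2 = prow[1], tauI = prow[2] * 1e-9),
    motionParams(3L, s2 = prow[1], rex = prow[2]),
    motionParams(4L, s2 = prow[1], tauI = prow[2] * 1e-9, rex = prow[3]),
    motionParams(5L, sf2 = prow[1], ss2 = prow[2], tauI = prow[3] * 1e-9))
}

## Monte-Carlo uncertainties for selected models, grouped by model id.
## Returns list (by residue index) of named sd vectors.
.mcUncertainties <- function(obs, sig, sel, fits, tauC, fc, draws) {
  n <- nrow(obs)
  out <- rep(list(numeric(0)), n)
  parNames <- list("s2", c("s2", "tauI"), c("s2", "rex"),
                   c("s2", "tauI", "rex"), c("sf2", "ss2", "tauI"))
  for (m in 1:5) {
    idx <- which(sel == m)
    if (!length(idx)) next
    k <- length(idx)
    big <- matrix(stats::rnorm(k * draws * 3), k * draws, 3)
    obsMC <- obs[rep(idx, each = draws), , drop = FALSE] +
      big * sig[rep(idx, each = draws), , drop = FALSE]
    sigMC <- sig[rep(idx, each = draws), , drop = FALSE]
    P0 <- fits[[m]]$P[rep(idx, each = draws), , drop = FALSE]
    fit <- .lmFitVec(m, P0, obsMC, sigMC, tauC, fc, maxit = 30L)
    p <- ncol(P0)
    for (j in seq_along(idx)) {
      rows <- ((j - 1) * draws + 1):(j * draws)
      sds <- apply(fit$P[rows, , drop = FALSE], 2, stats::sd)
      nm <- parNames[[m]]
      if ("tauI" %in% nm) sds[match("tauI", nm)] <-
          sds[match("tauI", nm)] * 1e-9   # back to seconds
      names(sds) <- nm
      out[[idx[j]]] <- sds
    }
  }
  out
}

## ---- exported operations ---------------------------------------------------

#' Fit a mono-exponential decay to peak intensities
#'
#' Fits I(t) = I0 exp(-t/T) to a series of peak intensities by nonlinear
#' least squares, as used to extract T1 and T2 from relaxation delay series.
#'
#' @param delay delay times (ms), length >= 3
#' @param intensity peak intensities (arbitrary units)
#' @param error optional intensity uncertainties (same units)
#' @param mcDraws optional Monte-Carlo draws for the uncertainty of T
#'   (default 0: use the covariance-based estimate)
#' @return list with T (ms), error (ms), i0, chisq and ok; \code{ok} is
#'   FALSE for a non-decaying series, in which case T is NA and the residue
#'   should be excluded downstream
#' @examples
#' t <- c(10, 100, 250, 500, 750, 1000, 1500, 1800)
#' fitExponentialDecay(t, 100 * exp(-t / 475.7))$T
#' @export
fitExponentialDecay <- function(delay, intensity, error = NULL, mcDraws = 0) {
  stopifnot(length(delay) >= 3, length(delay) == length(intensity))
  if (intensity[which.min(delay)] <= 0)
    stop("intensity at the shortest delay must be positive")
  sig <- if (is.null(error)) rep(1, length(delay)) else error
  sig[!(is.finite(sig) & sig > 0)] <- max(1e-6 * max(abs(intensity)), 1e-12)
  pos <- intensity > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm.fit(cbind(1, delay[pos]), log(intensity[pos]))
    slope <- lf$coefficients[2]; icpt <- lf$coefficients[1]
  } else slope <- 1
  if (!is.finite(slope) || slope >= 0)
    return(list(T = NA_real_, error = NA_real_, i0 = NA_real_,
                chisq = NA_real_, ok = FALSE))
  start <- c(i0 = exp(icpt), T = -1 / slope)
  resid <- function(p) (p[1] * exp(-delay / p[2]) - intensity) / sig
  fit <- minpack.lm::nls.lm(par = start, fn = resid,
                            lower = c(1e-12, 1e-6),
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-14, ptol = 1e-14, maxiter = 200))
  p <- fit$par
  chisq <- sum(fit$fvec^2)
  nfree <- length(delay) - 2
  covscale <- if (is.null(error) && nfree > 0) chisq / nfree else 1
  Terr <- tryCatch({
    cv <- covscale * solve(fit$hessian)
    sqrt(abs(cv[2, 2]))
  }, error = function(e) NA_real_)
  if (mcDraws > 0) {
    Ts <- replicate(mcDraws, {
      y <- p[1] * exp(-delay / p[2]) + stats::rnorm(length(delay), 0, sig)
      r <- function(q) (q[1] * exp(-delay / q[2]) - y) / sig
      minpack.lm::nls.lm(par = p, fn = r)$par[2]
    })
    Terr <- stats::sd(Ts)
  }
  list(T = unname(p[2]), error = unname(Terr), i0 = unname(p[1]),
       chisq = chisq, ok = TRUE)
}

#' Estimate the global rotational correlation time
#'
#' Estimates tauC under rigid isotropic tumbling from the T1/T2 ratios of
#' residues whose relaxation is dominated by overall tumbling: residues
#' with NOE above the cutoff and not flagged as bearing chemical exchange.
#' The 10 percent trimmed mean of the per-residue T1/T2 ratios is
#' root-solved against the rigid-rotor (S2 = 1, tauI = 0, Rex = 0) ratio
#' curve.
#'
#' @param table a [RelaxationTable-class]
#' @param constants a [FieldConstants-class]
#' @param exclude integer residue ids to exclude (exchange-flagged)
#' @param noeCutoff NOE retention cutoff (default 0.6, strict inequality)
#' @param trim trimming fraction for the ratio mean (default 0.1)
#' @param interval search interval for tauC in ns
#' @return tauC in nanoseconds
#' @export
estimateGlobalTauC <- function(table, constants, exclude = integer(),
                               noeCutoff = 0.6, trim = 0.1,
                               interval = c(0.3, 60)) {
  d <- table@data
  keep <- d$valid & d$noe > noeCutoff & !(d$residue %in% exclude)
  if (sum(keep) < 5)
    stop("insufficient data: fewer than 5 usable residues after filtering")
  target <- mean(d$t1[keep] / d$t2[keep], trim = trim)
  f <- function(tcns) {
    r <- .ratesCore(1, tcns * 1e-9, 0, 0, 1, constants)
    r[["r2"]] / r[["r1"]] - target
  }
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) > 0) return(lo)
  while (f(hi) < 0 && hi < 500) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Fit the five model-free models to one residue
#'
#' Fits all five Lipari-Szabo parameterisations to a residue's (R1, R2,
#' NOE) observables by bounded Levenberg-Marquardt least squares with
#' multiple deterministic starts (simple-model solutions seed the richer
#' models, which also enforces the chi-square nesting of the ladder), then
#' selects the simplest adequate model.
#'
#' Selection criteria: \code{"ftest"} walks the ladder from simple to
#' complex using a chi-square goodness-of-fit test at level alpha on the
#' models that retain residual degrees of freedom (models 1-3), stepping up
#' to the exactly-determined three-parameter models 4/5 only when no
#' simpler model is adequate; \code{"aic"} minimises chisq + 2k.
#'
#' @param record one residue's measurements: a one-row
#'   [RelaxationTable-class], or a list/data.frame row with fields residue,
#'   t1, t1err, t2, t2err, noe, noeerr
#' @param tauC global correlation time (seconds)
#' @param constants a [FieldConstants-class]
#' @param selection "ftest" (default) or "aic"
#' @param alpha significance level of the adequacy test
#' @param mcDraws Monte-Carlo draws for parameter uncertainties (500 is the
#'   recommended protocol; 0 skips the computation)
#' @return a [ModelFitResult-class]
#' @export
fitResidueModels <- function(record, tauC, constants,
                             selection = c("ftest", "aic"), alpha = 0.05,
                             mcDraws = 0) {
  selection <- match.arg(selection)
  if (is(record, "RelaxationTable")) record <- record@data
  record <- as.list(record)
  d <- data.frame(t1 = record$t1, t1err = record$t1err, t2 = record$t2,
                  t2err = record$t2err, noe = record$noe,
                  noeerr = record$noeerr)
  stopifnot(nrow(d) == 1, all(is.finite(unlist(d))))
  rr <- .tableToRates(d)
  fits <- .fitAllModels(rr$obs, rr$sig, tauC, constants)
  chisq <- do.call(cbind, lapply(fits, `[[`, "chisq"))
  sel <- .selectModels(chisq, selection, alpha)
  unc <- if (mcDraws > 0)
    .mcUncertainties(rr$obs, rr$sig, sel, fits, tauC, constants, mcDraws)[[1]]
  else numeric(0)
  m <- sel[1]
  new("ModelFitResult",
      residue = as.integer(record$residue %||% NA_integer_),
      params = .paramsFromRow(m, fits[[m]]$P[1, ]),
      chisq = chisq[1, m],
      modelTable = data.frame(model = 1:5, chisq = chisq[1, ],
                              npar = .mfNpar,
                              selected = (1:5) == m),
      uncertainties = unc,
      converged = is.finite(chisq[1, m]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the five model-free models to every residue of a table
#'
#' Batch version of [fitResidueModels()] at a fixed global correlation
#' time: fits all five models to every valid residue and applies the
#' selection criterion.
#'
#' @inheritParams runModelFree
#' @param tauC global correlation time (seconds)
#' @return data.frame with one row per residue: selected model, parameters
#'   (tauI in seconds), chi-square of the selected model, and the
#'   per-model chi-squares (chisq1..chisq5)
#' @export
fitAllResidues <- function(table, tauC, constants,
                           selection = c("ftest", "aic"), alpha = 0.05) {
  selection <- match.arg(selection)
  d <- table@data[table@data$valid, , drop = FALSE]
  rr <- .tableToRates(d)
  fits <- .fitAllModels(rr$obs, rr$sig, tauC, constants)
  chisq <- do.call(cbind, lapply(fits, `[[`, "chisq"))
  sel <- .selectModels(chisq, selection, alpha)
  n <- nrow(d)
  out <- data.frame(residue = d$residue, model = sel,
                    s2 = NA_real_, tauI = 0, rex = 0,
                    sf2 = 1, ss2 = NA_real_,
                    chisq = chisq[cbind(seq_len(n), sel)])
  for (m in 1:5) {
    i <- which(sel == m)
    if (!length(i)) next
    P <- fits[[m]]$P[i, , drop = FALSE]
    if (m == 5L) {
      out$sf2[i] <- P[, 1]; out$ss2[i] <- P[, 2]
      out$s2[i] <- P[, 1] * P[, 2]; out$tauI[i] <- P[, 3] * 1e-9
    } else {
      out$s2[i] <- P[, 1]; out$ss2[i] <- P[, 1]
      if (m %in% c(2L, 4L)) out$tauI[i] <- P[, 2] * 1e-9
      if (m == 3L) out$rex[i] <- P[, 2]
      if (m == 4L) out$rex[i] <- P[, 3]
    }
  }
  colnames(chisq) <- paste0("chisq", 1:5)
  cbind(out, chisq)
}

#' Run the full model-free analysis
#'
#' Alternates global correlation-time estimation and per-residue model
#' fitting until tauC changes by less than \code{tolTauC} (relative)
#' between iterations. An initial tauC estimate is obtained after removing
#' residues that carry a chemical exchange term, identified in a pre-pass
#' as residues for which the model-3 fit improves on model 1 at level
#' alpha; the exchange set is refreshed from the selected models at each
#' iteration. Isotropic tumbling is assumed throughout.
#'
#' @param table a [RelaxationTable-class]
#' @param constants a [FieldConstants-class]
#' @param selection model selection criterion, see [fitResidueModels()]
#' @param alpha significance level for adequacy/exchange tests
#' @param noeCutoff NOE cutoff for the tauC estimation subset
#' @param tolTauC relative tauC convergence tolerance (default 0.005)
#' @param maxIter maximum tauC iterations (default 20); hitting the cap
#'   returns the result with a warning and \code{converged = FALSE}
#' @param mcDraws Monte-Carlo uncertainty draws per residue (0 = off;
#'   500 is the recommended protocol for final analyses)
#' @return a [ModelFreeFit-class]
#' @export
runModelFree <- function(table, constants, selection = c("ftest", "aic"),
                         alpha = 0.05, noeCutoff = 0.6, tolTauC = 0.005,
                         maxIter = 20L, mcDraws = 0) {
  selection <- match.arg(selection)
  d <- table@data[table@data$valid, , drop = FALSE]
  if (nrow(d) < 5) stop("insufficient data: fewer than 5 valid residues")
  rr <- .tableToRates(d)
  crit <- stats::qchisq(1 - alpha, df = 1)

  tau0 <- estimateGlobalTauC(table, constants, noeCutoff = noeCutoff) * 1e-9
  ## exchange pre-pass: does adding Rex improve model 1 significantly?
  f1 <- .fitModelVec(1L, rr$obs, rr$sig, tau0, constants)
  f3 <- .fitModelVec(3L, rr$obs, rr$sig, tau0, constants,
                     warm = list(cbind(f1$P[, 1], 0.01)))
  exch <- d$residue[(f1$chisq - f3$chisq) > crit]
  tau <- estimateGlobalTauC(table, constants, exclude = exch,
                            noeCutoff = noeCutoff) * 1e-9
  history <- tau * 1e9
  converged <- FALSE
  fits <- sel <- chisq <- NULL
  for (it in seq_len(maxIter)) {
    fits <- .fitAllModels(rr$obs, rr$sig, tau, constants)
    chisq <- do.call(cbind, lapply(fits, `[[`, "chisq"))
    sel <- .selectModels(chisq, selection, alpha)
    exch <- d$residue[sel %in% c(3L, 4L)]
    tauNew <- tryCatch(
      estimateGlobalTauC(table, constants, exclude = exch,
                         noeCutoff = noeCutoff) * 1e-9,
      error = function(e) tau)
    history <- c(history, tauNew * 1e9)
    done <- abs(tauNew - tau) / tau < tolTauC
    tau <- tauNew
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("tauC iteration did not converge within ", maxIter, " iterations")
    fits <- .fitAllModels(rr$obs, rr$sig, tau, constants)
    chisq <- do.call(cbind, lapply(fits, `[[`, "chisq"))
    sel <- .selectModels(chisq, selection, alpha)
  }
  unc <- if (mcDraws > 0)
    .mcUncertainties(rr$obs, rr$sig, sel, fits, tau, constants, mcDraws)
  else rep(list(numeric(0)), nrow(d))
  resFits <- lapply(seq_len(nrow(d)), function(i) {
    m <- sel[i]
    new("ModelFitResult", residue = as.integer(d$residue[i]),
        params = .paramsFromRow(m, fits[[m]]$P[i, ]),
        chisq = chisq[i, m],
        modelTable = data.frame(model = 1:5, chisq = chisq[i, ],
                                npar = .mfNpar, selected = (1:5) == m),
        uncertainties = unc[[i]], converged = is.finite(chisq[i, m]))
  })
  new("ModelFreeFit", tauC = tau * 1e9, fits = resFits, history = history,
      converged = converged, constants = constants)
}
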