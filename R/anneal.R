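## Coarse backbone potential and simulated-annealing relaxation engine.
##
## The potential is built entirely from pairwise harmonic distance
## restraints (bonds, 1-3 angle distances, peptide-planarity CA-CA,
## helix i/i+2, i/i+3 and O..N i/i+4 restraints), weak positional
## restraints on conserved atoms, soft-sphere repulsion between nonbonded
## atoms, and a weak compaction term pulling atoms toward the centroid.
## Every term has an analytic gradient, so each annealing round is a
## temperature-scaled random kick followed by L-BFGS minimisation.

## ideal target distances, measured once from ideal builds
.idealTargetsCache <- new.env(parent = emptyenv())
.idealTargets <- function() {
  if (!is.null(.idealTargetsCache$t)) return(.idealTargetsCache$t)
  dp <- idealBackbone("AA", "CC")
  a <- dp@atoms
  pos <- function(rn, el) as.numeric(a[a$resno == rn & a$elety == el,
                                       c("x", "y", "z")])
  d <- function(p, q) sqrt(sum((p - q)^2))
  hx <- idealBackbone(strrep("A", 8), strrep("H", 8))@atoms
  hpos <- function(rn, el) as.numeric(hx[hx$resno == rn & hx$elety == el,
                                         c("x", "y", "z")])
  t <- list(
    bNCA = .GEO$bNCA, bCAC = .GEO$bCAC, bCO = .GEO$bCO, bCN = .GEO$bCN,
    dNC = d(pos(1, "N"), pos(1, "C")),        # 1-3 via CA
    dCAO = d(pos(1, "CA"), pos(1, "O")),      # 1-3 via C
    dCAN1 = d(pos(1, "CA"), pos(2, "N")),     # 1-3 via C(i)
    dON1 = d(pos(1, "O"), pos(2, "N")),       # 1-3 via C(i)
    dCCA1 = d(pos(1, "C"), pos(2, "CA")),     # 1-3 via N(i+1)
    dCACA = d(pos(1, "CA"), pos(2, "CA")),    # omega planarity
    hCACA2 = d(hpos(1, "CA"), hpos(3, "CA")),
    hCACA3 = d(hpos(1, "CA"), hpos(4, "CA")),
    hON4 = d(hpos(1, "O"), hpos(5, "N")))
  .idealTargetsCache$t <- t
  t
}

## atom index lookup key
.akey <- function(chain, resno, elety) paste(chain, resno, elety, sep = ":")

## Build the restraint context for a model.
## conservedRef: list(key = character keys, X0 = matrix) positional targets.
## ssMap: named list by chain of data.frame(resno, ss) covering residues
## whose secondary structure should be restrained.
.buildContext <- function(model, engine, conservedRef = NULL, tether = NULL) {
  a <- model@atoms
  n <- nrow(a)
  key <- .akey(a$chain, a$resno, a$elety)
  idx <- stats::setNames(seq_len(n), key)
  tg <- .idealTargets()
  pi <- integer(); pj <- integer(); pd0 <- numeric(); pk <- numeric()
  add <- function(k1, k2, d0, k) {
    i <- idx[k1]; j <- idx[k2]
    ok <- !is.na(i) & !is.na(j)
    pi <<- c(pi, i[ok]); pj <<- c(pj, j[ok])
    pd0 <<- c(pd0, rep_len(d0, sum(ok))); pk <<- c(pk, rep_len(k, sum(ok)))
  }
  ssVec <- character(n)  # per-atom ss (by residue), "" when unknown
  for (ch in unique(a$chain)) {
    res <- sort(unique(a$resno[a$chain == ch]))
    K <- function(rn, el) .akey(ch, rn, el)
    ## within-residue terms
    add(K(res, "N"), K(res, "CA"), tg$bNCA, engine@kBond)
    add(K(res, "CA"), K(res, "C"), tg$bCAC, engine@kBond)
    add(K(res, "C"), K(res, "O"), tg$bCO, engine@kBond)
    add(K(res, "N"), K(res, "C"), tg$dNC, engine@kBond / 2)
    add(K(res, "CA"), K(res, "O"), tg$dCAO, engine@kBond / 2)
    ## peptide junctions between numbering-consecutive residues
    prev <- res[which(diff(res) == 1)]
    if (length(prev)) {
      nxt <- prev + 1L
      add(K(prev, "C"), K(nxt, "N"), tg$bCN, engine@kBond)
      add(K(prev, "CA"), K(nxt, "N"), tg$dCAN1, engine@kBond / 2)
      add(K(prev, "O"), K(nxt, "N"), tg$dON1, engine@kBond / 2)
      add(K(prev, "C"), K(nxt, "CA"), tg$dCCA1, engine@kBond / 2)
      add(K(prev, "CA"), K(nxt, "CA"), tg$dCACA, engine@kBond / 2)
    }
    ## helical runs: i/i+2, i/i+3 CA distances and i/i+4 H-bond surrogates
    ss <- model@ss[[ch]]
    if (!is.null(ss)) {
      sschars <- strsplit(ss, "")[[1]]
      ssres <- res[seq_along(sschars)]   # ss string parallels residue order
      hres <- ssres[sschars == "H"]
      for (gap in c(2L, 3L, 4L)) {
        i1 <- hres[(hres + gap) %in% hres]
        ## only restrain within contiguous helical runs
        contig <- vapply(i1, function(r) all((r:(r + gap)) %in% hres), TRUE)
        i1 <- i1[contig]
        if (!length(i1)) next
        if (gap == 2L) add(K(i1, "CA"), K(i1 + 2L, "CA"), tg$hCACA2, engine@kSS)
        if (gap == 3L) add(K(i1, "CA"), K(i1 + 3L, "CA"), tg$hCACA3, engine@kSS)
        if (gap == 4L) add(K(i1, "O"), K(i1 + 4L, "N"), tg$hON4, engine@kSS)
      }
    }
  }
  if (!is.null(tether))
    add(tether$k1, tether$k2, tether$d0, tether$k)
  ## positional restraints
  posIdx <- integer(0); posX0 <- NULL
  if (!is.null(conservedRef)) {
    hit <- match(conservedRef$key, key)
    ok <- !is.na(hit)
    posIdx <- hit[ok]
    posX0 <- conservedRef$X0[ok, , drop = FALSE]
  }
  ## soft-sphere exclusion: same or numbering-adjacent residue in one chain
  resid <- as.integer(factor(a$chain)) * 100000L + a$resno
  excl <- abs(outer(resid, resid, "-")) <= 1L
  excl[cbind(pi, pj)] <- TRUE
  excl[cbind(pj, pi)] <- TRUE
  list(n = n, pi = pi, pj = pj, pd0 = pd0, pk = pk,
       posIdx = posIdx, posX0 = posX0, kPos = engine@kPos,
       excl = excl,
       upper = upper.tri(matrix(0, n, n)),
       r0 = engine@softRadius, kRepel = engine@kRepel,
       kCompact = engine@kCompact)
}

## energy and gradient of the coarse potential
.engineEval <- function(x, ctx) {
  X <- matrix(x, ctx$n, 3)
  G <- matrix(0, ctx$n, 3)
  ## pairwise harmonic restraints
  V <- X[ctx$pi, , drop = FALSE] - X[ctx$pj, , drop = FALSE]
  d <- sqrt(rowSums(V * V))
  d <- pmax(d, 1e-9)
  dev <- d - ctx$pd0
  e <- sum(ctx$pk * dev^2)
  gv <- (2 * ctx$pk * dev / d) * V
  gi <- rowsum(rbind(gv, -gv), c(ctx$pi, ctx$pj))
  rows <- as.integer(rownames(gi))
  G[rows, ] <- G[rows, ] + gi
  ## positional restraints
  if (length(ctx$posIdx)) {
    D <- X[ctx$posIdx, , drop = FALSE] - ctx$posX0
    e <- e + ctx$kPos * sum(D * D)
    gp <- rowsum(2 * ctx$kPos * D, ctx$posIdx)
    rp <- as.integer(rownames(gp))
    G[rp, ] <- G[rp, ] + gp
  }
  ## soft-sphere repulsion between non-bonded atoms
  x2 <- rowSums(X * X)
  D2 <- outer(x2, x2, "+") - 2 * tcrossprod(X)
  hit <- which(ctx$upper & !ctx$excl & D2 < ctx$r0^2, arr.ind = TRUE)
  if (nrow(hit)) {
    i <- hit[, 1]; j <- hit[, 2]
    V <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    d <- pmax(sqrt(rowSums(V * V)), 1e-9)
    pen <- ctx$r0 - d
    e <- e + ctx$kRepel * sum(pen^2)
    gv <- (-2 * ctx$kRepel * pen / d) * V
    gs <- rowsum(rbind(gv, -gv), c(i, j))
    rs <- as.integer(rownames(gs))
    G[rs, ] <- G[rs, ] + gs
  }
  ## compaction toward the centroid
  C <- sweep(X, 2, colMeans(X))
  e <- e + ctx$kCompact * sum(C * C)
  G <- G + 2 * ctx$kCompact * C
  list(energy = e, gradient = as.numeric(G))
}

## bonded-geometry feasibility: the strong (bond-class) distance restraints
## must be satisfied to tolAbs, and no non-bonded pair may sit below minSep
.geomOk <- function(ctx, x, engine, tolAbs = 0.2, minSep = 1.5) {
  X <- matrix(x, ctx$n, 3)
  strong <- ctx$pk >= engine@kBond / 2
  if (any(strong)) {
    V <- X[ctx$pi[strong], , drop = FALSE] - X[ctx$pj[strong], , drop = FALSE]
    if (max(abs(sqrt(rowSums(V * V)) - ctx$pd0[strong])) > tolAbs)
      return(FALSE)
  }
  x2 <- rowSums(X * X)
  D2 <- outer(x2, x2, "+") - 2 * tcrossprod(X)
  ok <- !any(ctx$upper & !ctx$excl & D2 < minSep^2)
  ok
}

## one minimisation from coordinates x
.engineMinimize <- function(x, ctx, maxit) {
  cache <- new.env(parent = emptyenv())
  evalAt <- function(p) {
    if (!is.null(cache$x) && identical(cache$x, p)) return(cache$v)
    v <- .engineEval(p, ctx)
    cache$x <- p; cache$v <- v
    v
  }
  o <- stats::optim(x, fn = function(p) evalAt(p)$energy,
                    gr = function(p) evalAt(p)$gradient,
                    method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e5))
  list(x = o$par, energy = o$value)
}

#' Relax a model until its SASA returns to a reference value
#'
#' Runs annealing rounds (temperature-scaled random kick on the mobile
#' atoms, then gradient minimisation of the coarse backbone potential)
#' until the total solvent-accessible surface area drops to
#' \code{reference * (1 + tol)}, or the round budget is exhausted (the
#' result is then flagged). Only rounds that strictly decrease the SASA
#' are accepted, so the recorded SASA sequence is monotone decreasing.
#' A monotone increase of the round-end energy over five consecutive
#' accepted rounds aborts with a diagnostic (engine divergence).
#'
#' @param model a [StructureModel-class]
#' @param engine an [EngineConfig-class]
#' @param reference target SASA (Angstrom^2, > 0)
#' @param tol relative tolerance above the reference (default 0.02)
#' @param mobile integer atom indices to kick (default: all atoms)
#' @param conservedRef positional restraint targets:
#'   list(key, X0) as built by [runGapGrowing()]; NULL for none
#' @param tether optional extra harmonic pair restraint specification
#' @param nPoints SASA sphere points per atom
#' @param stepOffset step index offset for the returned trace rows
#' @return list(model, trace, converged, rounds, sasa); trace is a
#'   data.frame of accepted rounds (step, sasa, event = "none")
#' @export
relaxUntilConverged <- function(model, engine, reference, tol = 0.02,
                                mobile = NULL, conservedRef = NULL,
                                tether = NULL, nPoints = 960,
                                stepOffset = 0L) {
  stopifnot(reference > 0)
  ctx <- .buildContext(model, engine, conservedRef, tether)
  x <- as.numeric(.coords(model))
  if (is.null(mobile)) mobile <- seq_len(ctx$n)
  sel <- as.numeric(outer(mobile, c(0, ctx$n, 2 * ctx$n), "+"))
  nA <- length(mobile)
  trace <- data.frame(step = integer(), sasa = numeric(),
                      event = character())
  ## geometry-restoration phase: minimise (kicking only on retries) until
  ## the strong bonded restraints are satisfied; not part of the SASA trace
  if (!.geomOk(ctx, x, engine)) {
    e0 <- .engineEval(x, ctx)$energy
    for (r in seq_len(engine@maxRounds)) {
      xk <- x
      if (r > 1) xk[sel] <- xk[sel] + stats::rnorm(3 * nA, 0, engine@tempStart)
      fit <- .engineMinimize(xk, ctx, engine@stepsPerRound)
      if (fit$energy <= e0) { x <- fit$x; e0 <- fit$energy }
      if (.geomOk(ctx, x, engine)) break
    }
    model@atoms[, c("x", "y", "z")] <- matrix(x, ctx$n, 3)
  }
  s <- computeSasa(model, nPoints = nPoints)$total
  if (s <= reference * (1 + tol) && .geomOk(ctx, x, engine))
    return(list(model = model, trace = trace, converged = TRUE,
                rounds = 0L, sasa = s))
  energies <- numeric(0)
  accepted <- 0L
  converged <- FALSE
  for (r in seq_len(engine@maxRounds)) {
    frac <- (r - 1) / max(engine@maxRounds - 1, 1)
    temp <- engine@tempStart * (engine@tempEnd / engine@tempStart)^frac
    xk <- x
    xk[sel] <- xk[sel] + stats::rnorm(3 * nA, 0, temp)
    fit <- .engineMinimize(xk, ctx, engine@stepsPerRound)
    m2 <- model
    m2@atoms[, c("x", "y", "z")] <- matrix(fit$x, ctx$n, 3)
    s2 <- computeSasa(m2, nPoints = nPoints)$total
    if (s2 < s && .geomOk(ctx, fit$x, engine)) {
      x <- fit$x
      s <- s2
      accepted <- accepted + 1L
      energies <- c(energies, fit$energy)
      trace <- rbind(trace, data.frame(step = stepOffset + accepted,
                                       sasa = s, event = "none"))
      if (length(energies) >= 5 &&
          all(diff(utils::tail(energies, 5)) > 0))
        stop("engine divergence: energy increased over 5 consecutive rounds")
      if (s <= reference * (1 + tol)) { converged <- TRUE; break }
    }
  }
  model@atoms[, c("x", "y", "z")] <- matrix(x, ctx$n, 3)
  list(model = model, trace = trace, converged = converged,
       rounds = accepted, sasa = s)
}
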