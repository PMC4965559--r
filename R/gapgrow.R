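#' Globally align a target to a template and extract insertions
#'
#' Global pairwise alignment with affine gap penalties (BLOSUM62); runs of
#' gaps in the template row become insertion specifications, numbered 1..k
#' from N- to C-terminus. When a template secondary structure string is
#' supplied, an insertion flanked on both sides by helical template
#' residues is annotated helical (the local secondary structure is
#' conserved when introducing the new residues); otherwise coil.
#'
#' @param target,template one-letter amino acid strings (ungapped)
#' @param chain chain id recorded in the specs
#' @param templateSS optional template secondary structure string (H/C)
#' @param gapOpening,gapExtension affine gap penalties
#' @return list with target and template gapped strings (\code{$target},
#'   \code{$template}), \code{$names}, and \code{$insertions}, a list of
#'   [InsertionSpec-class]
#' @export
alignWithInsertions <- function(target, template, chain = "A",
                                templateSS = NULL, gapOpening = 10,
                                gapExtension = 0.5) {
  stopifnot(nchar(target) > 0, nchar(template) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(target), Biostrings::AAString(template),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
  gt <- as.character(Biostrings::alignedPattern(pa))
  gs <- as.character(Biostrings::alignedSubject(pa))
  if (nchar(gt) == 0) stop("empty alignment")
  tchars <- strsplit(gt, "")[[1]]
  schars <- strsplit(gs, "")[[1]]
  ssc <- if (!is.null(templateSS)) strsplit(templateSS, "")[[1]] else NULL
  ins <- list()
  tpos <- 0L; spos <- 0L
  i <- 1L
  ncol <- length(tchars)
  while (i <= ncol) {
    if (schars[i] == "-") {
      start <- i
      anchor <- tpos               # target numbering of preceding residue
      seqIns <- character(0)
      while (i <= ncol && schars[i] == "-") {
        tpos <- tpos + 1L
        seqIns <- c(seqIns, tchars[i])
        i <- i + 1L
      }
      ## helical iff template is helical on both flanks
      ssIns <- "C"
      if (!is.null(ssc) && spos >= 1 && spos < length(ssc) &&
          ssc[spos] == "H" && ssc[spos + 1] == "H") ssIns <- "H"
      ins[[length(ins) + 1L]] <- insertionSpec(
        chain = chain, anchor = anchor,
        sequence = paste(seqIns, collapse = ""),
        ss = strrep(ssIns, length(seqIns)),
        index = length(ins) + 1L)
    } else {
      spos <- spos + 1L
      if (tchars[i] != "-") tpos <- tpos + 1L
      i <- i + 1L
    }
  }
  list(target = gt, template = gs, names = c("target", "template"),
       insertions = ins)
}

#' Thread a target sequence onto a template backbone
#'
#' Builds the base model for gap growing: target residues aligned to
#' template residues take the template backbone coordinates verbatim
#' (renamed and renumbered to the target); insertion positions are left
#' absent, with chain breaks declared at their anchors; template residues
#' deleted in the target are skipped, with a break declared.
#'
#' @param aln alignment as returned by [alignWithInsertions()] or
#'   [readAlignment()]
#' @param template a [StructureModel-class]; the chain to thread is taken
#'   from \code{chain}
#' @param chain chain id (default: first chain of the template)
#' @return a [StructureModel-class] in target numbering
#' @export
buildBaseModel <- function(aln, template, chain = NULL) {
  a <- template@atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, ]
  if (!nrow(a)) stop("template has no chain ", chain)
  tres <- sort(unique(a$resno))
  tchars <- strsplit(aln$target, "")[[1]]
  schars <- strsplit(aln$template, "")[[1]]
  if (length(tchars) != length(schars))
    stop("alignment/template mismatch: unequal gapped lengths")
  if (sum(schars != "-") != length(tres))
    stop("alignment/template mismatch: template has ", length(tres),
         " residues but alignment has ", sum(schars != "-"))
  tssAll <- template@ss[[chain]]
  tpos <- 0L; spos <- 0L
  keepRows <- list(); ssOut <- character(0)
  breaks <- integer(0)
  lastKept <- NA_integer_
  for (i in seq_along(tchars)) {
    tIs <- tchars[i] != "-"
    sIs <- schars[i] != "-"
    if (tIs) tpos <- tpos + 1L
    if (sIs) spos <- spos + 1L
    if (tIs && sIs) {
      res <- a[a$resno == tres[spos], ]
      res$resno <- tpos
      res$resname <- .aa123(tchars[i])
      keepRows[[length(keepRows) + 1L]] <- res
      ssOut <- c(ssOut, if (!is.null(tssAll)) substr(tssAll, spos, spos)
                 else "C")
      if (!is.na(lastKept) && tpos - lastKept > 1L)
        breaks <- c(breaks, lastKept)          # insertion gap
      lastKept <- tpos
    } else if (!tIs && sIs) {
      ## deletion: template residue skipped, break declared
      if (!is.na(lastKept)) breaks <- unique(c(breaks, lastKept))
    }
  }
  if (!length(keepRows)) stop("alignment covers no template residues")
  atoms <- do.call(rbind, keepRows)
  structureModel(atoms,
                 ss = stats::setNames(list(paste(ssOut, collapse = "")), chain),
                 breaks = data.frame(chain = rep(chain, length(breaks)),
                                     afterResno = as.integer(breaks)))
}

## splice freshly built residues onto the growing end:
## continue the chain from the last placed residue by NeRF construction
.spliceChunk <- function(model, chain, prevResno, resnos, seqChunk, ssChunk) {
  a <- model@atoms
  g <- .GEO
  P <- function(rn, el) as.numeric(a[a$chain == chain & a$resno == rn &
                                       a$elety == el, c("x", "y", "z")])
  Nprev <- P(prevResno, "N"); CAprev <- P(prevResno, "CA")
  Cprev <- P(prevResno, "C")
  sschars <- strsplit(ssChunk, "")[[1]]
  aa <- strsplit(seqChunk, "")[[1]]
  newRows <- list()
  for (q in seq_along(resnos)) {
    pp <- .PHIPSI[[sschars[q]]]
    N <- .placeAtom(Nprev, CAprev, Cprev, g$bCN, g$aCACN, pp["psi"])
    CA <- .placeAtom(CAprev, Cprev, N, g$bNCA, g$aCNCA, g$omega)
    C <- .placeAtom(Cprev, N, CA, g$bCAC, g$aNCAC, pp["phi"])
    O <- .placeAtom(N, CA, C, g$bCO, g$aCACO, pp["psi"] + 180)
    newRows[[q]] <- data.frame(chain = chain, resno = resnos[q],
                               resname = .aa123(aa[q]),
                               elety = c("N", "CA", "C", "O"),
                               x = c(N[1], CA[1], C[1], O[1]),
                               y = c(N[2], CA[2], C[2], O[2]),
                               z = c(N[3], CA[3], C[3], O[3]))
    Nprev <- N; CAprev <- CA; Cprev <- C
  }
  a <- rbind(a, do.call(rbind, newRows))
  a <- a[order(a$chain, a$resno, match(a$elety, c("N", "CA", "C", "O", "CB"))), ]
  model@atoms <- a
  rownames(model@atoms) <- NULL
  ## extend the ss annotation for the chain, in residue order
  res <- sort(unique(a$resno[a$chain == chain]))
  old <- model@ss[[chain]]
  ssNew <- character(length(res))
  oldRes <- setdiff(res, resnos)
  if (!is.null(old)) ssNew[match(oldRes, res)] <- strsplit(old, "")[[1]]
  ssNew[match(resnos, res)] <- sschars
  ssNew[ssNew == ""] <- "C"
  model@ss[[chain]] <- paste(ssNew, collapse = "")
  model
}

#' Grow one insertion into a model
#'
#' Introduces the inserted residues a few at a time (default chunks of 3,
#' final remainder possibly smaller), splicing each chunk at the growing
#' end with ideal geometry at the annotated secondary structure dihedrals,
#' then relaxing with the annealing engine. While the gap is open, a loose
#' tether guides the growing end toward the downstream anchor; placing the
#' final residue seals the chain break (the peptide-geometry restraints
#' across the junction restore bonded geometry during the final
#' relaxation, which runs until the SASA convergence criterion is met).
#'
#' @param model base model (insertion residues absent)
#' @param spec an [InsertionSpec-class]
#' @param chunk chunk size in residues (2-5; remainder chunks may be
#'   smaller)
#' @param engine an [EngineConfig-class]
#' @param sasaRef pre-insertion reference SASA (Angstrom^2)
#' @param tol SASA convergence tolerance (default 0.02)
#' @param conservedRef positional restraint targets for conserved atoms
#' @param nPoints SASA sphere points
#' @param stepOffset step counter offset for trace continuity
#' @param chunkRounds round budget of the intermediate (per-chunk)
#'   relaxations; the final relaxation uses the engine's full budget
#' @return list(model, trace, flagged, sasa)
#' @export
growInsertion <- function(model, spec, chunk = 3L, engine, sasaRef,
                          tol = 0.02, conservedRef = NULL, nPoints = 960,
                          stepOffset = 0L, chunkRounds = 12L) {
  len <- nchar(spec@sequence)
  stopifnot(chunk >= 1, chunk <= 5)
  a <- model@atoms
  if (!any(a$chain == spec@chain & a$resno == spec@anchor))
    stop("anchor residue ", spec@anchor, " not present in chain ", spec@chain)
  sizes <- c(rep(chunk, len %/% chunk), if (len %% chunk) len %% chunk)
  res <- sort(unique(a$resno[a$chain == spec@chain]))
  nextRes <- res[res > spec@anchor][1]          # downstream of the gap
  trace <- data.frame(step = integer(), sasa = numeric(),
                      event = character())
  step <- stepOffset
  placed <- 0L
  flagged <- FALSE
  sasa <- NA_real_
  for (ci in seq_along(sizes)) {
    sz <- sizes[ci]
    resnos <- spec@anchor + placed + seq_len(sz)
    prev <- if (placed == 0L) spec@anchor else spec@anchor + placed
    model <- .spliceChunk(model, spec@chain, prev, resnos,
                          substr(spec@sequence, placed + 1, placed + sz),
                          substr(spec@ss, placed + 1, placed + sz))
    placed <- placed + sz
    step <- step + 1L
    s <- computeSasa(model, nPoints = nPoints)$total
    trace <- rbind(trace, data.frame(step = step, sasa = s,
                                     event = "residues-added"))
    lastChunk <- ci == length(sizes)
    tether <- NULL
    if (!lastChunk && !is.na(nextRes)) {
      remaining <- len - placed
      tether <- list(k1 = .akey(spec@chain, spec@anchor + placed, "CA"),
                     k2 = .akey(spec@chain, nextRes, "CA"),
                     d0 = 3.8 * (remaining + 1), k = 0.3)
    }
    ## mobile set: the inserted residues placed so far
    insRes <- spec@anchor + seq_len(placed)
    mobile <- which(model@atoms$chain == spec@chain &
                      model@atoms$resno %in% insRes)
    eng <- engine
    if (!lastChunk) eng@maxRounds <- as.integer(chunkRounds)
    rx <- relaxUntilConverged(model, eng, sasaRef, tol = tol,
                              mobile = mobile, conservedRef = conservedRef,
                              tether = tether, nPoints = nPoints,
                              stepOffset = step)
    model <- rx$model
    trace <- rbind(trace, rx$trace)
    step <- step + nrow(rx$trace)
    sasa <- rx$sasa
    if (lastChunk) {
      flagged <- !rx$converged
      ## the junction is sealed: drop the declared break at the anchor
      b <- model@breaks
      model@breaks <- b[!(b$chain == spec@chain &
                            b$afterResno == spec@anchor), , drop = FALSE]
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, sasa = rx$sasa,
                                       event = "insertion-complete"))
    }
  }
  list(model = model, trace = trace, flagged = flagged, sasa = sasa)
}

#' Run the full iterative gap-growing protocol
#'
#' Aligns each target sequence to its template chain, threads the base
#' model with insertions absent, equilibrates it briefly to obtain the
#' pre-insertion reference SASA, then grows every insertion chunk-wise
#' with relaxation after each addition, processing insertions in
#' descending index order (3 -> 2 -> 1 for three insertions; generally
#' C- to N-terminal). The run is deterministic for a fixed seed.
#'
#' @param targetSeqs named character vector/list of target sequences, one
#'   per template chain (names = chain ids; a single unnamed sequence maps
#'   to the template's first chain)
#' @param template a [StructureModel-class]
#' @param config list of options: chunk (3), sasaTol (0.02), engine (an
#'   [EngineConfig-class]), equilibRounds (5), nPoints (960), order
#'   ("descending" or "ascending"), chunkRounds (12)
#' @return list with model (final [StructureModel-class]), trace
#'   ([SasaTrace-class]), and report (insertion order, per-insertion
#'   rounds and flags, conserved-region CA RMSD to the template, the
#'   reference and final SASA, and the proximity-based structural
#'   alignment)
#' @export
runGapGrowing <- function(targetSeqs, template, config = list()) {
  cfg <- utils::modifyList(list(chunk = 3L, sasaTol = 0.02,
                                engine = engineConfig(),
                                equilibRounds = 5L, nPoints = 960L,
                                order = "descending", chunkRounds = 12L),
                           config)
  engine <- cfg$engine
  chains <- unique(template@atoms$chain)
  targetSeqs <- as.list(targetSeqs)
  if (is.null(names(targetSeqs)) && length(targetSeqs) == 1)
    names(targetSeqs) <- chains[1]
  stopifnot(all(names(targetSeqs) %in% chains))
  ## RNG discipline: one private stream for the whole run
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(engine@seed)

  ## per-chain alignment and threading
  base <- NULL
  specs <- list()
  for (ch in names(targetSeqs)) {
    tseq <- .chainSeq(template, ch)
    aln <- alignWithInsertions(targetSeqs[[ch]], tseq, chain = ch,
                               templateSS = template@ss[[ch]])
    bm <- buildBaseModel(aln, template, chain = ch)
    base <- if (is.null(base)) bm else .mergeModels(base, bm)
    specs <- c(specs, aln$insertions)
  }
  templateRef <- list(key = .akey(base@atoms$chain, base@atoms$resno,
                                  base@atoms$elety),
                      X0 = .coords(base))
  ## brief equilibration of the base model: accepted-SASA-decrease rounds
  eq <- engine
  eq@maxRounds <- as.integer(cfg$equilibRounds)
  rx <- relaxUntilConverged(base, eq, reference = 1e-6, tol = 0,
                            conservedRef = templateRef,
                            nPoints = cfg$nPoints)
  model <- rx$model
  reference <- rx$sasa
  trace <- data.frame(step = 0L, sasa = reference, event = "none")
  step <- nrow(rx$trace)                     # equilibration steps not traced
  ## insertion processing order
  ord <- order(vapply(specs, function(s) s@index, 1L),
               decreasing = (cfg$order == "descending"))
  report <- list(insertionOrder = vapply(specs[ord], function(s) s@index, 1L),
                 insertions = list())
  step <- 0L
  for (s in specs[ord]) {
    gr <- growInsertion(model, s, chunk = cfg$chunk, engine = engine,
                        sasaRef = reference, tol = cfg$sasaTol,
                        conservedRef = templateRef, nPoints = cfg$nPoints,
                        stepOffset = step, chunkRounds = cfg$chunkRounds)
    model <- gr$model
    trace <- rbind(trace, gr$trace)
    step <- max(trace$step)
    report$insertions[[length(report$insertions) + 1L]] <-
      list(index = s@index, chain = s@chain, anchor = s@anchor,
           length = nchar(s@sequence), flagged = gr$flagged,
           finalSasa = gr$sasa)
  }
  finalSasa <- computeSasa(model, nPoints = cfg$nPoints)$total
  ## conserved-region CA RMSD vs the template threading
  consKey <- templateRef$key[base@atoms$elety == "CA"]
  nowKey <- .akey(model@atoms$chain, model@atoms$resno, model@atoms$elety)
  hit <- match(consKey, nowKey)
  rmsd <- .kabschRmsd(.coords(model)[hit, , drop = FALSE],
                      templateRef$X0[base@atoms$elety == "CA", , drop = FALSE])
  report$conservedCaRmsd <- rmsd
  report$referenceSasa <- reference
  report$finalSasa <- finalSasa
  report$sasaRatio <- finalSasa / reference
  report$flagged <- vapply(report$insertions, function(i) i$flagged, TRUE)
  report$structuralAlignment <- .proximityAlignment(model, template)
  list(model = model, trace = new("SasaTrace", trace = trace),
       report = report)
}

## one-letter sequence of a chain, in residue order
.chainSeq <- function(model, chain) {
  a <- model@atoms
  a <- a[a$chain == chain & a$elety == "CA", ]
  a <- a[order(a$resno), ]
  paste(.aa321(a$resname), collapse = "")
}

.mergeModels <- function(a, b) {
  structureModel(rbind(a@atoms, b@atoms), ss = c(a@ss, b@ss),
                 breaks = rbind(a@breaks, b@breaks))
}

## post-hoc residue correspondence by CA proximity (structural alignment)
.proximityAlignment <- function(model, template, cutoff = 3.0) {
  mc <- model@atoms[model@atoms$elety == "CA", ]
  tc <- template@atoms[template@atoms$elety == "CA", ]
  M <- as.matrix(mc[, c("x", "y", "z")])
  T <- as.matrix(tc[, c("x", "y", "z")])
  D2 <- outer(rowSums(M^2), rowSums(T^2), "+") - 2 * tcrossprod(M, T)
  j <- max.col(-D2)
  d <- sqrt(pmax(D2[cbind(seq_len(nrow(M)), j)], 0))
  data.frame(chain = mc$chain, resno = mc$resno,
             templateChain = ifelse(d <= cutoff, tc$chain[j], NA),
             templateResno = ifelse(d <= cutoff, tc$resno[j], NA),
             distance = d)
}
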