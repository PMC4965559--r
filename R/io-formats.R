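## Readers and writers for the external representations the pipeline
## touches. Every reader/writer pair round-trips on its own output (exact
## for text fields, to format precision for floats), and readers never
## silently drop rows: rejected lines are reported.

#' Read a 2-D peak list
#'
#' Supports two dialects: \code{"sparky"} (whitespace-separated
#' "assignment w1 w2 height" with w1 = 15N and w2 = 1H ppm in the usual
#' Sparky column order, a header line starting with "Assignment" tolerated)
#' and \code{"tabular"} (TSV with header columns assignment, dH, dN,
#' height). Malformed lines raise a parse error naming the line number;
#' an empty file yields an empty list with a warning.
#'
#' @param path file path
#' @param dialect "sparky" or "tabular"
#' @return a [PeakList-class]
#' @seealso [writePeakList()]
#' @export
readPeakList <- function(path, dialect = c("sparky", "tabular")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (dialect == "sparky" && length(lines) && grepl("^\\s*Assignment", lines[1]))
    lines <- lines[-1]
  if (dialect == "tabular" && length(lines)) {
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("assignment", "dH", "dN", "height")
    if (!all(need %in% hdr))
      stop("tabular peak list must have header columns: ",
           paste(need, collapse = ", "))
    lines <- lines[-1]
  }
  if (!length(lines)) {
    warning("empty peak list: ", path)
    return(peakList(character(), numeric(), numeric(), numeric()))
  }
  parse1 <- function(i) {
    f <- strsplit(trimws(lines[i]),
                  if (dialect == "sparky") "\\s+" else "\t")[[1]]
    if (length(f) < 3) stop("parse error at line ", i, ": too few fields")
    if (dialect == "sparky") {
      w1 <- suppressWarnings(as.numeric(f[2]))   # 15N
      w2 <- suppressWarnings(as.numeric(f[3]))   # 1H
      ht <- if (length(f) >= 4) suppressWarnings(as.numeric(f[4])) else 1
    } else {
      if (length(f) < 4) stop("parse error at line ", i, ": too few fields")
      w2 <- suppressWarnings(as.numeric(f[2]))
      w1 <- suppressWarnings(as.numeric(f[3]))
      ht <- suppressWarnings(as.numeric(f[4]))
    }
    if (!is.finite(w1) || !is.finite(w2))
      stop("parse error at line ", i, ": malformed ppm field")
    asg <- if (f[1] %in% c("?", "?-?", "NA")) NA_character_ else f[1]
    list(assignment = asg, dH = w2, dN = w1, height = ht)
  }
  rows <- lapply(seq_along(lines), parse1)
  peakList(assignment = vapply(rows, `[[`, "", "assignment"),
           dH = vapply(rows, `[[`, 1, "dH"),
           dN = vapply(rows, `[[`, 1, "dN"),
           height = vapply(rows, `[[`, 1, "height"))
}

#' Write a peak list
#'
#' @param x a [PeakList-class]
#' @param path output path
#' @param dialect "sparky" or "tabular"; see [readPeakList()]
#' @export
writePeakList <- function(x, path, dialect = c("sparky", "tabular")) {
  dialect <- match.arg(dialect)
  p <- x@peaks
  asg <- ifelse(is.na(p$assignment), "?-?", p$assignment)
  if (dialect == "sparky") {
    lines <- c(sprintf("%18s %10s %10s %12s",
                       "Assignment", "w1", "w2", "Height"),
               sprintf("%18s %10.4f %10.4f %12.4f",
                       asg, p$dN, p$dH, p$height))
  } else {
    lines <- c("assignment\tdH\tdN\theight",
               sprintf("%s\t%.4f\t%.4f\t%.4f", asg, p$dH, p$dN, p$height))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-residue relaxation table
#'
#' TSV with header columns residue, t1, t1err, t2, t2err, noe, noeerr
#' (times in ms).
#'
#' @param path file path
#' @return a [RelaxationTable-class]
#' @export
readRelaxationTable <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path)
  need <- c("residue", "t1", "t1err", "t2", "t2err", "noe", "noeerr")
  if (!all(need %in% names(d)))
    stop("relaxation table must have columns: ", paste(need, collapse = ", "))
  relaxationTable(d$residue, d$t1, d$t1err, d$t2, d$t2err, d$noe, d$noeerr,
                  valid = if ("valid" %in% names(d)) as.logical(d$valid) else NULL)
}

#' Write a relaxation table
#'
#' @param x a [RelaxationTable-class]
#' @param path output path
#' @export
writeRelaxationTable <- function(x, path) {
  utils::write.table(x@data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## backbone atom names the structure reader keeps
.BACKBONE <- c("N", "CA", "C", "O", "CB")

#' Read a backbone structure from a PDB file
#'
#' Parses coordinate records (via bio3d) and retains the backbone subset
#' (N, CA, C, O, optional CB). A residue without a CA atom makes the
#' structure unusable; missing O atoms are tolerated with a warning.
#' Chain breaks are detected where consecutive CA-CA distance exceeds
#' 4.5 Angstrom and recorded as declared breaks.
#'
#' @param path PDB file path
#' @return a [StructureModel-class]
#' @seealso [writeStructure()]
#' @export
readStructure <- function(path) {
  stopifnot(file.exists(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$elety %in% .BACKBONE, c("chain", "resno", "resid", "elety",
                                   "x", "y", "z")]
  names(a)[names(a) == "resid"] <- "resname"
  a$chain[is.na(a$chain)] <- "A"
  if (!any(a$elety == "CA")) stop("unusable structure: no CA atoms")
  res <- unique(a[, c("chain", "resno")])
  hasCA <- mapply(function(ch, rn)
    any(a$chain == ch & a$resno == rn & a$elety == "CA"),
    res$chain, res$resno)
  if (!all(hasCA))
    stop("unusable structure: residue(s) without CA: ",
         paste(res$resno[!hasCA], collapse = ", "))
  hasO <- mapply(function(ch, rn)
    any(a$chain == ch & a$resno == rn & a$elety == "O"),
    res$chain, res$resno)
  if (!all(hasO))
    warning(sum(!hasO), " residue(s) lack O atoms; tolerated")
  m <- structureModel(a)
  m@breaks <- .detectBreaks(m)
  m
}

## CA-CA distance screen for chain breaks
.detectBreaks <- function(model, maxCACA = 4.5) {
  a <- model@atoms
  out <- data.frame(chain = character(), afterResno = integer())
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch & a$elety == "CA", ]
    ca <- ca[order(ca$resno), ]
    if (nrow(ca) < 2) next
    d <- sqrt(rowSums((ca[-1, c("x", "y", "z")] -
                       ca[-nrow(ca), c("x", "y", "z")])^2))
    br <- which(d > maxCACA)
    if (length(br))
      out <- rbind(out, data.frame(chain = ch, afterResno = ca$resno[br]))
  }
  out
}

#' Write a structure model to PDB
#'
#' @param x a [StructureModel-class]
#' @param path output path
#' @export
writeStructure <- function(x, path) {
  a <- x@atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   elety = a$elety)
  invisible(path)
}

#' Read a pairwise gapped alignment
#'
#' FASTA with gap characters; exactly two sequences of equal gapped length.
#'
#' @param path FASTA file path
#' @return list with target, template (gapped character strings) and their
#'   names; target first record, template second
#' @export
readAlignment <- function(path) {
  stopifnot(file.exists(path))
  s <- Biostrings::readBStringSet(path)
  if (length(s) != 2) stop("alignment must contain exactly two sequences")
  w <- Biostrings::width(s)
  if (w[1] != w[2])
    stop("format error: gapped sequences have unequal lengths (",
         w[1], " vs ", w[2], ")")
  list(target = as.character(s)[[1]], template = as.character(s)[[2]],
       names = names(s))
}

#' Write a pairwise gapped alignment
#'
#' @param aln list as returned by [readAlignment()] or
#'   [alignWithInsertions()]
#' @param path output path
#' @export
writeAlignment <- function(aln, path) {
  nm <- aln$names %||% c("target", "template")
  writeLines(c(paste0(">", nm[1]), aln$target,
               paste0(">", nm[2]), aln$template), path)
  invisible(path)
}

#' Read a titration manifest
#'
#' TSV with header columns ratio, path (molar ratio and peak-list file,
#' paths relative to the manifest location), plus optional attribute lines
#' "# proteinConcmM <x>".
#'
#' @param path manifest path
#' @param dialect peak-list dialect, see [readPeakList()]
#' @return a [TitrationSeries-class]
#' @export
readTitrationSeries <- function(path, dialect = "sparky") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  conc <- 0.8
  m <- regmatches(lines, regexec("^#\\s*proteinConcmM\\s+([0-9.eE+-]+)", lines))
  hit <- which(lengths(m) == 2)
  if (length(hit)) conc <- as.numeric(m[[hit[1]]][2])
  d <- utils::read.delim(text = lines[!grepl("^#", lines)])
  if (!all(c("ratio", "path") %in% names(d)))
    stop("titration manifest needs columns: ratio, path")
  d <- d[order(d$ratio), ]
  pls <- lapply(file.path(dirname(path), d$path), readPeakList,
                dialect = dialect)
  titrationSeries(d$ratio, pls, proteinConcmM = conc,
                  maxRatio = max(4, max(d$ratio)))
}

#' Write a titration series to a manifest plus peak-list files
#'
#' @param x a [TitrationSeries-class]
#' @param dir output directory (created if needed)
#' @param dialect peak-list dialect
#' @return the manifest path
#' @export
writeTitrationSeries <- function(x, dir, dialect = "sparky") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("point_%02d.list", seq_along(x@ratios))
  for (i in seq_along(files))
    writePeakList(x@peakLists[[i]], file.path(dir, files[i]), dialect)
  manifest <- file.path(dir, "series.tsv")
  writeLines(c(sprintf("# proteinConcmM %g", x@proteinConcmM),
               "ratio\tpath",
               sprintf("%g\t%s", x@ratios, files)), manifest)
  manifest
}
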