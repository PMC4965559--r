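## Ideal backbone geometry (lengths in Angstrom, angles in degrees)
.GEO <- list(
  bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
  aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8,
  omega = 180)

## dihedral-angle defaults per secondary structure code
.PHIPSI <- list(H = c(phi = -60, psi = -45), C = c(phi = -120, psi = 130))

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame construction: returns the position of
#' atom D given the three preceding atoms A, B, C, the C-D bond length, the
#' B-C-D bond angle and the A-B-C-D dihedral.
#'
#' @param a,b,c numeric xyz of the three reference atoms
#' @param bond C-D distance (Angstrom)
#' @param angle B-C-D angle (degrees)
#' @param dihedral A-B-C-D dihedral (degrees)
#' @return numeric xyz of D
#' @keywords internal
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m <- .cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an ideal backbone from dihedral angles
#'
#' Constructs N, CA, C, O backbone coordinates for a sequence using ideal
#' bond lengths and angles, with per-residue (phi, psi) taken from the
#' secondary structure annotation: helix (H) at (-60, -45), coil (C) at the
#' extended (-120, 130). Explicit phi/psi vectors override the annotation.
#'
#' @param sequence one-letter amino acid string
#' @param ss secondary structure string (H/C), same length as sequence
#' @param phi,psi optional explicit dihedral vectors (degrees); psi of the
#'   last residue only positions its carbonyl oxygen
#' @param chain chain id for the returned model
#' @param startRes first residue number
#' @return a [StructureModel-class] with 4 atoms per residue
#' @examples
#' h <- idealBackbone("AAAAAAAAAA", strrep("H", 10))
#' @export
idealBackbone <- function(sequence, ss = strrep("C", nchar(sequence)),
                          phi = NULL, psi = NULL, chain = "A",
                          startRes = 1L) {
  n <- nchar(sequence)
  stopifnot(n >= 1, nchar(ss) == n)
  sschars <- strsplit(ss, "")[[1]]
  if (any(!sschars %in% names(.PHIPSI)))
    stop("unknown secondary structure code: ",
         paste(unique(sschars[!sschars %in% names(.PHIPSI)]), collapse = ""))
  if (is.null(phi)) phi <- vapply(sschars, function(s) .PHIPSI[[s]]["phi"], 1)
  if (is.null(psi)) psi <- vapply(sschars, function(s) .PHIPSI[[s]]["psi"], 1)
  g <- .GEO
  ## residue 1 seed frame
  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3); O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  ang <- g$aNCAC * pi / 180
  C[1, ] <- CA[1, ] + g$bCAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$bCN, g$aCACN, psi[i - 1])
      CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$bNCA, g$aCNCA, g$omega)
      C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                           g$bCAC, g$aNCAC, phi[i])
    }
    ## carbonyl O antiperiplanar to the next N (psi + 180)
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO,
                         psi[i] + 180)
  }
  aa3 <- .aa123(strsplit(sequence, "")[[1]])
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = startRes + i - 1L,
               resname = aa3[i],
               elety = c("N", "CA", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]))
  }))
  structureModel(atoms, ss = stats::setNames(list(ss), chain))
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.aa123 <- function(x) {
  out <- .AA1TO3[x]
  out[is.na(out)] <- "UNK"
  unname(out)
}

.aa321 <- function(x) {
  m <- stats::setNames(names(.AA1TO3), .AA1TO3)
  out <- m[x]
  out[is.na(out)] <- "X"
  unname(out)
}

## coordinate matrix of a structure model (atoms in table order)
.coords <- function(model) as.matrix(model@atoms[, c("x", "y", "z")])

## Kabsch superposition: returns RMSD of x onto y (n x 3 matrices)
.kabschRmsd <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x <- sweep(x, 2, cx); y <- sweep(y, 2, cy)
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((x %*% r - y)^2)))
}
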