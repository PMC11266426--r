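#' @include AllClasses.R
NULL

## van der Waals radii (Angstrom), Bondi (1964) values with the common
## additions used by NACCESS-style SASA codes.  Pinned here so SASA output
## is stable across releases; override via the `radii` argument of sasa().
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 1.80, ZN = 1.39, MG = 1.73, MN = 1.73, CU = 1.40, NI = 1.63,
  "NA" = 2.27, K = 2.75)

#' van der Waals radii used for SASA
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
vdwRadii <- function() VDW_RADII

## Deterministic, uniform-ish unit sphere quadrature (Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)         # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

## Canonical orthonormal frame of a coordinate cloud: covariance
## eigenvectors, signs fixed so the first atom (by molecule order) with a
## non-negligible projection lies on the positive side of each axis,
## right-handed.  Atom order is intrinsic to the molecule, so the frame
## co-rotates under rigid motions; expressing the quadrature sphere in it
## makes SASA rigid-motion invariant (molecules with perfectly degenerate
## principal moments excepted).
canonicalFrame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    proj <- rel %*% V[, k]
    lead <- which(abs(proj) > 1e-6)[1]
    if (!is.na(lead) && proj[lead] < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere (default 1.4 Angstrom) over the van der Waals
#' surface, approximating each atom's accessible fraction on a deterministic
#' Fibonacci point lattice.  Hydrogens are excluded.  The quadrature lattice
#' is expressed in a canonical frame derived from the structure's own
#' coordinate covariance, so results are invariant under rigid rotation and
#' translation of the input.
#'
#' @param structure a \code{Structure} (heavy atoms are used; H skipped).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints quadrature points per atom (default 960; single-sphere
#'   relative error is then below 0.5 percent).
#' @param radii named radius table in Angstrom (default \code{vdwRadii()}).
#' @return numeric vector of per-atom SASA in Angstrom^2, one entry per
#'   heavy atom, with attribute \code{"atomIndex"} giving the 0-based atom
#'   indices; \code{sum()} of it is the total SASA.
#' @examples
#' d <- buildDimer()
#' total <- sum(sasa(d))
#' @export
sasa <- function(structure, probe = 1.4, nPoints = 960L, radii = vdwRadii()) {
  a <- structure@atoms
  heavy <- a$element != "H" & a$element != "D"
  a <- a[heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms")
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop(sprintf("no van der Waals radius for element(s): %s (atoms %s)",
                 paste(unknown, collapse = ", "),
                 paste(utils::head(a$index[a$element %in% unknown], 5),
                       collapse = ", ")))
  xyzA <- as.matrix(a[, c("x", "y", "z")]) * ANGSTROM_PER_NM
  sphere <- fibonacciSphere(nPoints) %*% t(canonicalFrame(xyzA))
  r <- unname(radii[a$element])
  out <- cpp_sasa(xyzA, r, probe, sphere)
  attr(out, "atomIndex") <- a$index
  out
}

subsetChains <- function(structure, chains) {
  a <- structure@atoms[structure@atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0)
    stop(sprintf("no atoms in chain(s) %s", paste(chains, collapse = ",")))
  newStructure(a, box = structure@box, sourceUnits = structure@sourceUnits)
}

## Per-residue SASA sums from a per-atom vector + its atom table.
residueSums <- function(a, vals) {
  key <- paste(a$chain, a$resseq, a$resname, sep = "\r")
  s <- tapply(vals, key, sum)
  data.frame(key = names(s), sasa = as.numeric(s), stringsAsFactors = FALSE)
}

HYDROPHOBIC_SET <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

#' Buried interface area between two chain sets
#'
#' Computes SASA of each chain set alone and of the complex, and reports the
#' buried interface area in the PISA convention:
#' \code{(SASA(A) + SASA(B) - SASA(AB)) / 2}, in Angstrom^2.  Also reports
#' the per-chain-set buried areas, the per-residue buried fraction
#' (residue delta-SASA / residue SASA alone), and a census of hydrophobic
#' residues (set: Ala, Val, Leu, Ile, Pro, Phe, Met, Trp) whose buried
#' fraction exceeds \code{hydrophobicThreshold}.
#'
#' @param structure a \code{Structure} holding both chain sets.
#' @param chainsA,chainsB disjoint, non-empty chain id sets.
#' @param probe,nPoints,radii passed to \code{\link{sasa}}.
#' @param hydrophobicThreshold buried-fraction threshold for the hydrophobic
#'   census (default 0.70).
#' @return list with \code{buriedArea} (PISA convention, Angstrom^2),
#'   \code{buriedAreaSum} (sum over both chain sets, = 2 x buriedArea),
#'   \code{perChainBuried}, \code{interfaceResidues} (data.frame: chain,
#'   resseq, resname, sasaAlone, deltaSasa, buriedFraction),
#'   \code{hydrophobicCount}.
#' @export
interfaceArea <- function(structure, chainsA, chainsB, probe = 1.4,
                          nPoints = 960L, radii = vdwRadii(),
                          hydrophobicThreshold = 0.70) {
  if (!length(chainsA) || !length(chainsB))
    stop("both chain sets must be non-empty")
  if (length(intersect(chainsA, chainsB)))
    stop("chain sets must be disjoint")
  have <- unique(structure@atoms$chain)
  missing <- setdiff(c(chainsA, chainsB), have)
  if (length(missing))
    stop(sprintf("chain id(s) absent from structure: %s",
                 paste(missing, collapse = ", ")))
  sA <- subsetChains(structure, chainsA)
  sB <- subsetChains(structure, chainsB)
  sAB <- subsetChains(structure, c(chainsA, chainsB))
  vA <- sasa(sA, probe, nPoints, radii)
  vB <- sasa(sB, probe, nPoints, radii)
  vAB <- sasa(sAB, probe, nPoints, radii)
  totA <- sum(vA); totB <- sum(vB); totAB <- sum(vAB)
  buried <- (totA + totB - totAB) / 2

  heavy <- function(s) {
    a <- s@atoms
    a[a$element != "H" & a$element != "D", , drop = FALSE]
  }
  alone <- rbind(cbind(heavy(sA), v = as.numeric(vA)),
                 cbind(heavy(sB), v = as.numeric(vB)))
  cplx <- cbind(heavy(sAB), v = as.numeric(vAB))
  ra <- residueSums(alone, alone$v)
  rc <- residueSums(cplx, cplx$v)
  m <- merge(ra, rc, by = "key", suffixes = c("Alone", "Complex"))
  parts <- do.call(rbind, strsplit(m$key, "\r", fixed = TRUE))
  res <- data.frame(chain = parts[, 1], resseq = as.integer(parts[, 2]),
                    resname = parts[, 3], sasaAlone = m$sasaAlone,
                    deltaSasa = m$sasaAlone - m$sasaComplex,
                    stringsAsFactors = FALSE)
  res$deltaSasa[res$deltaSasa < 0 & res$deltaSasa > -1e-6] <- 0
  res$buriedFraction <- ifelse(res$sasaAlone > 0,
                               pmin(1, pmax(0, res$deltaSasa / res$sasaAlone)),
                               0)
  iface <- res[res$deltaSasa > 1e-6, , drop = FALSE]
  iface <- iface[order(iface$chain, iface$resseq), , drop = FALSE]
  rownames(iface) <- NULL
  perChain <- c(sum(totA) - sum(vAB[cplx$chain %in% chainsA]),
                sum(totB) - sum(vAB[cplx$chain %in% chainsB]))
  hydro <- sum(iface$resname %in% HYDROPHOBIC_SET &
                 iface$buriedFraction > hydrophobicThreshold)
  list(buriedArea = buried, buriedAreaSum = 2 * buried,
       perChainBuried = perChain, interfaceResidues = iface,
       hydrophobicCount = hydro)
}
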