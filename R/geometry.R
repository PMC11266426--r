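#' @include AllClasses.R
NULL

## Select Calpha rows of the atom table.  Pseudo-atomic synthetic chains use
## "CA" atom names as well, so the same selection works for both.
calphaRows <- function(a, chain = NULL, range = NULL) {
  sel <- a$name == "CA" & a$element != "CA"  # exclude calcium ions
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(range)) sel <- sel & a$resseq >= range[1] & a$resseq <= range[2]
  a[sel, , drop = FALSE]
}

principalAxis <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(axis = sv$v[, 1], centroid = ctr)
}

#' Helix axis from the Calpha coordinate cloud
#'
#' The axis is the dominant principal direction of the Calpha coordinates of
#' the residue range, oriented from low to high residue number.  Gaps in the
#' range (e.g. disordered residues missing from the model) are tolerated; at
#' least 10 Calpha atoms must be present.
#'
#' @param structure a \code{Structure}.
#' @param chain chain id.
#' @param range inclusive residue-number interval \code{c(first, last)}.
#' @return list of class \code{HelixSpec} fields: \code{chain},
#'   \code{range}, \code{axis} (unit 3-vector), \code{centroid} (nm),
#'   \code{nCalpha}.
#' @examples
#' d <- buildDimer()
#' h <- helixAxis(d, "A", c(64, 136))
#' @export
helixAxis <- function(structure, chain, range) {
  ca <- calphaRows(structure@atoms, chain, range)
  if (nrow(ca) < 10)
    stop(sprintf("need >= 10 Calpha atoms in %s %d-%d, found %d",
                 chain, range[1], range[2], nrow(ca)))
  ca <- ca[order(ca$resseq), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  pa <- principalAxis(xyz)
  axis <- pa$axis
  ## orient from low to high residue number
  proj <- xyz %*% axis
  if (stats::cov(proj[, 1], as.numeric(ca$resseq)) < 0) axis <- -axis
  list(chain = chain, range = range, axis = as.numeric(axis),
       centroid = as.numeric(pa$centroid), nCalpha = nrow(ca))
}

#' Angle between two helix axes
#'
#' By default the acute-angle convention is used:
#' \code{acos(|a . b|)} in degrees, in [0, 90].  Set \code{acute = FALSE}
#' for the signed-orientation angle \code{acos(a . b)} in [0, 180].
#'
#' @param a,b helix specs from \code{\link{helixAxis}}.
#' @param acute logical, report the acute angle (default TRUE).
#' @return angle in degrees.
#' @export
interhelixAngle <- function(a, b, acute = TRUE) {
  d <- sum(a$axis * b$axis)
  d <- max(-1, min(1, d))
  if (acute) d <- abs(d)
  acos(d) * 180 / pi
}

#' Overall extent of a (dimeric) structure
#'
#' Length is the extent of the Calpha projections onto the first principal
#' axis of the Calpha cloud.  The bundle diameter is defined as twice the
#' RMS radial Calpha distance from that axis, over atoms whose projection
#' lies within the central 20 percent of the length (a measure of the
#' six-helix-bundle core girth).  Values are reported in Angstrom to match
#' crystallographic convention.
#'
#' @param structure a \code{Structure} with >= 3 Calpha atoms.
#' @return list with \code{length} and \code{bundleDiameter}, both in
#'   Angstrom.
#' @export
dimerExtent <- function(structure) {
  ca <- calphaRows(structure@atoms)
  if (nrow(ca) < 3) stop("need >= 3 Calpha atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  pa <- principalAxis(xyz)
  rel <- sweep(xyz, 2, pa$centroid)
  proj <- as.numeric(rel %*% pa$axis)
  len <- max(proj) - min(proj)
  mid <- (max(proj) + min(proj)) / 2
  central <- abs(proj - mid) <= 0.1 * len
  if (!any(central)) central <- rep(TRUE, length(proj))
  radial2 <- rowSums(rel^2) - proj^2
  radial2[radial2 < 0] <- 0
  diam <- 2 * sqrt(mean(radial2[central]))
  list(length = len * ANGSTROM_PER_NM,
       bundleDiameter = diam * ANGSTROM_PER_NM)
}
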