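#' @include AllClasses.R
NULL

## Residue names that are never lipids: amino acids, waters, common ions.
AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE", "SEC", "PYL")
SOLVENT_IONS <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "NA", "CL", "K", "MG",
                  "CA", "ZN", "NA+", "CL-", "SOD", "CLA", "POT")

#' Default lipid classification map
#'
#' Maps common residue names of the model-bilayer lipid species onto the
#' five classes POPC, POPE, POPS, PIP2 (PI(4,5)P2) and CDL (cardiolipin).
#' The marker for ordinary phospholipids is the phosphorus atom; cardiolipin
#' carries two phosphates and uses the midpoint of its two P atoms.
#'
#' @return a \code{\linkS4class{LipidClassMap}}.
#' @export
defaultLipidClassMap <- function() {
  classes <- c(POPC = "POPC", POPE = "POPE", POPS = "POPS",
               PIP2 = "PIP2", POP2 = "PIP2", SAPI = "PIP2", SAP24 = "PIP2",
               CDL = "CDL", CDL2 = "CDL", TOCL = "CDL", CL2 = "CDL")
  markers <- c(POPC = "P", POPE = "P", POPS = "P", PIP2 = "P",
               CDL = "P_midpoint", OTHER = "P")
  new("LipidClassMap", classes = classes, markers = markers)
}

#' Construct a lipid classification map
#'
#' @param classes named character vector, residue name -> class.
#' @param markers named character vector, class -> marker rule (atom-name
#'   prefix, or \code{"P_midpoint"}).
#' @return a \code{\linkS4class{LipidClassMap}}.
#' @export
lipidClassMap <- function(classes, markers = defaultLipidClassMap()@markers) {
  new("LipidClassMap", classes = classes, markers = markers)
}

isLipidResidue <- function(resname) {
  !(resname %in% AMINO3) & !(resname %in% SOLVENT_IONS)
}

#' Classify lipid residues and locate their marker atoms
#'
#' Assigns every lipid residue of a topology to a lipid class and records
#' the 0-based atom indices of its marker: the phosphorus atom for ordinary
#' phospholipids, the two phosphorus atoms (midpoint rule) for cardiolipin.
#' Residues that look like lipids (not amino acids, water or ions) but have
#' no entry in the map are assigned class OTHER with a warning.
#'
#' @param topology a \code{Structure} containing lipid residues.
#' @param map a \code{LipidClassMap} (default \code{defaultLipidClassMap()}).
#' @return data.frame with one row per lipid molecule: \code{lipid} (1-based
#'   id), \code{chain}, \code{resseq}, \code{resname}, \code{class},
#'   \code{m1}, \code{m2} (0-based marker atom indices; \code{m2} is NA
#'   except for cardiolipin).
#' @export
classifyLipids <- function(topology, map = defaultLipidClassMap()) {
  a <- topology@atoms
  lip <- a[isLipidResidue(a$resname), , drop = FALSE]
  if (nrow(lip) == 0) stop("topology contains no lipid residues")
  key <- paste(lip$chain, lip$resseq, lip$resname, sep = "\r")
  ukey <- unique(key)
  out <- data.frame(lipid = seq_along(ukey), chain = "", resseq = 0L,
                    resname = "", class = "", m1 = NA_integer_,
                    m2 = NA_integer_, stringsAsFactors = FALSE)
  unmapped <- character(0)
  for (i in seq_along(ukey)) {
    rows <- lip[key == ukey[i], , drop = FALSE]
    rn <- rows$resname[1]
    cls <- if (rn %in% names(map@classes)) unname(map@classes[rn]) else "OTHER"
    if (cls == "OTHER" && !(rn %in% names(map@classes)))
      unmapped <- c(unmapped, rn)
    pAtoms <- rows[rows$element == "P", , drop = FALSE]
    if (cls == "CDL") {
      if (nrow(pAtoms) < 2)
        stop(sprintf("cardiolipin residue %s %d:%s needs two P atoms, has %d",
                     rn, rows$resseq[1], rows$chain[1], nrow(pAtoms)))
      m1 <- pAtoms$index[1]; m2 <- pAtoms$index[2]
    } else if (cls == "OTHER" && nrow(pAtoms) == 0) {
      ## unmapped non-phosphate species: marker = first atom, best effort
      m1 <- rows$index[1]; m2 <- NA_integer_
    } else {
      if (nrow(pAtoms) == 0)
        stop(sprintf("lipid residue %s %d:%s of class %s has no P atom",
                     rn, rows$resseq[1], rows$chain[1], cls))
      m1 <- pAtoms$index[1]; m2 <- NA_integer_
    }
    out$chain[i] <- rows$chain[1]
    out$resseq[i] <- rows$resseq[1]
    out$resname[i] <- rn
    out$class[i] <- cls
    out$m1[i] <- m1
    out$m2[i] <- m2
  }
  if (length(unmapped))
    warning(sprintf("unmapped lipid residue name(s) assigned class OTHER: %s",
                    paste(unique(unmapped), collapse = ", ")))
  out
}

#' Marker positions for classified lipids
#'
#' @param classification output of \code{\link{classifyLipids}}.
#' @param positions (nAtoms x 3) coordinate matrix in nm (e.g. one frame's
#'   positions, or \code{coords(structure)}).
#' @return (nLipids x 3) matrix of marker positions in nm; cardiolipin rows
#'   are the midpoint of the two phosphorus atoms.
#' @export
markerPositions <- function(classification, positions) {
  m1 <- positions[classification$m1 + 1L, , drop = FALSE]
  two <- !is.na(classification$m2)
  if (any(two)) {
    m2 <- positions[classification$m2[two] + 1L, , drop = FALSE]
    m1[two, ] <- (m1[two, , drop = FALSE] + m2) / 2
  }
  m1
}
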