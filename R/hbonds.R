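#' @include AllClasses.R
NULL

## Heavy-atom hydrogen-bond donor/acceptor typing for the 20 standard amino
## acids.  Backbone N donates, backbone O accepts; side-chain atoms per
## residue chemistry.  Used for crystal structures without hydrogens, where
## the criterion is donor-acceptor heavy-atom distance only.

#' Heavy-atom hydrogen-bond donor/acceptor typing table
#'
#' @return data.frame with columns \code{resname} (\code{"*"} = backbone,
#'   any residue), \code{atom}, \code{role} (donor/acceptor).
#' @export
donorAcceptorTable <- function() {
  bb <- data.frame(resname = "*", atom = c("N", "O"),
                   role = c("donor", "acceptor"), stringsAsFactors = FALSE)
  sc <- rbind(
    data.frame(resname = "SER", atom = "OG",  role = c("donor", "acceptor")),
    data.frame(resname = "THR", atom = "OG1", role = c("donor", "acceptor")),
    data.frame(resname = "TYR", atom = "OH",  role = c("donor", "acceptor")),
    data.frame(resname = "ASN", atom = c("ND2", "OD1"),
               role = c("donor", "acceptor")),
    data.frame(resname = "GLN", atom = c("NE2", "OE1"),
               role = c("donor", "acceptor")),
    data.frame(resname = "LYS", atom = "NZ", role = "donor"),
    data.frame(resname = "ARG", atom = c("NE", "NH1", "NH2"), role = "donor"),
    data.frame(resname = "TRP", atom = "NE1", role = "donor"),
    data.frame(resname = "HIS", atom = c("ND1", "ND1", "NE2", "NE2"),
               role = c("donor", "acceptor", "donor", "acceptor")),
    data.frame(resname = "ASP", atom = c("OD1", "OD2"), role = "acceptor"),
    data.frame(resname = "GLU", atom = c("OE1", "OE2"), role = "acceptor"),
    data.frame(resname = "CYS", atom = "SG", role = "donor"))
  rbind(bb, sc)
}

typedAtoms <- function(a, role, table) {
  bb <- table[table$resname == "*" & table$role == role, "atom"]
  sel <- a$name %in% bb
  sc <- table[table$resname != "*" & table$role == role, , drop = FALSE]
  sel <- sel | paste(a$resname, a$name) %in% paste(sc$resname, sc$atom)
  a[sel, , drop = FALSE]
}

#' Hydrogen bonds across a chain interface
#'
#' Enumerates donor-acceptor heavy-atom pairs across the interface between
#' two chain sets with distance at most \code{dMax} Angstrom.  No angular
#' criterion is applied by default: the intended inputs are crystal
#' structures without modelled hydrogens, where only heavy-atom geometry is
#' available.  Donor/acceptor typing follows a bundled per-residue table
#' (\code{\link{donorAcceptorTable}}).
#'
#' @param structure a \code{Structure}.
#' @param chainsA,chainsB the two chain sets.
#' @param dMax donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param table donor/acceptor typing table.
#' @return data.frame with one row per bond: donor chain/resname/resseq/atom,
#'   acceptor chain/resname/resseq/atom, and \code{distance} (Angstrom),
#'   sorted by distance.  \code{nrow()} of it is the bond count.
#' @export
interfaceHBonds <- function(structure, chainsA, chainsB, dMax = 3.5,
                            table = donorAcceptorTable()) {
  a <- structure@atoms
  setA <- a[a$chain %in% chainsA, , drop = FALSE]
  setB <- a[a$chain %in% chainsB, , drop = FALSE]
  if (nrow(setA) == 0 || nrow(setB) == 0)
    stop("both chain sets must resolve to atoms")
  pairsOf <- function(don, acc) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    dx <- outer(don$x, acc$x, "-")
    dy <- outer(don$y, acc$y, "-")
    dz <- outer(don$z, acc$z, "-")
    d <- sqrt(dx^2 + dy^2 + dz^2) * ANGSTROM_PER_NM
    hit <- which(d <= dMax, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(
      donorChain = don$chain[hit[, 1]], donorResname = don$resname[hit[, 1]],
      donorResseq = don$resseq[hit[, 1]], donorAtom = don$name[hit[, 1]],
      acceptorChain = acc$chain[hit[, 2]],
      acceptorResname = acc$resname[hit[, 2]],
      acceptorResseq = acc$resseq[hit[, 2]],
      acceptorAtom = acc$name[hit[, 2]],
      distance = d[hit], stringsAsFactors = FALSE)
  }
  out <- rbind(pairsOf(typedAtoms(setA, "donor", table),
                       typedAtoms(setB, "acceptor", table)),
               pairsOf(typedAtoms(setB, "donor", table),
                       typedAtoms(setA, "acceptor", table)))
  if (is.null(out))
    out <- data.frame(donorChain = character(0), donorResname = character(0),
                      donorResseq = integer(0), donorAtom = character(0),
                      acceptorChain = character(0),
                      acceptorResname = character(0),
                      acceptorResseq = integer(0), acceptorAtom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call structural report for a dimer
#'
#' Convenience wrapper producing the static geometry summary of a BAR-domain
#' dimer: the three helix axes per chain, the inter-alpha2 angle, overall
#' extent, buried interface area and interface hydrogen bonds.
#'
#' @param structure a \code{Structure} with (at least) two protein chains.
#' @param chainsA,chainsB chain ids of the two protomers.
#' @param helixRanges named list of residue intervals (defaults: alpha1
#'   2-61, alpha2 64-136, alpha3 142-211).
#' @param ... passed to \code{\link{interfaceArea}}.
#' @return list: \code{helices}, \code{interhelixAngles} (per helix, between
#'   the two chains, acute convention), \code{extent}, \code{interface},
#'   \code{hbonds}.
#' @export
structureReport <- function(structure, chainsA = "A", chainsB = "B",
                            helixRanges = list(alpha1 = c(2, 61),
                                               alpha2 = c(64, 136),
                                               alpha3 = c(142, 211)),
                            ...) {
  helices <- list()
  angles <- list()
  for (h in names(helixRanges)) {
    hr <- helixRanges[[h]]
    specA <- tryCatch(helixAxis(structure, chainsA[1], hr),
                      error = function(e) NULL)
    specB <- tryCatch(helixAxis(structure, chainsB[1], hr),
                      error = function(e) NULL)
    helices[[h]] <- list(A = specA, B = specB)
    if (!is.null(specA) && !is.null(specB))
      angles[[h]] <- interhelixAngle(specA, specB)
  }
  list(helices = helices, interhelixAngles = angles,
       extent = dimerExtent(structure),
       interface = interfaceArea(structure, chainsA, chainsB, ...),
       hbonds = interfaceHBonds(structure, chainsA, chainsB))
}
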