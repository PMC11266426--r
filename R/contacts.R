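#' @include AllClasses.R
NULL

#' Minimum inter-group distance, optionally under periodic boundaries
#'
#' Exhaustive minimum over all atom pairs; with \code{pbc = TRUE} distances
#' use the minimum-image convention in an orthorhombic box.
#'
#' @param a,b coordinate matrices (n x 3, nm); both must be non-empty.
#' @param box numeric(3) box lengths in nm (required when \code{pbc}).
#' @param pbc logical.
#' @return minimum distance in nm.
#' @export
minDistance <- function(a, b, box = NULL, pbc = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("atom groups must be non-empty")
  if (pbc) {
    if (is.null(box) || length(box) != 3 || any(box <= 0))
      stop("pbc requires a positive numeric(3) box")
  } else box <- numeric(0)
  cpp_min_distance(a, b, as.numeric(box), isTRUE(pbc))
}

PHOSPHOLIPID_CLASSES <- c("POPC", "POPE", "POPS", "PIP2", "CDL")

proteinResidueGroups <- function(a) {
  prot <- a[a$resname %in% AMINO3 & a$element != "H", , drop = FALSE]
  if (nrow(prot) == 0) stop("topology contains no protein residues")
  key <- paste(prot$chain, prot$resseq, sep = "\r")
  ukey <- unique(key)
  list(atoms = prot, group0 = match(key, ukey) - 1L,
       residues = data.frame(
         chain = sub("\r.*", "", ukey),
         resseq = as.integer(sub(".*\r", "", ukey)),
         stringsAsFactors = FALSE))
}

#' Residue-lipid contact series
#'
#' For every protein residue and frame, records whether the minimum
#' heavy-atom distance between the residue and any lipid of the queried
#' class is within \code{cutoff} (default 0.4 nm, the interaction
#' criterion).  Also records \code{tFirstGlobal}: the time of the first
#' frame at which any residue contacts any phospholipid of any class (the
#' normalisation origin of the occupancy statistic).
#'
#' @param traj a \code{Trajectory} with at least 2 frames.
#' @param lipidClass one of POPC, POPE, POPS, PIP2, CDL, or \code{"ALL"}
#'   to pool every phospholipid class.
#' @param cutoff contact cutoff in nm (> 0; default 0.4).
#' @param pbc use the minimum-image convention (default TRUE).
#' @param map a \code{LipidClassMap}.
#' @param method \code{"grid"} (exact cell-list search) or \code{"brute"}
#'   (exhaustive all-pairs; reference path).
#' @return a \code{\linkS4class{ContactSeries}}.
#' @export
contactSeries <- function(traj, lipidClass, cutoff = 0.4, pbc = TRUE,
                          map = defaultLipidClassMap(),
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.na(traj@dt))
    stop("trajectory has a single frame: dt undefined, contact series refused")
  a <- traj@topology@atoms
  pg <- proteinResidueGroups(a)
  cls <- classifyLipids(traj@topology, map)
  classes <- if (identical(lipidClass, "ALL")) PHOSPHOLIPID_CLASSES
             else lipidClass
  if (!all(classes %in% c(PHOSPHOLIPID_CLASSES, "OTHER")))
    stop(sprintf("unknown lipid class: %s", lipidClass))
  lipRes <- cls[cls$class %in% classes, , drop = FALSE]
  if (nrow(lipRes) == 0)
    stop(sprintf("no lipids of class %s in topology", lipidClass))
  lipidAtomIdx <- function(classSet) {
    sel <- cls$class %in% classSet
    keys <- paste(cls$chain[sel], cls$resseq[sel], cls$resname[sel], sep = "\r")
    akey <- paste(a$chain, a$resseq, a$resname, sep = "\r")
    which(akey %in% keys & a$element != "H")
  }
  qIdx <- lipidAtomIdx(classes)
  allIdx <- lipidAtomIdx(PHOSPHOLIPID_CLASSES)
  protIdxRows <- pg$atoms$index + 1L  # 0-based atom index -> position row
  nf <- length(traj@times)
  nres <- nrow(pg$residues)
  contacts <- matrix(FALSE, nres, nf)
  anyGlobal <- logical(nf)
  kernel <- if (method == "grid") cpp_group_contact_grid else
    function(a, g, ng, b, cut, box, pbc)
      cpp_group_min_dist_brute(a, g, ng, b, box, pbc) <= cut
  for (f in seq_len(nf)) {
    pos <- traj@positions[[f]]
    box <- as.numeric(traj@boxes[f, ])
    if (pbc && any(box <= 0))
      stop(sprintf("frame %d has a non-positive box; pbc analysis refused", f))
    pA <- pos[protIdxRows, , drop = FALSE]
    hit <- kernel(pA, pg$group0, nres, pos[qIdx, , drop = FALSE],
                  cutoff, box, pbc)
    contacts[, f] <- as.logical(hit)
    if (identical(qIdx, allIdx)) {
      anyGlobal[f] <- any(hit)
    } else {
      hitAll <- kernel(pA, pg$group0, nres, pos[allIdx, , drop = FALSE],
                       cutoff, box, pbc)
      anyGlobal[f] <- any(hitAll)
    }
  }
  tRel <- traj@times - traj@times[1]
  tFirst <- if (any(anyGlobal)) tRel[which(anyGlobal)[1]] else NA_real_
  new("ContactSeries", residues = pg$residues,
      lipidClass = if (identical(lipidClass, "ALL")) "ALL" else lipidClass,
      contacts = contacts, times = traj@times, dt = traj@dt,
      tFirstGlobal = tFirst, cutoff = cutoff)
}

longestRun <- function(v) {
  r <- rle(v)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Normalised occupancy profile from a contact series
#'
#' Occupancy of a residue is the longest continuous period of contact,
#' divided by the simulation time elapsed after the first protein-lipid
#' contact: \code{k * dt / (T_total - tFirstGlobal)}, where \code{k} is the
#' longest run of consecutive contact frames, \code{T_total = nFrames * dt},
#' and \code{tFirstGlobal} is the first-contact time over all phospholipid
#' classes.  A value of 1 means the residue is always in contact from the
#' first protein-lipid contact onward; 0 means it never is.  Values are
#' clipped to [0, 1].
#'
#' @param series a \code{ContactSeries}.
#' @param runConvention \code{"k"} (default: a run of k frames counts as
#'   k * dt, each frame representing one sampling interval) or \code{"k-1"}
#'   (elapsed time between first and last frame of the run).
#' @return an \code{\linkS4class{OccupancyProfile}}.
#' @export
occupancyProfile <- function(series, runConvention = c("k", "k-1")) {
  runConvention <- match.arg(runConvention)
  nres <- nrow(series@contacts)
  occ <- numeric(nres)
  if (is.na(series@tFirstGlobal)) {
    warning("no protein-phospholipid contact in the run: all-zero profile")
  } else {
    nf <- ncol(series@contacts)
    Ttot <- nf * series@dt
    denom <- Ttot - series@tFirstGlobal
    for (r in seq_len(nres)) {
      k <- longestRun(series@contacts[r, ])
      if (runConvention == "k-1") k <- max(0L, k - 1L)
      occ[r] <- if (denom > 0) min(1, max(0, k * series@dt / denom)) else 0
    }
  }
  tb <- cbind(series@residues,
              data.frame(class = series@lipidClass, occupancy = occ,
                         stringsAsFactors = FALSE))
  new("OccupancyProfile", table = tb, nReplicates = 1L)
}

#' Aggregate occupancy profiles over replicates
#'
#' Element-wise mean and sample SD (n - 1) across replicate profiles sharing
#' the same residue and class index.
#'
#' @param profiles list of \code{OccupancyProfile} objects.
#' @return an \code{OccupancyProfile} whose table gains \code{mean} and
#'   \code{sd} columns (\code{sd} is NA for a single replicate).
#' @export
aggregateOccupancy <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]@table[, c("chain", "resseq", "class")]
  vals <- sapply(profiles, function(p) {
    if (!identical(p@table[, c("chain", "resseq", "class")], ref))
      stop("profiles have mismatched residue/class indices")
    p@table$occupancy
  })
  vals <- matrix(vals, nrow = nrow(ref))
  tb <- ref
  tb$occupancy <- rowMeans(vals)
  tb$mean <- rowMeans(vals)
  tb$sd <- if (ncol(vals) >= 2) apply(vals, 1, stats::sd) else NA_real_
  new("OccupancyProfile", table = tb,
      nReplicates = as.integer(length(profiles)))
}

#' @rdname asTable
#' @export
setMethod("asTable", "OccupancyProfile", function(x) x@table)

#' Default membrane-binding residue clusters
#'
#' The two positively charged clusters on the concave face used as named
#' residue sets in contact analyses: cluster1 = 107, 109, 110 (Lys/Lys/Arg)
#' and cluster2 = 132, 134, 136 (Arg/Arg/Arg).
#'
#' @return named list of residue-number vectors.
#' @export
bindingSiteAnnotation <- function() {
  list(cluster1 = c(107L, 109L, 110L), cluster2 = c(132L, 134L, 136L))
}
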