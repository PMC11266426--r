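#' @include AllClasses.R
NULL

#' Default concave-angle residue groups
#'
#' The concave-angle groups: arm tips = Calpha centroid of residues 132-136
#' of each chain (the distal-arm membrane-binding cluster), center = Calpha
#' centroid of residues 2-10 of both chains (the six-helix-bundle core).
#' Fully configurable; the exact inset triplet of the source analysis is
#' pictorial, so this is a documented stand-in recorded in outputs.
#'
#' @param chainA,chainB chain ids of the two protomers.
#' @return list of three selections, each \code{list(chain =, resseq =)}.
#' @export
defaultAngleGroups <- function(chainA = "A", chainB = "B") {
  list(armTipA = list(chain = chainA, resseq = 132:136),
       center = list(chain = c(chainA, chainB), resseq = 2:10),
       armTipB = list(chain = chainB, resseq = 132:136))
}

resolveSelection <- function(a, sel) {
  rows <- a$name == "CA" & a$element != "CA" & a$chain %in% sel$chain &
    a$resseq %in% sel$resseq
  which(rows)
}

#' Calpha centroid of a residue selection in one frame
#'
#' @param positions (nAtoms x 3) frame coordinates in nm.
#' @param topology the \code{Structure} the rows refer to.
#' @param selection \code{list(chain =, resseq =)}.
#' @return numeric(3) unweighted mean Calpha position in nm.
#' @export
groupCentroid <- function(positions, topology, selection) {
  rows <- resolveSelection(topology@atoms, selection)
  if (length(rows) == 0)
    stop(sprintf("selection resolves to no Calpha atoms (chains %s, residues %s)",
                 paste(selection$chain, collapse = ","),
                 paste(range(selection$resseq), collapse = "-")))
  colMeans(positions[rows, , drop = FALSE])
}

angleAt <- function(center, tipA, tipB) {
  u <- tipA - center; v <- tipB - center
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("coincident centroids")
  d <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Concave-angle time series of the dimer
#'
#' Per frame, the angle at the central residue-group centroid subtended by
#' the two arm-tip centroids (degrees).  Optionally smoothed with a centered
#' moving average.
#'
#' @param traj a \code{Trajectory}.
#' @param groups three selections as from \code{\link{defaultAngleGroups}}.
#' @param smoothWindow odd integer window for a centered moving average
#'   (default 1 = no smoothing).
#' @return an \code{\linkS4class{AngleSeries}} (single replicate column).
#' @export
angleSeries <- function(traj, groups = defaultAngleGroups(),
                        smoothWindow = 1L) {
  stopifnot(length(groups) == 3)
  a <- traj@topology
  nf <- length(traj@times)
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    pos <- traj@positions[[f]]
    ctr <- groupCentroid(pos, a, groups[[2]])
    tA <- groupCentroid(pos, a, groups[[1]])
    tB <- groupCentroid(pos, a, groups[[3]])
    ang[f] <- tryCatch(angleAt(ctr, tA, tB),
                       error = function(e)
                         stop(sprintf("frame %d: %s", f, conditionMessage(e))))
  }
  if (smoothWindow > 1) {
    if (smoothWindow %% 2 == 0) stop("smoothing window must be odd")
    k <- rep(1 / smoothWindow, smoothWindow)
    sm <- stats::filter(ang, k, sides = 2)
    ang <- ifelse(is.na(sm), ang, as.numeric(sm))
  }
  new("AngleSeries", times = traj@times, angles = matrix(ang, ncol = 1),
      mean = numeric(0), sd = numeric(0), groups = groups)
}

#' Aggregate angle series across replicates
#'
#' @param seriesList list of \code{AngleSeries} on identical time bases.
#' @return an \code{AngleSeries} with all replicate columns and per-time
#'   \code{mean} and sample \code{sd} populated.
#' @export
aggregateAngles <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  ref <- seriesList[[1]]
  for (s in seriesList[-1])
    if (!isTRUE(all.equal(s@times, ref@times)))
      stop("angle series have mismatched time bases")
  m <- do.call(cbind, lapply(seriesList, function(s) s@angles))
  new("AngleSeries", times = ref@times, angles = m,
      mean = rowMeans(m),
      sd = if (ncol(m) >= 2) apply(m, 1, stats::sd) else
        rep(NA_real_, nrow(m)),
      groups = ref@groups)
}

#' @rdname asTable
#' @export
setMethod("asTable", "AngleSeries", function(x) {
  tb <- data.frame(time_ps = x@times)
  for (j in seq_len(ncol(x@angles)))
    tb[[paste0("angle_deg_rep", j)]] <- x@angles[, j]
  if (length(x@mean)) {
    tb$mean_deg <- x@mean
    tb$sd_deg <- x@sd
  }
  tb
})
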