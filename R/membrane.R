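#' @include AllClasses.R
NULL

#' Assign lipids to bilayer leaflets
#'
#' Default method: a lipid belongs to the upper leaflet when its marker z
#' exceeds the instantaneous mean marker z (global midplane).  The
#' \code{"local"} method uses a local midplane: the mean marker z of the
#' lipid's lateral neighbourhood (radius \code{localRadius} in xy),
#' which tolerates strongly bent membranes.
#'
#' @param markers (nLipids x 3) marker position matrix in nm.
#' @param method \code{"global"} (default) or \code{"local"}.
#' @param localRadius lateral neighbourhood radius in nm for the local
#'   method (default 3).
#' @return list with integer vectors \code{upper} and \code{lower} (row
#'   indices into \code{markers}).
#' @export
assignLeaflets <- function(markers, method = c("global", "local"),
                           localRadius = 3) {
  method <- match.arg(method)
  markers <- as.matrix(markers)
  if (nrow(markers) < 2) stop("need at least 2 lipids")
  z <- markers[, 3]
  if (max(z) - min(z) < 1e-9)
    stop("all markers coplanar at one z: not a bilayer")
  if (method == "global") {
    mid <- mean(z)
    up <- z > mid
  } else {
    up <- logical(length(z))
    for (i in seq_along(z)) {
      d2 <- (markers[, 1] - markers[i, 1])^2 + (markers[, 2] - markers[i, 2])^2
      nb <- d2 <= localRadius^2
      up[i] <- z[i] > mean(z[nb])
    }
  }
  list(upper = which(up), lower = which(!up))
}

## In-plane alignment of a frame on the protein: recenter on the protein
## centre of geometry and optionally rotate so the protein's first in-plane
## principal axis lies along x.
alignFrameXY <- function(markerXY, proteinXYZ, alignment) {
  if (alignment == "none") return(markerXY)
  ctr <- colMeans(proteinXYZ[, 1:2, drop = FALSE])
  out <- sweep(markerXY, 2, ctr)
  if (alignment == "protein_aligned") {
    rel <- sweep(proteinXYZ[, 1:2, drop = FALSE], 2, ctr)
    sv <- svd(rel)
    v1 <- sv$v[, 1]
    ## orient v1 toward the first protein atom with a clear projection
    ## (atom order co-rotates with the molecule, unlike odd moments,
    ## which vanish for symmetric rods)
    proj <- rel %*% v1
    lead <- which(abs(proj) > 1e-6)[1]
    if (!is.na(lead) && proj[lead] < 0) v1 <- -v1
    R <- rbind(c(v1[1], v1[2]), c(-v1[2], v1[1]))
    out <- out %*% t(R)
  }
  out
}

#' Time-averaged 2D lipid density map
#'
#' Bins the lateral (xy) positions of one lipid class's markers per frame,
#' averages the per-bin counts over the frames of the averaging window, and
#' divides by the bin area, giving mean number density in lipids/nm^2.
#' With \code{alignment = "protein_centered"} frames are recentred on the
#' protein centre of geometry first; \code{"protein_aligned"} additionally
#' rotates each frame in-plane so the protein's first principal axis lies
#' along x (the default for diffusing monomers, otherwise the map smears).
#'
#' @param traj a \code{Trajectory}.
#' @param lipidClass the mapped class to map.
#' @param windowPs length of the trailing averaging window in ps (default
#'   100000, i.e. the last 100 ns; truncated to the trajectory span).
#' @param binNm bin width in nm (default 0.2).
#' @param alignment "none", "protein_centered" or "protein_aligned".
#' @param map a \code{LipidClassMap}.
#' @return a \code{\linkS4class{DensityMap2D}}.
#' @export
densityMap2D <- function(traj, lipidClass, windowPs = 1e5, binNm = 0.2,
                         alignment = c("protein_aligned", "protein_centered",
                                       "none"),
                         map = defaultLipidClassMap()) {
  alignment <- match.arg(alignment)
  if (binNm <= 0) stop("bin width must be > 0")
  cls <- classifyLipids(traj@topology, map)
  sel <- cls$class == lipidClass
  if (!any(sel)) stop(sprintf("no lipids of class %s", lipidClass))
  cls <- cls[sel, , drop = FALSE]
  if (windowPs <= 0) stop("empty averaging window")
  tEnd <- traj@times[length(traj@times)]
  frames <- which(traj@times >= tEnd - windowPs - 1e-9)
  if (length(frames) == 0) stop("empty averaging window")
  a <- traj@topology@atoms
  protRows <- which(a$resname %in% AMINO3) # may be empty for pure bilayers
  if (alignment != "none" && length(protRows) == 0)
    stop("protein alignment requested but topology has no protein")
  box <- traj@boxes[frames[1], ]
  if (alignment == "none") {
    xedges <- seq(0, box[1], by = binNm)
    yedges <- seq(0, box[2], by = binNm)
    if (xedges[length(xedges)] < box[1]) xedges <- c(xedges, box[1])
    if (yedges[length(yedges)] < box[2]) yedges <- c(yedges, box[2])
  } else {
    hx <- box[1] / 2; hy <- box[2] / 2
    xedges <- seq(-hx, hx, by = binNm)
    yedges <- seq(-hy, hy, by = binNm)
  }
  nx <- length(xedges) - 1L; ny <- length(yedges) - 1L
  acc <- matrix(0, nx, ny)
  totCount <- 0
  for (f in frames) {
    pos <- traj@positions[[f]]
    mk <- markerPositions(cls, pos)
    xy <- mk[, 1:2, drop = FALSE]
    if (alignment == "none") {
      ## wrap into the box
      xy[, 1] <- xy[, 1] %% box[1]
      xy[, 2] <- xy[, 2] %% box[2]
    } else {
      xy <- alignFrameXY(xy, pos[protRows, , drop = FALSE], alignment)
    }
    ix <- findInterval(xy[, 1], xedges, rightmost.closed = TRUE,
                       all.inside = FALSE)
    iy <- findInterval(xy[, 2], yedges, rightmost.closed = TRUE,
                       all.inside = FALSE)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    totCount <- totCount + sum(ok)
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(nx)),
                   factor(iy[ok], levels = seq_len(ny)))
      acc <- acc + unclass(tab)
    }
  }
  nfw <- length(frames)
  ## last bin may be narrower when the box is not a multiple of binNm
  wx <- diff(xedges); wy <- diff(yedges)
  areas <- outer(wx, wy)
  grid <- (acc / nfw) / areas
  new("DensityMap2D", lipidClass = lipidClass, xedges = xedges,
      yedges = yedges, grid = grid,
      windowPs = c(traj@times[frames[1]], tEnd), alignment = alignment,
      meanCount = totCount / nfw)
}

#' @rdname asTable
#' @export
setMethod("asTable", "DensityMap2D", function(x) {
  xc <- (x@xedges[-1] + x@xedges[-length(x@xedges)]) / 2
  yc <- (x@yedges[-1] + x@yedges[-length(x@yedges)]) / 2
  data.frame(x_nm = rep(xc, times = length(yc)),
             y_nm = rep(yc, each = length(xc)),
             density_per_nm2 = as.vector(x@grid))
})

#' Leaflet height profile along the membrane long axis
#'
#' Bins the selected leaflet's marker positions along x (default bin width
#' 1 nm) at a fixed sampling stride (default every 200 ps) and reports the
#' per-bin mean marker z over all sampled frames.  Leaflets are re-assigned
#' per sampled frame.  Bins that never receive a marker are flagged missing
#' (NA mean), never interpolated.
#'
#' @param traj a \code{Trajectory} of a bilayer system.
#' @param leaflet "upper", "lower" or "both".
#' @param binNm bin width along x in nm (default 1).
#' @param sampleEveryPs sampling stride in ps (default 200); must be an
#'   integer multiple of the trajectory dt.
#' @param map a \code{LipidClassMap}.
#' @param leafletMethod passed to \code{\link{assignLeaflets}}.
#' @return a \code{\linkS4class{HeightProfile}}.
#' @export
heightProfile <- function(traj, leaflet = c("upper", "lower", "both"),
                          binNm = 1.0, sampleEveryPs = 200,
                          map = defaultLipidClassMap(),
                          leafletMethod = "global") {
  leaflet <- match.arg(leaflet)
  if (binNm <= 0) stop("bin width must be > 0")
  cls <- classifyLipids(traj@topology, map)
  nf <- length(traj@times)
  if (nf >= 2) {
    ratio <- sampleEveryPs / traj@dt
    if (abs(ratio - round(ratio)) > 1e-9)
      stop(sprintf("sampling stride %g ps is not a multiple of dt = %g ps",
                   sampleEveryPs, traj@dt))
    stride <- max(1L, as.integer(round(ratio)))
  } else stride <- 1L
  frames <- seq(1L, nf, by = stride)
  box <- traj@boxes[1, ]
  edges <- seq(0, box[1], by = binNm)
  if (edges[length(edges)] < box[1] - 1e-9) edges <- c(edges, box[1])
  nb <- length(edges) - 1L
  sumZ <- numeric(nb); cnt <- integer(nb)
  for (f in frames) {
    pos <- traj@positions[[f]]
    mk <- markerPositions(cls, pos)
    rows <- seq_len(nrow(mk))
    if (leaflet != "both") {
      lf <- assignLeaflets(mk, method = leafletMethod)
      rows <- lf[[leaflet]]
    }
    x <- mk[rows, 1] %% box[1]
    z <- mk[rows, 3]
    ib <- findInterval(x, edges, rightmost.closed = TRUE)
    ok <- ib >= 1 & ib <= nb
    sumZ <- sumZ + as.numeric(tapply(z[ok], factor(ib[ok], levels = seq_len(nb)),
                                     sum, default = 0))
    cnt <- cnt + as.integer(table(factor(ib[ok], levels = seq_len(nb))))
  }
  meanZ <- ifelse(cnt > 0, sumZ / pmax(cnt, 1L), NA_real_)
  new("HeightProfile",
      binCenters = (edges[-1] + edges[-length(edges)]) / 2,
      meanZ = meanZ, sd = rep(NA_real_, nb), n = cnt, missing = cnt == 0L,
      leaflet = leaflet, binWidth = binNm)
}

#' Aggregate height profiles across replicates
#'
#' Per-bin mean and sample SD (n - 1) of the replicate per-bin means.  Bins
#' missing in any replicate stay flagged missing.
#'
#' @param profiles list of \code{HeightProfile} objects on identical bins.
#' @return a \code{HeightProfile} with the \code{sd} slot populated.
#' @export
aggregateProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p@binCenters, ref@binCenters)))
      stop("profiles have mismatched bins")
  }
  m <- sapply(profiles, function(p) p@meanZ)
  m <- matrix(m, nrow = length(ref@binCenters))
  miss <- apply(is.na(m), 1, any)
  new("HeightProfile", binCenters = ref@binCenters,
      meanZ = ifelse(miss, NA_real_, rowMeans(m)),
      sd = if (ncol(m) >= 2) apply(m, 1, stats::sd) else
        rep(NA_real_, nrow(m)),
      n = as.integer(Reduce(`+`, lapply(profiles, function(p) p@n))),
      missing = miss, leaflet = ref@leaflet, binWidth = ref@binWidth)
}

#' @rdname asTable
#' @export
setMethod("asTable", "HeightProfile", function(x)
  data.frame(bin_center_nm = x@binCenters, mean_z_nm = x@meanZ,
             sd_nm = x@sd, n = x@n, missing = x@missing))

#' Signed curvature estimate along a height profile
#'
#' Estimates kappa(x) = -z'' / (1 + z'^2)^(3/2) per bin by central finite
#' differences on the binned means.  The sign convention is: a bulge toward
#' the protein side (+z, the upper-leaflet face the dimer binds) is
#' positive; mirroring the profile in z flips the sign.  Requires at least
#' 5 consecutive non-missing bins; end bins and neighbours of missing bins
#' are NA.
#'
#' @param profile a \code{HeightProfile}.
#' @return data.frame with \code{bin_center_nm} and \code{curvature_per_nm}.
#' @export
curvatureEstimate <- function(profile) {
  z <- profile@meanZ
  x <- profile@binCenters
  ok <- !is.na(z)
  if (max(rle(ok)$lengths[rle(ok)$values], 0) < 5)
    stop("need at least 5 consecutive non-missing bins")
  n <- length(z)
  h <- profile@binWidth
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    if (ok[i - 1] && ok[i] && ok[i + 1]) {
      zp <- (z[i + 1] - z[i - 1]) / (2 * h)
      zpp <- (z[i + 1] - 2 * z[i] + z[i - 1]) / h^2
      kappa[i] <- -zpp / (1 + zp^2)^1.5
    }
  }
  data.frame(bin_center_nm = x, curvature_per_nm = kappa)
}
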