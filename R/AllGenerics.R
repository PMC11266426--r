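#' @include AllClasses.R
NULL

#' Accessors for structure and trajectory objects
#'
#' \code{atoms} returns the atom table; \code{coords} the (n x 3) coordinate
#' matrix in nm; \code{nAtoms} the atom count; \code{boxDims} the box vector
#' (nm); \code{nFrames} the frame count; \code{frameTimes} the frame times
#' (ps); \code{timeStep} the uniform spacing dt (ps).
#'
#' @param x a \code{Structure} or \code{Trajectory}.
#' @return See individual descriptions.
#' @name accessors
#' @aliases atoms coords nAtoms boxDims nFrames frameTimes timeStep
#' @examples
#' s <- buildDimer()
#' nAtoms(s)
#' head(atoms(s))
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("coords", "Structure", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("boxDims", "Structure", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@times))
#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("timeStep", "Trajectory", function(x) x@dt)

#' Extract one frame from a trajectory
#'
#' @param x a \code{Trajectory}.
#' @param i frame index (1-based).
#' @return list with elements \code{time} (ps), \code{box} (nm, numeric(3))
#'   and \code{positions} (nAtoms x 3 matrix, nm).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
  stopifnot(i >= 1, i <= length(x@times))
  list(time = x@times[i], box = x@boxes[i, ], positions = x@positions[[i]])
})

#' Topology of a trajectory
#' @param x a \code{Trajectory}.
#' @return the topology \code{Structure}.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' Tidy table view of result objects
#'
#' Converts an analysis result to a plain data.frame suitable for writing as
#' CSV: one row per residue for occupancy profiles, per bin for height
#' profiles, per (x, y) cell for density maps, per time point for angle
#' series.
#'
#' @param x a result object.
#' @return a data.frame.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              nrow(unique(a[, c("chain", "resseq")]))))
  if (length(object@box) == 3)
    cat(sprintf("  box: %.3f x %.3f x %.3f nm\n",
                object@box[1], object@box[2], object@box[3]))
  cat(sprintf("  source units: %s (stored in nm)\n", object@sourceUnits))
})

setMethod("show", "Trajectory", function(object) {
  nf <- length(object@times)
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %s ps, span %.0f ps\n",
              nf, nrow(object@topology@atoms),
              ifelse(is.na(object@dt), "NA", format(object@dt)),
              diff(range(object@times))))
})

setMethod("show", "ContactSeries", function(object) {
  cat(sprintf("ContactSeries [%s]: %d residues x %d frames, cutoff %.2f nm\n",
              object@lipidClass, nrow(object@contacts), ncol(object@contacts),
              object@cutoff))
  cat(sprintf("  first global phospholipid contact: %s\n",
              ifelse(is.na(object@tFirstGlobal), "never",
                     sprintf("%.0f ps", object@tFirstGlobal))))
})

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf("OccupancyProfile: %d residue/class rows, %d replicate(s)\n",
              nrow(object@table), object@nReplicates))
})

setMethod("show", "DensityMap2D", function(object) {
  cat(sprintf(
    "DensityMap2D [%s]: %d x %d bins, window %.0f-%.0f ps, alignment %s\n",
    object@lipidClass, nrow(object@grid), ncol(object@grid),
    object@windowPs[1], object@windowPs[2], object@alignment))
})

setMethod("show", "HeightProfile", function(object) {
  cat(sprintf(
    "HeightProfile [%s leaflet]: %d bins of %.1f nm, %d missing\n",
    object@leaflet, length(object@binCenters), object@binWidth,
    sum(object@missing)))
})

setMethod("show", "AngleSeries", function(object) {
  cat(sprintf("AngleSeries: %d frames x %d replicate(s), range %.1f-%.1f deg\n",
              nrow(object@angles), ncol(object@angles),
              min(object@angles), max(object@angles)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %s, seed %d, %d frames @ %g ps, %d replicate(s)\n",
              object@system, object@seed, object@nFrames, object@dtPs,
              object@nReplicates))
  cat(sprintf("  composition: %s\n",
              paste(sprintf("%s=%.3f", names(object@composition),
                            object@composition), collapse = " ")))
  cat(sprintf("  height field: %s, noise sigma %.3f nm\n",
              object@heightField$type, object@noiseSigma))
})
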