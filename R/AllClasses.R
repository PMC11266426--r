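#' @import methods
NULL

#' Molecular structure container
#'
#' Holds an ordered atom table with chain/residue identity and coordinates.
#' All coordinates are stored in nanometres regardless of the source file's
#' units; readers convert on the way in.  The atom table has columns
#' \code{index} (0-based, contiguous), \code{name}, \code{element},
#' \code{resname}, \code{resseq} (1-based, as in the source file),
#' \code{chain}, and \code{x}, \code{y}, \code{z} (nm).
#'
#' @slot atoms data.frame of atom records (see Details).
#' @slot box numeric(3) orthorhombic box lengths in nm, or numeric(0) when
#'   the structure is aperiodic.
#' @slot sourceUnits either \code{"angstrom"} or \code{"nm"}: the units of
#'   the file the structure was read from (informational; slots are nm).
#' @export
setClass("Structure",
  representation(atoms = "data.frame", box = "numeric",
                 sourceUnits = "character"),
  prototype(atoms = data.frame(), box = numeric(0), sourceUnits = "nm"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("index", "name", "element", "resname", "resseq", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (anyDuplicated(a$index)) return("atom indices must be unique")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all atom positions must be finite")
  if (any(!nzchar(a$chain))) return("chain ids must be non-empty")
  if (length(object@box) > 0 && length(object@box) != 3)
    return("box must be numeric(3) or numeric(0)")
  if (!object@sourceUnits %in% c("angstrom", "nm"))
    return("sourceUnits must be 'angstrom' or 'nm'")
  TRUE
})

#' Trajectory container
#'
#' Time-ordered frames over a fixed topology.  Frame times must be strictly
#' increasing and uniformly spaced (relative deviation from \code{dt} below
#' 1e-6).  A single-frame trajectory is valid with \code{dt = NA}; operations
#' that normalise by time refuse it.
#'
#' @slot topology a \code{\linkS4class{Structure}} giving atom identities.
#' @slot times numeric vector of frame times in ps.
#' @slot boxes matrix (nFrames x 3) of per-frame box lengths in nm.
#' @slot positions list of (nAtoms x 3) coordinate matrices in nm.
#' @slot dt uniform frame spacing in ps (NA for a single frame).
#' @export
setClass("Trajectory",
  representation(topology = "Structure", times = "numeric",
                 boxes = "matrix", positions = "list", dt = "numeric"))

setValidity("Trajectory", function(object) {
  nf <- length(object@times)
  if (nf == 0) return("trajectory has no frames")
  if (length(object@positions) != nf || nrow(object@boxes) != nf)
    return("times, boxes and positions must agree in frame count")
  na <- nrow(object@topology@atoms)
  for (i in seq_len(nf)) {
    p <- object@positions[[i]]
    if (!is.matrix(p) || nrow(p) != na || ncol(p) != 3)
      return(sprintf("frame %d positions must be a %d x 3 matrix", i, na))
  }
  if (nf >= 2) {
    dts <- diff(object@times)
    if (any(dts <= 0)) return("frame times must be strictly increasing")
    dt <- object@dt
    if (!is.finite(dt) || dt <= 0) return("dt must be positive for >1 frame")
    if (any(abs(dts - dt) / dt >= 1e-6))
      return("frame spacing is not uniform (relative deviation >= 1e-6)")
  }
  TRUE
})

#' Lipid classification map
#'
#' Maps lipid residue names onto the bilayer's lipid classes and records the
#' marker rule for each class.  The marker is the phosphorus ("P") atom for
#' ordinary phospholipids; cardiolipin (class \code{CDL}) carries two
#' phosphates and its marker is the midpoint of the two P atoms.
#'
#' @slot classes named character: residue name -> class; classes are one of
#'   POPC, POPE, POPS, PIP2, CDL, OTHER.
#' @slot markers named character: class -> marker rule, either an atom-name
#'   prefix (matched against atom names, element P) or \code{"P_midpoint"}.
#' @export
setClass("LipidClassMap",
  representation(classes = "character", markers = "character"))

setValidity("LipidClassMap", function(object) {
  ok <- c("POPC", "POPE", "POPS", "PIP2", "CDL", "OTHER")
  if (!all(object@classes %in% ok))
    return("classes must map onto POPC/POPE/POPS/PIP2/CDL/OTHER")
  if (is.null(names(object@classes)) || any(!nzchar(names(object@classes))))
    return("classes must be named by residue name")
  TRUE
})

#' Residue-lipid contact record
#'
#' Boolean residue x frame contact matrix for one lipid class, together with
#' the time base and the global first-contact time used to normalise
#' occupancy.  \code{tFirstGlobal} is the time (ps, relative to the first
#' frame) of the first frame at which any residue contacts any phospholipid
#' of any class; \code{NA} if no contact ever occurs.
#'
#' @slot residues data.frame with columns chain, resseq identifying matrix rows.
#' @slot lipidClass character scalar, the queried class.
#' @slot contacts logical matrix, residues x frames.
#' @slot times numeric frame times in ps.
#' @slot dt frame spacing in ps.
#' @slot tFirstGlobal numeric scalar (ps, relative to first frame) or NA.
#' @slot cutoff contact cutoff in nm.
#' @export
setClass("ContactSeries",
  representation(residues = "data.frame", lipidClass = "character",
                 contacts = "matrix", times = "numeric", dt = "numeric",
                 tFirstGlobal = "numeric", cutoff = "numeric"))

setValidity("ContactSeries", function(object) {
  if (!is.logical(object@contacts)) return("contacts must be logical")
  if (nrow(object@contacts) != nrow(object@residues))
    return("contact rows must match residues")
  if (ncol(object@contacts) != length(object@times))
    return("contact columns must match frame count")
  TRUE
})

#' Normalized occupancy profile
#'
#' Per-residue occupancy in [0, 1]: the longest continuous contact period,
#' normalised by the simulation time elapsed after the first protein-lipid
#' contact.  When aggregated over replicates, \code{mean} and \code{sd}
#' columns are populated (sample SD, n - 1).
#'
#' @slot table data.frame with columns chain, resseq, class, occupancy and,
#'   after aggregation, mean and sd.
#' @slot nReplicates integer, 1 for a single-run profile.
#' @export
setClass("OccupancyProfile",
  representation(table = "data.frame", nReplicates = "integer"))

setValidity("OccupancyProfile", function(object) {
  tb <- object@table
  if (!all(c("chain", "resseq", "class", "occupancy") %in% names(tb)))
    return("table needs columns chain, resseq, class, occupancy")
  occ <- tb$occupancy[!is.na(tb$occupancy)]
  if (length(occ) && (min(occ) < 0 || max(occ) > 1))
    return("occupancy must lie in [0, 1]")
  TRUE
})

#' Time-averaged 2D lipid density map
#'
#' Mean number density (lipids/nm^2) of one lipid class on an xy grid,
#' averaged over an averaging window of frames, optionally in a
#' protein-centered or protein-aligned frame.
#'
#' @slot lipidClass character scalar.
#' @slot xedges,yedges numeric bin edges in nm.
#' @slot grid numeric matrix (nx x ny) of mean number density, lipids/nm^2.
#' @slot windowPs numeric(2), the averaged time window in ps.
#' @slot alignment one of "none", "protein_centered", "protein_aligned".
#' @slot meanCount mean number of in-region lipids per frame (conservation
#'   reference).
#' @export
setClass("DensityMap2D",
  representation(lipidClass = "character", xedges = "numeric",
                 yedges = "numeric", grid = "matrix", windowPs = "numeric",
                 alignment = "character", meanCount = "numeric"))

setValidity("DensityMap2D", function(object) {
  if (any(object@grid < 0)) return("density must be non-negative")
  if (nrow(object@grid) != length(object@xedges) - 1L ||
      ncol(object@grid) != length(object@yedges) - 1L)
    return("grid dimensions must match bin edges")
  TRUE
})

#' Leaflet height profile along the membrane long axis
#'
#' Per-bin mean phosphate z (nm) binned along x, with per-bin sample counts;
#' empty bins are flagged missing, never interpolated.  After replicate
#' aggregation the \code{sd} slot holds the across-replicate SD per bin.
#'
#' @slot binCenters numeric bin centers in nm.
#' @slot meanZ numeric per-bin mean marker z in nm (NA where missing).
#' @slot sd numeric per-bin SD (across replicates; NA for single run).
#' @slot n integer per-bin sample count.
#' @slot missing logical flag per bin.
#' @slot leaflet "upper", "lower" or "both".
#' @slot binWidth nm.
#' @export
setClass("HeightProfile",
  representation(binCenters = "numeric", meanZ = "numeric", sd = "numeric",
                 n = "integer", missing = "logical", leaflet = "character",
                 binWidth = "numeric"))

setValidity("HeightProfile", function(object) {
  k <- length(object@binCenters)
  if (length(object@meanZ) != k || length(object@n) != k ||
      length(object@missing) != k)
    return("profile slots must have equal length")
  if (any(object@missing & !is.na(object@meanZ)))
    return("missing bins must have NA mean")
  TRUE
})

#' Dimer concave-angle time series
#'
#' The angle (degrees) subtended at a central residue-group centroid by the
#' two arm-tip centroids, per frame, for one or more replicates.
#'
#' @slot times numeric frame times in ps.
#' @slot angles numeric matrix, frames x replicates, degrees in (0, 180].
#' @slot mean,sd per-time mean and sample SD across replicates (length 0
#'   until aggregated).
#' @slot groups the residue selections used (list of three selections).
#' @export
setClass("AngleSeries",
  representation(times = "numeric", angles = "matrix", mean = "numeric",
                 sd = "numeric", groups = "list"))

setValidity("AngleSeries", function(object) {
  if (nrow(object@angles) != length(object@times))
    return("angle rows must match times")
  if (!all(is.finite(object@angles))) return("angles must be finite")
  if (any(object@angles <= 0 | object@angles > 180))
    return("angles must lie in (0, 180]")
  TRUE
})

#' Seeded recipe for synthetic systems
#'
#' A reproducible specification of a synthetic BAR-dimer/bilayer system:
#' geometry, lipid composition, prescribed leaflet height field, noise, frame
#' schedule, scripted residue-lipid contacts and a concave-angle ramp.  The
#' same seed always yields bit-identical outputs; replicate r uses the
#' derived seed \code{seed + 7919 * r}.
#'
#' @slot seed integer master seed.
#' @slot system "monomer_18nm" (18 nm cube, protein 3.4 nm above the
#'   bilayer) or "dimer_45x15x15" (45 x 15 x 15 nm box, dimer 0.2 nm above).
#' @slot composition named numeric mole fractions over POPC/POPE/POPS/PIP2/
#'   CDL summing to 1; default is the mitochondrial-inner-membrane-like
#'   liposome ratio 40:32:3:5:18 renormalised.
#' @slot areaPerLipid nm^2 per lipid per leaflet (default 0.65).
#' @slot heightField list(type = "flat"|"gaussian_bump"|"sinusoid", ...).
#' @slot noiseSigma thermal z-noise SD in nm.
#' @slot nFrames,dtPs frame schedule (dt default 200 ps).
#' @slot proteinOffset nm above the upper-leaflet surface (NA = system default).
#' @slot nReplicates default 3.
#' @slot contactSchedule data.frame(resseq, chain, tOn, tOff, class) in ps.
#' @slot angleRamp numeric(2) target concave angle at first/last frame, or
#'   numeric(0) for no ramp.
#' @slot armAngleDeg inter-arm (inter-helix) angle of the built dimer.
#' @slot totalLengthNm end-to-end dimer length.
#' @slot residuesPerArm residues per chain (numbered from 2).
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", system = "character",
                 composition = "numeric", areaPerLipid = "numeric",
                 heightField = "list", noiseSigma = "numeric",
                 nFrames = "integer", dtPs = "numeric",
                 proteinOffset = "numeric", nReplicates = "integer",
                 contactSchedule = "data.frame", angleRamp = "numeric",
                 armAngleDeg = "numeric", totalLengthNm = "numeric",
                 residuesPerArm = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!object@system %in% c("monomer_18nm", "dimer_45x15x15"))
    return("system must be monomer_18nm or dimer_45x15x15")
  if (abs(sum(object@composition) - 1) > 1e-9)
    return("composition mole fractions must sum to 1 (tolerance 1e-9)")
  if (any(object@composition < 0)) return("mole fractions must be >= 0")
  if (!length(names(object@composition)))
    return("composition must be named by lipid class")
  if (length(object@angleRamp) && length(object@angleRamp) != 2)
    return("angleRamp must be numeric(2) or empty")
  if (object@nFrames < 1) return("nFrames must be >= 1")
  if (object@dtPs <= 0) return("dtPs must be > 0")
  TRUE
})
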