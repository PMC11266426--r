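#' @include AllClasses.R
NULL

ANGSTROM_PER_NM <- 10

## Internal constructors -----------------------------------------------------

newStructure <- function(atoms, box = numeric(0), sourceUnits = "nm") {
  atoms$index <- as.integer(seq_len(nrow(atoms)) - 1L)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, box = as.numeric(box),
      sourceUnits = sourceUnits)
}

newTrajectory <- function(topology, times, boxes, positions) {
  times <- as.numeric(times)
  nf <- length(times)
  dt <- if (nf >= 2) (times[nf] - times[1]) / (nf - 1) else NA_real_
  if (nf >= 2) {
    dts <- diff(times)
    if (any(dts <= 0)) {
      bad <- which(dts <= 0)[1]
      stop(sprintf("frame times must be strictly increasing (frame %d)", bad + 1L))
    }
    ref <- dts[1]  # first interval sets dt; later deviations name their frame
    off <- abs(dts - ref) / ref
    if (any(off >= 1e-6)) {
      bad <- which(off >= 1e-6)[1]
      stop(sprintf("non-uniform frame spacing at frame %d (dt = %g, got %g)",
                   bad + 1L, ref, dts[bad]))
    }
  }
  new("Trajectory", topology = topology, times = times,
      boxes = boxes, positions = positions, dt = dt)
}

## Element inference: two-letter element symbols recognised when the whole
## (digit-stripped) atom name matches; otherwise the first alphabetic char.
guessElement <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- c("CL", "BR", "NA", "MG", "FE", "ZN", "SE", "MN", "CU", "NI")
  ifelse(nm %in% two, nm,
         ifelse(nzchar(nm), substr(nm, 1, 1), ""))
}

## PDB -----------------------------------------------------------------------

#' Read a PDB file into a Structure
#'
#' Parses ATOM/HETATM records (via bio3d), keeping the first model only.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (first wins on a tie).  Coordinates are converted from
#' Angstrom to nm.  Files containing insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @return a \code{\linkS4class{Structure}} (coordinates in nm,
#'   \code{sourceUnits = "angstrom"}).
#' @seealso \code{\link{writePDB}}, \code{\link{readGRO}}
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom)) stop(sprintf("no ATOM/HETATM records in %s", path))
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM record at line %d of %s: too short", i, path))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed ATOM record at line %d of %s: bad coordinates",
                   i, path))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  ins <- a$insert
  if (any(!is.na(ins) & nzchar(trimws(ins))))
    stop(sprintf("insertion codes are not supported (%s)", path))
  ## altloc: keep the highest-occupancy conformer, first on tie
  alt <- a$alt
  hasAlt <- !is.na(alt) & nzchar(trimws(alt))
  if (any(hasAlt)) {
    key <- paste(a$chain, a$resno, a$elety, sep = "\r")
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- rep(TRUE, nrow(a))
    for (k in unique(key[hasAlt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    a <- a[keep, , drop = FALSE]
  }
  chain <- ifelse(is.na(a$chain) | !nzchar(trimws(a$chain)), "A",
                  trimws(a$chain))
  elem <- trimws(ifelse(is.na(a$elesy), "", a$elesy))
  noel <- !nzchar(elem)
  if (any(noel)) elem[noel] <- guessElement(a$elety[noel])
  atoms <- data.frame(
    index = 0L, name = trimws(a$elety), element = toupper(elem),
    resname = trimws(a$resid), resseq = as.integer(a$resno), chain = chain,
    x = a$x / ANGSTROM_PER_NM, y = a$y / ANGSTROM_PER_NM,
    z = a$z / ANGSTROM_PER_NM, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0) stop(sprintf("empty structure in %s", path))
  newStructure(atoms, box = numeric(0), sourceUnits = "angstrom")
}

#' Write a Structure as a PDB file
#'
#' Coordinates are converted nm -> Angstrom and written with the standard
#' fixed-column layout (3 decimals, i.e. 1e-4 nm precision).
#'
#' @param x a \code{Structure}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(x, path) {
  a <- x@atoms
  name4 <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  ## 4-character residue names occupy columns 18-21 (GROMACS convention)
  lines <- sprintf(
    "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (a$index + 1L) %% 100000L, name4, substr(a$resname, 1, 4),
    substr(a$chain, 1, 1), a$resseq %% 10000L,
    a$x * ANGSTROM_PER_NM, a$y * ANGSTROM_PER_NM, a$z * ANGSTROM_PER_NM,
    1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## GRO -----------------------------------------------------------------------

#' Read a GROMACS GRO file into a Structure
#'
#' Positions are native nm; velocities, if present, are ignored.  The final
#' line must hold the box vector; triclinic boxes (9 components with nonzero
#' off-diagonals) are rejected as unsupported.
#'
#' @param path path to a .gro file.
#' @return a \code{\linkS4class{Structure}} with \code{sourceUnits = "nm"}.
#' @export
readGRO <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop(sprintf("truncated GRO file: %s", path))
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || nat < 1)
    stop(sprintf("bad atom count at line 2 of %s", path))
  if (length(lines) < nat + 3)
    stop(sprintf("atom-count header says %d atoms but file %s has %d atom lines",
                 nat, path, max(0L, length(lines) - 3L)))
  atomLines <- lines[3:(2 + nat)]
  resseq <- suppressWarnings(as.integer(substr(atomLines, 1, 5)))
  resname <- trimws(substr(atomLines, 6, 10))
  name <- trimws(substr(atomLines, 11, 15))
  rest <- substring(atomLines, 21)
  xyz <- matrix(NA_real_, nat, 3)
  for (i in seq_len(nat)) {
    tok <- strsplit(trimws(rest[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (!(length(v) %in% c(3L, 6L)) || any(is.na(v)))
      stop(sprintf("malformed coordinate line %d in %s", i + 2L, path))
    xyz[i, ] <- v[1:3]
  }
  if (any(is.na(resseq)))
    stop(sprintf("malformed residue field at line %d in %s",
                 which(is.na(resseq))[1] + 2L, path))
  boxTok <- strsplit(trimws(lines[nat + 3L]), "\\s+")[[1]]
  boxv <- suppressWarnings(as.numeric(boxTok))
  if (any(is.na(boxv)) || !(length(boxv) %in% c(3L, 9L)))
    stop(sprintf("malformed box line in %s", path))
  if (length(boxv) == 9L && any(abs(boxv[4:9]) > 0))
    stop(sprintf("triclinic boxes are unsupported (%s)", path))
  atoms <- data.frame(
    index = 0L, name = name, element = guessElement(name),
    resname = resname, resseq = resseq, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  newStructure(atoms, box = boxv[1:3], sourceUnits = "nm")
}

#' Write a Structure as a GRO file
#'
#' Positions are written at 5 decimals (1e-5 nm quantisation) so that
#' PDB -> GRO -> re-read round trips stay within 1e-4 nm.  GRO has no chain
#' field; chain identity is not preserved by this format.
#'
#' @param x a \code{Structure}.
#' @param path output path.
#' @param title title line content.
#' @return invisibly, \code{path}.
#' @export
writeGRO <- function(x, path, title = "memBAR structure") {
  a <- x@atoms
  n <- nrow(a)
  lines <- sprintf("%5d%-5s%5s%5d%10.5f%10.5f%10.5f",
                   a$resseq %% 100000L, substr(a$resname, 1, 5),
                   substr(a$name, 1, 5), (a$index + 1L) %% 100000L,
                   a$x, a$y, a$z)
  box <- if (length(x@box) == 3) x@box else c(0, 0, 0)
  out <- c(title, sprintf("%5d", n), lines,
           sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(out, path)
  invisible(path)
}

## Frame table ---------------------------------------------------------------

#' Read a frame-table CSV into a Trajectory
#'
#' The frame table is the package's plain-text trajectory interchange
#' format: a CSV with columns \code{frame, time_ps, box_x, box_y, box_z}
#' followed by \code{x0, y0, z0, x1, ...} coordinate columns (nm), one row
#' per frame, in the topology's atom order.  Frame times must be strictly
#' increasing and uniformly spaced.  Binary trajectory readers (XTC/DCD)
#' can be substituted by any adapter producing the same
#' \code{\linkS4class{Trajectory}} contract.
#'
#' @param path path to a frame-table CSV.
#' @param topology the \code{Structure} the coordinates refer to.
#' @return a \code{\linkS4class{Trajectory}}.
#' @seealso \code{\link{writeFrameTable}}
#' @export
readFrameTable <- function(path, topology) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tb <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "time_ps", "box_x", "box_y", "box_z")
  if (!all(need %in% names(tb)))
    stop(sprintf("frame table %s must start with columns %s",
                 path, paste(need, collapse = ", ")))
  n <- nAtoms(topology)
  coordCols <- paste0(rep(c("x", "y", "z"), n),
                      rep(topology@atoms$index, each = 3))
  if (!all(coordCols %in% names(tb)))
    stop(sprintf("frame table %s has %d coordinate columns; topology needs %d",
                 path, ncol(tb) - 5L, 3L * n))
  nf <- nrow(tb)
  if (nf == 0) stop(sprintf("frame table %s has no frames", path))
  m <- as.matrix(tb[, coordCols])
  positions <- lapply(seq_len(nf), function(i)
    matrix(m[i, ], ncol = 3, byrow = TRUE))
  boxes <- as.matrix(tb[, c("box_x", "box_y", "box_z")])
  dimnames(boxes) <- NULL
  newTrajectory(topology, tb$time_ps, boxes, positions)
}

#' Write a Trajectory as a frame-table CSV
#'
#' Deterministic writer: numbers are formatted with \code{\%.10g}, so
#' identical trajectories yield byte-identical files.
#'
#' @param traj a \code{Trajectory}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFrameTable <- function(traj, path) {
  n <- nAtoms(traj)
  idx <- traj@topology@atoms$index
  header <- c("frame", "time_ps", "box_x", "box_y", "box_z",
              paste0(rep(c("x", "y", "z"), n), rep(idx, each = 3)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_along(traj@times)) {
    p <- t(traj@positions[[i]])  # x1,y1,z1,x2,... order
    row <- c(sprintf("%d", i - 1L), sprintf("%.10g", traj@times[i]),
             sprintf("%.10g", traj@boxes[i, ]), sprintf("%.10g", as.vector(p)))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}
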