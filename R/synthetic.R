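#' @include AllClasses.R
NULL

## Fixed geometric conventions of the synthetic systems (nm).  The bilayer
## midplane sits at z = 5 with a 4 nm phosphate-to-phosphate thickness;
## z is the membrane normal.
SYN_MIDPLANE <- 5.0
SYN_HALF_THICKNESS <- 2.0
SYN_CHAIN_XOFF <- 0.05   # half-separation of the two protomer rods at the core

#' Default synthetic lipid composition
#'
#' Mole fractions mirroring the mitochondrial-inner-membrane-like liposome
#' recipe POPC:POPE:POPS:PIP2:CDL = 40:32:3:5:18 (the 2 percent fluorescent
#' tracer of the wet-lab recipe is dropped and the remainder renormalised).
#' This main-text ratio is a documented stand-in for the full simulated
#' membrane composition table.
#'
#' @return named numeric mole fractions summing to 1.
#' @export
defaultComposition <- function() {
  r <- c(POPC = 40, POPE = 32, POPS = 3, PIP2 = 5, CDL = 18)
  r / sum(r)
}

#' Construct a synthetic-system specification
#'
#' See \code{\linkS4class{SyntheticSpec}} for slot semantics.  Defaults
#' encode the emulated study conditions: an 18 nm cubic box with the
#' monomer 3.4 nm above the bilayer, or a 45 x 15 x 15 nm box with the
#' dimer 0.2 nm above it; 0.65 nm^2 per lipid; frames every 200 ps; three
#' replicates; composition \code{\link{defaultComposition}}.
#'
#' @param seed integer master seed.
#' @param system "dimer_45x15x15" (default) or "monomer_18nm".
#' @param composition named mole fractions summing to 1.
#' @param areaPerLipid nm^2 (default 0.65).
#' @param heightField list(type, ...): \code{list(type = "flat")},
#'   \code{list(type = "gaussian_bump", A =, sigma =, x0 =)} or
#'   \code{list(type = "sinusoid", A =, lambda =)}.
#' @param noiseSigma thermal marker z-noise SD in nm (default 0.1,
#'   truncated at 3 sigma so scripted distance bounds hold deterministically).
#' @param nFrames number of frames (default 100).
#' @param dtPs frame spacing in ps (default 200).
#' @param proteinOffset nm above the upper leaflet (NA = 3.4 for the
#'   monomer system, 0.2 for the dimer system).
#' @param nReplicates default 3.
#' @param contactSchedule data.frame(resseq, chain, tOn, tOff, class) ps.
#' @param angleRamp numeric(2) concave-angle targets (deg) at the first and
#'   last frame, or numeric(0).
#' @param armAngleDeg inter-arm angle of the built dimer (default 33.2).
#' @param totalLengthNm dimer end-to-end length (default 15).
#' @param residuesPerArm residues per chain, numbered from 2 (default 210).
#' @return a \code{\linkS4class{SyntheticSpec}}.
#' @export
syntheticSpec <- function(seed = 1L, system = "dimer_45x15x15",
                          composition = defaultComposition(),
                          areaPerLipid = 0.65,
                          heightField = list(type = "flat"),
                          noiseSigma = 0.1, nFrames = 100L, dtPs = 200,
                          proteinOffset = NA_real_, nReplicates = 3L,
                          contactSchedule = emptySchedule(),
                          angleRamp = numeric(0), armAngleDeg = 33.2,
                          totalLengthNm = 15, residuesPerArm = 210L) {
  new("SyntheticSpec", seed = as.integer(seed), system = system,
      composition = composition, areaPerLipid = areaPerLipid,
      heightField = heightField, noiseSigma = noiseSigma,
      nFrames = as.integer(nFrames), dtPs = dtPs,
      proteinOffset = as.numeric(proteinOffset),
      nReplicates = as.integer(nReplicates),
      contactSchedule = contactSchedule, angleRamp = as.numeric(angleRamp),
      armAngleDeg = armAngleDeg, totalLengthNm = totalLengthNm,
      residuesPerArm = as.integer(residuesPerArm))
}

#' @rdname syntheticSpec
#' @export
emptySchedule <- function() {
  data.frame(resseq = integer(0), chain = character(0), tOn = numeric(0),
             tOff = numeric(0), class = character(0),
             stringsAsFactors = FALSE)
}

synBox <- function(system) {
  switch(system,
         monomer_18nm = c(18, 18, 18),
         dimer_45x15x15 = c(45, 15, 15),
         stop(sprintf("unknown system: %s", system)))
}

synOffset <- function(spec) {
  if (is.finite(spec@proteinOffset)) return(spec@proteinOffset)
  switch(spec@system, monomer_18nm = 3.4, dimer_45x15x15 = 0.2)
}

## Residue-name pattern for synthetic chains: membrane-binding cluster
## residues carry their true identities so selections read naturally.
synResname <- function(resseq) {
  fixed <- c(`107` = "LYS", `109` = "LYS", `110` = "ARG",
             `132` = "ARG", `134` = "ARG", `136` = "ARG")
  pat <- c("ALA", "LEU", "GLU", "SER", "VAL", "LYS", "ILE", "THR")
  out <- pat[(resseq %% length(pat)) + 1L]
  hit <- as.character(resseq) %in% names(fixed)
  out[hit] <- fixed[as.character(resseq[hit])]
  out
}

## One straight pseudo-atomic rod: residues numbered from 2, atoms CA/N/O.
synRod <- function(chain, nRes, origin, direction, length) {
  t <- seq(0, length, length.out = nRes)
  ca <- cbind(origin[1] + t * direction[1],
              origin[2] + t * direction[2],
              origin[3] + t * direction[3])
  resseq <- seq(2L, by = 1L, length.out = nRes)
  mk <- function(name, dy) {
    data.frame(index = 0L, name = name,
               element = substr(name, 1, 1),
               resname = synResname(resseq), resseq = resseq, chain = chain,
               x = ca[, 1], y = ca[, 2] + dy, z = ca[, 3],
               stringsAsFactors = FALSE)
  }
  rows <- vector("list", nRes)
  caDf <- mk("CA", 0); caDf$element <- "C"
  nDf <- mk("N", 0.06)
  oDf <- mk("O", -0.06)
  ## interleave per residue: CA, N, O
  out <- do.call(rbind, lapply(seq_len(nRes), function(i)
    rbind(caDf[i, ], nDf[i, ], oDf[i, ])))
  rownames(out) <- NULL
  out
}

## Calpha polyline of one protomer: an antiparallel core segment along x
## (the six-helix-bundle stand-in, offset +/- SYN_CHAIN_XOFF in z) followed
## by an arm rising at half the inter-arm angle.  sgn = +1 traces chain A
## (core -x -> +x, arm toward +x), sgn = -1 the two-fold related chain B.
dimerChainCalpha <- function(nRes, coreN, h, beta, sgn) {
  k <- seq_len(nRes) - 1L
  cHalf <- (coreN - 1) * h / 2
  x <- ifelse(k <= coreN - 1L, -cHalf + k * h,
              cHalf + (k - (coreN - 1L)) * h * cos(beta))
  z <- ifelse(k <= coreN - 1L, 0, (k - (coreN - 1L)) * h * sin(beta))
  cbind(sgn * x, 0, z + sgn * SYN_CHAIN_XOFF)
}

#' Build a banana-shaped synthetic dimer
#'
#' Two pseudo-atomic Calpha traces (with backbone N/O dressing atoms),
#' chains A and B related by a two-fold axis: an antiparallel central core
#' along x (the six-helix-bundle stand-in, chains offset by 0.1 nm) with
#' distal arms rising at half the inter-arm angle, residues numbered from 2
#' so the standard selections (alpha2 64-136, clusters 107/109/110 and
#' 132/134/136) resolve.  The inter-arm angle equals the inter-helix angle
#' recovered by \code{\link{interhelixAngle}} on the alpha2 arms, and with
#' \code{armLengthNm = NULL} the residue spacing is derived so the
#' principal-axis extent is exactly \code{totalLengthNm}.  Construction is
#' deterministic.
#'
#' This object is a synthetic stand-in for a crystallographic BAR-domain
#' dimer: it reproduces prescribed angles and extents exactly, but not an
#' atomistic packing interface.
#'
#' @param armLengthNm arm path length in nm (core-end to tip), or NULL to
#'   derive the spacing from \code{totalLengthNm}.
#' @param armAngleDeg inter-arm angle in degrees, in (0, 180) (default 33.2).
#' @param residuesPerArm residues per chain, >= 10 (default 210).
#' @param totalLengthNm end-to-end length in nm (default 15).
#' @return a \code{\linkS4class{Structure}}.
#' @examples
#' d <- buildDimer(armAngleDeg = 33.2)
#' interhelixAngle(helixAxis(d, "A", c(64, 136)), helixAxis(d, "B", c(64, 136)))
#' @export
buildDimer <- function(armLengthNm = NULL, armAngleDeg = 33.2,
                       residuesPerArm = 210L, totalLengthNm = 15) {
  if (armAngleDeg <= 0 || armAngleDeg >= 180)
    stop("arm angle must lie in (0, 180) degrees")
  if (residuesPerArm < 10) stop("residuesPerArm must be >= 10")
  n <- as.integer(residuesPerArm)
  beta <- armAngleDeg / 2 * pi / 180
  ## core covers the same residue fraction as alpha1 (2-61 of 2-211)
  coreN <- max(4L, min(n - 4L, as.integer(round(n * 60 / 210))))
  armInt <- n - coreN
  h <- if (!is.null(armLengthNm)) armLengthNm / armInt else
    totalLengthNm / ((coreN - 1) + 2 * armInt * cos(beta))
  mkChain <- function(chain, sgn) {
    ca <- dimerChainCalpha(n, coreN, h, beta, sgn)
    resseq <- seq(2L, by = 1L, length.out = n)
    base <- data.frame(index = 0L, name = "CA", element = "C",
                       resname = synResname(resseq), resseq = resseq,
                       chain = chain, x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       stringsAsFactors = FALSE)
    nD <- transform(base, name = "N", element = "N", y = y + 0.06)
    oD <- transform(base, name = "O", element = "O", y = y - 0.06)
    out <- do.call(rbind, lapply(seq_len(n), function(i)
      rbind(base[i, ], nD[i, ], oD[i, ])))
    rownames(out) <- NULL
    out
  }
  a <- rbind(mkChain("A", 1), mkChain("B", -1))
  newStructure(a, box = numeric(0), sourceUnits = "nm")
}

## Largest-remainder apportionment of n lipids over mole fractions.
largestRemainderCounts <- function(fractions, n) {
  tgt <- fractions * n
  fl <- floor(tgt)
  rem <- tgt - fl
  short <- n - sum(fl)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(fl), names(fractions))
}

fieldZ <- function(field, x, y) {
  switch(field$type,
         flat = rep(0, length(x)),
         gaussian_bump = field$A * exp(-(x - field$x0)^2 / (2 * field$sigma^2)),
         sinusoid = field$A * sin(2 * pi * x / field$lambda),
         stop(sprintf("unknown height field type: %s", field$type)))
}

## Truncated (clamped at 3 sigma) Gaussian noise: keeps scripted distance
## bounds deterministic while staying near-Gaussian for SE-based checks.
clampedNoise <- function(n, sigma) {
  if (sigma <= 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sigma), -3 * sigma), 3 * sigma)
}

#' Build a synthetic point-lipid bilayer
#'
#' Places one marker (P) atom plus two dressing carbon atoms per lipid on a
#' lateral grid in the spec's box, with per-class counts from
#' largest-remainder apportionment of the mole fractions.  Cardiolipin
#' lipids carry two P atoms (marker = midpoint).  Leaflet z is
#' \code{midplane +/- half-thickness + heightField(x, y) + noise}.  Lipids
#' are 3-point pseudo-molecules: the analyses only need marker atoms and
#' heavy-atom distances, not atomistic lipid geometry.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param noise logical: add the spec's marker z-noise to the built
#'   snapshot (default TRUE; \code{scriptTrajectory} builds its own
#'   noise-free home configuration and adds per-frame noise instead).
#' @return list with \code{structure} (a \code{Structure}, box set),
#'   and \code{groundTruth}: data.frame per lipid (class, leaflet, home
#'   x/y/z of the marker) plus the field parameters as attributes.
#' @export
buildBilayer <- function(spec, noise = TRUE) {
  box <- synBox(spec@system)
  nLeaflet <- floor(box[1] * box[2] / spec@areaPerLipid)
  if (nLeaflet < 50)
    stop("box area / areaPerLipid must give at least 50 lipids per leaflet")
  counts <- largestRemainderCounts(spec@composition, nLeaflet)
  set.seed(spec@seed)
  nx <- max(1L, round(box[1] / sqrt(spec@areaPerLipid)))
  ny <- ceiling(nLeaflet / nx)
  sx <- box[1] / nx; sy <- box[2] / ny
  sites <- cbind(((seq_len(nLeaflet) - 1L) %% nx + 0.5) * sx,
                 ((seq_len(nLeaflet) - 1L) %/% nx + 0.5) * sy)
  classVec <- sample(rep(names(counts), counts))
  lip <- list(); gt <- list()
  resseq <- 0L
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    z0 <- SYN_MIDPLANE + sgn * SYN_HALF_THICKNESS +
      fieldZ(spec@heightField, sites[, 1], sites[, 2])
    zn <- z0 + if (noise) clampedNoise(nLeaflet, spec@noiseSigma) else 0
    for (i in seq_len(nLeaflet)) {
      resseq <- resseq + 1L
      cls <- classVec[i]
      x <- sites[i, 1]; y <- sites[i, 2]; z <- zn[i]
      if (cls == "CDL") {
        at <- data.frame(
          index = 0L, name = c("P1", "P2", "C1"), element = c("P", "P", "C"),
          resname = "CDL", resseq = resseq, chain = "L",
          x = c(x - 0.05, x + 0.05, x),
          y = c(y, y, y), z = c(z, z, z - sgn * 0.05),
          stringsAsFactors = FALSE)
      } else {
        at <- data.frame(
          index = 0L, name = c("P", "C1", "C2"), element = c("P", "C", "C"),
          resname = cls, resseq = resseq, chain = "L",
          x = c(x, x + 0.04, x - 0.04), y = y,
          z = c(z, z - sgn * 0.05, z - sgn * 0.05),
          stringsAsFactors = FALSE)
      }
      lip[[length(lip) + 1L]] <- at
      gt[[length(gt) + 1L]] <- data.frame(
        lipid = resseq, class = cls, leaflet = leaf, x = x, y = y,
        zHome = z0[i], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, lip)
  rownames(atoms) <- NULL
  truth <- do.call(rbind, gt)
  attr(truth, "heightField") <- spec@heightField
  attr(truth, "midplane") <- SYN_MIDPLANE
  attr(truth, "halfThickness") <- SYN_HALF_THICKNESS
  list(structure = newStructure(atoms, box = box, sourceUnits = "nm"),
       groundTruth = truth)
}

rotY <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, sin(r), 0, 1, 0, -sin(r), 0, cos(r)), 3, 3)
}

#' Script a synthetic trajectory with known ground truth
#'
#' Generates one \code{Trajectory} per replicate of the spec's system:
#' a point-lipid bilayer plus (optionally) the synthetic protein, with
#' per-frame truncated-Gaussian marker z-noise (and protein positional
#' noise), an exactly realised residue-lipid contact schedule, and an
#' exactly realised concave-angle ramp.
#'
#' Scheduled contacts are realised by protruding the scheduled residue to
#' 0.3 nm above the designated lipid's marker during its window; scheduled
#' residues and designated lipids are exempt from noise so the scripted
#' distances hold exactly (within 0.35 nm in the window, at least 0.6 nm
#' outside it).  A non-empty schedule therefore requires a protein offset
#' of at least \code{0.6 + 3 * noiseSigma + 0.2} nm.  The angle ramp is
#' realised by rigid in-plane rotation of the arms (residues 11+) about the
#' core hinge, which changes the measured concave angle exactly.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param includeProtein logical; FALSE builds a protein-free bilayer
#'   (for leaflet profiles without the bound dimer).
#' @return list with \code{topology} (Structure, box set),
#'   \code{trajectories} (list of \code{Trajectory}, one per replicate) and
#'   \code{groundTruth} (lipid table as in \code{\link{buildBilayer}}, plus
#'   \code{anglePerFrame}, realised \code{schedule} with frame indices,
#'   \code{times}, and the per-replicate derived seeds).
#' @export
scriptTrajectory <- function(spec, includeProtein = TRUE) {
  box <- synBox(spec@system)
  nf <- spec@nFrames
  times <- (seq_len(nf) - 1) * spec@dtPs
  bl <- buildBilayer(spec, noise = FALSE)
  lipAtoms <- bl$structure@atoms
  truth <- bl$groundTruth
  sched <- spec@contactSchedule
  if (nrow(sched) > 0 && !includeProtein)
    stop("a contact schedule requires the protein")
  if (length(spec@angleRamp) && spec@system != "dimer_45x15x15")
    stop("an angle ramp requires the dimer system")

  protAtoms <- NULL
  hinge <- NULL
  builtAngle <- NULL
  if (includeProtein) {
    offset <- synOffset(spec)
    if (nrow(sched) > 0) {
      minOff <- 0.6 + 3 * spec@noiseSigma + 0.2
      if (offset < minOff)
        stop(sprintf(
          "contact schedule needs proteinOffset >= %.2f nm (have %.2f)",
          minOff, offset))
    }
    if (spec@system == "dimer_45x15x15") {
      prot <- buildDimer(armAngleDeg = spec@armAngleDeg,
                         residuesPerArm = spec@residuesPerArm,
                         totalLengthNm = spec@totalLengthNm)
    } else {
      a <- synRod("A", spec@residuesPerArm, c(0, 0, 0), c(1, 0, 0),
                  spec@totalLengthNm / 2)
      prot <- newStructure(a, sourceUnits = "nm")
    }
    pa <- prot@atoms
    surface <- SYN_MIDPLANE + SYN_HALF_THICKNESS
    shift <- c(box[1] / 2 - mean(range(pa$x)),
               box[2] / 2 - mean(range(pa$y)),
               surface + offset - min(pa$z))
    pa$x <- pa$x + shift[1]; pa$y <- pa$y + shift[2]; pa$z <- pa$z + shift[3]
    protAtoms <- pa
    if (length(spec@angleRamp)) {
      grp <- defaultAngleGroups()
      tmp <- newStructure(pa, box = box, sourceUnits = "nm")
      pos <- unname(as.matrix(pa[, c("x", "y", "z")]))
      hinge <- groupCentroid(pos, tmp, grp$center)
      tipA0 <- groupCentroid(pos, tmp, grp$armTipA)
      tipB0 <- groupCentroid(pos, tmp, grp$armTipB)
      builtAngle <- angleAt(hinge, tipA0, tipB0)
      ## orientation of the symmetric arm rotation that OPENS the angle:
      ## probe both senses on the tip centroids (closed form, exact)
      probe <- function(s, delta) {
        u <- as.numeric(rotY(s * delta / 2) %*% (tipA0 - hinge))
        v <- as.numeric(rotY(-s * delta / 2) %*% (tipB0 - hinge))
        angleAt(c(0, 0, 0), u, v)
      }
      rampSign <- if (probe(1, 1) > builtAngle) 1 else -1
    }
  }

  atoms <- rbind(protAtoms, lipAtoms)
  rownames(atoms) <- NULL
  topo <- newStructure(atoms, box = box, sourceUnits = "nm")
  nProt <- if (is.null(protAtoms)) 0L else nrow(protAtoms)
  a <- topo@atoms

  ## resolve the schedule: designated lipid + frame windows + residue rows
  schedInfo <- NULL
  if (nrow(sched) > 0) {
    used <- integer(0)
    schedInfo <- vector("list", nrow(sched))
    Ttot <- nf * spec@dtPs
    for (s in seq_len(nrow(sched))) {
      e <- sched[s, ]
      if (e$tOn < 0 || e$tOff > Ttot || e$tOn >= e$tOff)
        stop(sprintf("schedule entry %d is outside the run [0, %g] ps",
                     s, Ttot))
      resRows <- which(a$chain == e$chain & a$resseq == e$resseq &
                         seq_len(nrow(a)) <= nProt)
      if (length(resRows) == 0)
        stop(sprintf("scheduled residue %d:%s not in topology",
                     e$resseq, e$chain))
      caRow <- resRows[a$name[resRows] == "CA"][1]
      cand <- which(truth$class == e$class & truth$leaflet == "upper" &
                      !(truth$lipid %in% used))
      if (length(cand) == 0)
        stop(sprintf("no free upper-leaflet lipid of class %s", e$class))
      d2 <- (truth$x[cand] - a$x[caRow])^2 + (truth$y[cand] - a$y[caRow])^2
      pick <- cand[which.min(d2)]
      used <- c(used, truth$lipid[pick])
      lipRows <- which(a$chain == "L" & a$resseq == truth$lipid[pick])
      frames <- which(times >= e$tOn & times < e$tOff)
      schedInfo[[s]] <- list(resRows = resRows, caRow = caRow,
                             lipRows = lipRows, lipid = truth$lipid[pick],
                             frames = frames,
                             target = c(truth$x[pick], truth$y[pick],
                                        truth$zHome[pick]))
    }
  }
  schedResRows <- unlist(lapply(schedInfo, `[[`, "resRows"))
  schedLipRows <- unlist(lapply(schedInfo, `[[`, "lipRows"))

  ## marker rows (P atoms) per lipid for z-noise application
  lipPRows <- which(a$chain == "L" & a$element == "P")

  anglePerFrame <- NULL
  if (length(spec@angleRamp))
    anglePerFrame <- seq(spec@angleRamp[1], spec@angleRamp[2],
                         length.out = nf)

  basePos <- unname(as.matrix(a[, c("x", "y", "z")]))
  subSeeds <- spec@seed + 7919L * seq_len(spec@nReplicates)
  trajs <- vector("list", spec@nReplicates)
  for (r in seq_len(spec@nReplicates)) {
    set.seed(subSeeds[r])
    positions <- vector("list", nf)
    for (f in seq_len(nf)) {
      pos <- basePos
      ## angle ramp: rigid arm rotation about the core hinge (y-axis)
      if (!is.null(anglePerFrame)) {
        delta <- anglePerFrame[f] - builtAngle
        armA <- which(a$chain == "A" & a$resseq >= 11 &
                        seq_len(nrow(a)) <= nProt)
        armB <- which(a$chain == "B" & a$resseq >= 11 &
                        seq_len(nrow(a)) <= nProt)
        ## both tips lie in the xz-plane through the hinge, so symmetric
        ## in-plane arm rotations change the subtended angle by exactly
        ## delta (sense established on the built geometry above)
        RA <- rotY(rampSign * delta / 2); RB <- rotY(-rampSign * delta / 2)
        pos[armA, ] <- sweep(sweep(pos[armA, , drop = FALSE], 2, hinge) %*%
                               t(RA), 2, hinge, `+`)
        pos[armB, ] <- sweep(sweep(pos[armB, , drop = FALSE], 2, hinge) %*%
                               t(RB), 2, hinge, `+`)
      }
      ## noise: lipid marker z + protein xyz (scripted rows exempt)
      zn <- clampedNoise(length(lipPRows), spec@noiseSigma)
      noisyLip <- setdiff(lipPRows, schedLipRows)
      pos[noisyLip, 3] <- pos[noisyLip, 3] +
        zn[match(noisyLip, lipPRows)]
      if (nProt > 0 && spec@noiseSigma > 0) {
        protRows <- setdiff(seq_len(nProt), schedResRows)
        pn <- matrix(clampedNoise(3 * length(protRows), spec@noiseSigma),
                     ncol = 3)
        pos[protRows, ] <- pos[protRows, ] + pn
      }
      ## scripted contacts: protrude the residue to 0.3 nm above the lipid
      if (!is.null(schedInfo)) {
        for (s in schedInfo) {
          if (f %in% s$frames) {
            delta <- s$target + c(0, 0, 0.3) - basePos[s$caRow, ]
            pos[s$resRows, ] <- sweep(basePos[s$resRows, , drop = FALSE],
                                      2, delta, `+`)
          }
        }
      }
      positions[[f]] <- pos
    }
    trajs[[r]] <- newTrajectory(topo, times,
                                matrix(rep(box, each = nf), nf, 3), positions)
  }
  gt <- list(lipids = truth, anglePerFrame = anglePerFrame,
             builtAngle = builtAngle, times = times, subSeeds = subSeeds,
             nProteinAtoms = nProt,
             schedule = if (is.null(schedInfo)) NULL else
               lapply(schedInfo, function(s)
                 s[c("lipid", "frames")]))
  list(topology = topo, trajectories = trajs, groundTruth = gt)
}
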