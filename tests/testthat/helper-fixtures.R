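# Shared fixtures and independent oracles, built in code.

# Minimal atom table row
atomRow <- function(name = "C", element = "C", resname = "ALA", resseq = 1L,
                    chain = "A", x = 0, y = 0, z = 0) {
  data.frame(index = 0L, name = name, element = element, resname = resname,
             resseq = as.integer(resseq), chain = chain, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

structureFrom <- function(...) {
  memBAR:::newStructure(do.call(rbind, list(...)))
}

# Straight poly-Calpha rod along `direction`, residues 1..n
rodStructure <- function(n = 20, direction = c(1, 0, 0), spacing = 0.15,
                         chain = "A", origin = c(0, 0, 0)) {
  rows <- lapply(seq_len(n), function(i) {
    p <- origin + (i - 1) * spacing * direction
    atomRow("CA", "C", "ALA", i, chain, p[1], p[2], p[3])
  })
  memBAR:::newStructure(do.call(rbind, rows))
}

# Deterministic random rotation matrix (QR of a seeded Gaussian matrix)
randomRotation <- function(seed) {
  set.seed(seed)
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidTransform <- function(structure, R, t = c(0, 0, 0)) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  memBAR:::newStructure(a, box = structure@box,
                        sourceUnits = structure@sourceUnits)
}

# Analytic SASA of two equal spheres of expanded radius R at distance d:
# each sphere loses the cap beyond the bisecting plane.
twoSphereSasaAnalytic <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  a1 <- 2 * pi * R1 * (R1 + max(-R1, min(R1, x1)))
  a2 <- 2 * pi * R2 * (R2 + max(-R2, min(R2, x2)))
  a1 + a2
}

# Independent occupancy oracle: exhaustive run-length scan over a logical
# contact vector, k*dt duration convention.
occupancyOracle <- function(contactVec, dt, tFirstGlobal) {
  n <- length(contactVec)
  best <- 0L; run <- 0L
  for (f in seq_len(n)) {
    run <- if (contactVec[f]) run + 1L else 0L
    best <- max(best, run)
  }
  denom <- n * dt - tFirstGlobal
  if (denom <= 0) return(0)
  min(1, max(0, best * dt / denom))
}

# Tiny trajectory around a fixed topology from a list of position matrices
trajectoryFrom <- function(topology, positionsList, dtPs = 200,
                           box = c(10, 10, 10)) {
  nf <- length(positionsList)
  memBAR:::newTrajectory(topology, (seq_len(nf) - 1) * dtPs,
                         matrix(rep(box, each = nf), nf, 3), positionsList)
}

# Small bilayer spec used across membrane tests (full dimer box, modest
# frame count so the suite stays fast)
smallBilayerSpec <- function(seed = 1L, ...) {
  syntheticSpec(seed = seed, system = "dimer_45x15x15", nFrames = 10L,
                nReplicates = 2L, noiseSigma = 0, ...)
}
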