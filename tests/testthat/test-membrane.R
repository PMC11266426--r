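test_that("leaflet assignment splits a planar bilayer and mirrors correctly", {
  set.seed(8)
  up <- cbind(runif(40, 0, 10), runif(40, 0, 10), 7)
  lo <- cbind(runif(40, 0, 10), runif(40, 0, 10), 3)
  mk <- rbind(up, lo)
  lf <- assignLeaflets(mk)
  expect_setequal(lf$upper, 1:40)
  expect_setequal(lf$lower, 41:80)
  ## mirroring about the midplane swaps the labels exactly
  mirrored <- mk
  mirrored[, 3] <- 10 - mirrored[, 3]
  lf2 <- assignLeaflets(mirrored)
  expect_setequal(lf2$upper, lf$lower)
  expect_setequal(lf2$lower, lf$upper)
  expect_error(assignLeaflets(cbind(1:5, 1:5, 2)), "coplanar")
})

test_that("local-midplane assignment beats the global midplane on a bent bilayer", {
  ## strongly tilted bilayer: global midplane misassigns the ends
  xs <- seq(0.5, 19.5, by = 1)
  tilt <- 0.8 * xs
  z <- c(7 + tilt, 3 + tilt)
  mk <- cbind(rep(xs, 2), 0.5, z)
  truthUpper <- 1:20
  lfG <- assignLeaflets(mk, method = "global")
  lfL <- assignLeaflets(mk, method = "local", localRadius = 2)
  misG <- length(setdiff(lfG$upper, truthUpper)) +
    length(setdiff(truthUpper, lfG$upper))
  misL <- length(setdiff(lfL$upper, truthUpper)) +
    length(setdiff(truthUpper, lfL$upper))
  expect_gt(misG, 0)     # the global method fails here by construction
  expect_equal(misL, 0)  # the local method recovers the truth
})

test_that("flat noiseless bilayers give constant profiles with zero replicate SD", {
  spec <- smallBilayerSpec(seed = 31)
  res <- scriptTrajectory(spec, includeProtein = FALSE)
  profs <- lapply(res$trajectories, heightProfile, leaflet = "upper")
  for (p in profs) {
    expect_false(any(p@missing))
    expect_equal(unname(p@meanZ), rep(7, length(p@meanZ)))
  }
  agg <- aggregateProfiles(profs)
  expect_equal(max(abs(agg@sd)), 0)
  low <- heightProfile(res$trajectories[[1]], "lower")
  expect_equal(unname(low@meanZ), rep(3, length(low@meanZ)))
})

test_that("profiles depend only on the selected leaflet and flag empty bins", {
  ## three clustered lipids -> most bins empty, flagged missing
  a <- do.call(rbind, lapply(1:3, function(i)
    rbind(atomRow("P", "P", "POPC", i, "L", 1 + 0.1 * i, 1, 7),
          atomRow("P", "P", "POPE", i + 10L, "L", 1 + 0.1 * i, 2, 3))))
  topo <- memBAR:::newStructure(a, box = c(10, 10, 10))
  p <- coords(topo)
  tr <- trajectoryFrom(topo, list(p, p), dtPs = 200)
  hp <- heightProfile(tr, "upper")
  expect_equal(sum(!hp@missing), 1)
  expect_equal(hp@meanZ[!hp@missing], 7)
  expect_true(all(is.na(hp@meanZ[hp@missing])))
  expect_error(heightProfile(tr, "upper", binNm = 0), "bin width")
  expect_error(heightProfile(tr, "upper", sampleEveryPs = 300), "multiple")
})

test_that("gaussian bump height field is recovered within the noise CI", {
  spec <- syntheticSpec(seed = 11, system = "dimer_45x15x15", nFrames = 60L,
                        heightField = list(type = "gaussian_bump", A = 1,
                                           sigma = 3, x0 = 22.5),
                        noiseSigma = 0.1, nReplicates = 1L)
  res <- scriptTrajectory(spec, includeProtein = FALSE)
  hp <- heightProfile(res$trajectories[[1]], "upper")
  gt <- res$groundTruth$lipids
  up <- gt[gt$leaflet == "upper", ]
  ib <- findInterval(up$x, seq(0, 45, by = 1), rightmost.closed = TRUE)
  expd <- tapply(up$zHome, ib, mean)
  N <- tapply(up$zHome, ib, length) * 60
  dev <- abs(hp@meanZ - as.numeric(expd))
  ci <- 1.96 * 0.1 / sqrt(N)
  expect_gte(mean(dev <= ci), 0.9)
  ## amplitude recovered
  expect_equal(max(hp@meanZ) - min(hp@meanZ), 1, tolerance = 0.1)
})

test_that("per-bin SD of replicate means scales as sigma over sqrt(n)", {
  sigma <- 0.1
  profs <- lapply(1:8, function(r) {
    spec <- syntheticSpec(seed = 100 + r, system = "dimer_45x15x15",
                          nFrames = 25L, noiseSigma = sigma, nReplicates = 1L)
    res <- scriptTrajectory(spec, includeProtein = FALSE)
    heightProfile(res$trajectories[[1]], "upper")
  })
  m <- sapply(profs, function(p) p@meanZ)
  sdObs <- apply(m, 1, sd)
  nPerBin <- profs[[1]]@n          # markers x sampled frames per bin
  sdExp <- sigma / sqrt(nPerBin)
  ## pooled over bins; noise is clamped at 3 sigma so expectation is an
  ## upper bound, and 8 replicates estimate SD to ~25 percent
  expect_equal(mean(sdObs) / mean(sdExp), 1, tolerance = 0.35)
})

test_that("density maps conserve lipid counts and respect alignment invariance", {
  spec <- smallBilayerSpec(seed = 41)
  res <- scriptTrajectory(spec, includeProtein = FALSE)
  tr <- res$trajectories[[1]]
  for (cl in c("POPC", "CDL")) {
    dm <- densityMap2D(tr, cl, windowPs = 2000, alignment = "none",
                       binNm = 0.5)
    integral <- sum(dm@grid * outer(diff(dm@xedges), diff(dm@yedges)))
    expect_equal(integral, dm@meanCount, tolerance = 0.01)
    nLip <- sum(res$groundTruth$lipids$class == cl)
    expect_equal(dm@meanCount, nLip)
  }
  expect_error(densityMap2D(tr, "POPC", windowPs = 0), "window")

  ## one static lipid, no alignment: all mass in a single bin
  a <- rbind(atomRow("P", "P", "POPC", 1L, "L", 2.3, 3.1, 7),
             atomRow("P", "P", "POPE", 2L, "L", 8, 8, 3))
  topo <- memBAR:::newStructure(a, box = c(10, 10, 10))
  p <- coords(topo)
  tr1 <- trajectoryFrom(topo, list(p, p), dtPs = 200)
  dm1 <- densityMap2D(tr1, "POPC", windowPs = 400, alignment = "none")
  integral <- sum(dm1@grid * outer(diff(dm1@xedges), diff(dm1@yedges)))
  expect_equal(integral, 1)
  expect_equal(sum(dm1@grid > 0), 1)
})

test_that("protein-aligned maps are invariant to a global in-plane rotation", {
  spec <- syntheticSpec(seed = 51, system = "monomer_18nm", nFrames = 4L,
                        nReplicates = 1L, noiseSigma = 0)
  res <- scriptTrajectory(spec)
  tr <- res$trajectories[[1]]
  dm0 <- densityMap2D(tr, "POPC", windowPs = 800,
                      alignment = "protein_aligned", binNm = 1)
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- c(9, 9, 0)
  rot <- lapply(tr@positions, function(p)
    sweep(sweep(p, 2, ctr) %*% Rz, 2, ctr, `+`))
  tr2 <- trajectoryFrom(res$topology, rot, dtPs = 200, box = c(18, 18, 18))
  dm1 <- densityMap2D(tr2, "POPC", windowPs = 800,
                      alignment = "protein_aligned", binNm = 1)
  ## identical up to binning tolerance: compare total mass and the
  ## occupied-cell overlap
  expect_equal(sum(dm1@grid), sum(dm0@grid), tolerance = 0.02)
  expect_gt(sum(dm0@grid > 0 & dm1@grid > 0) / sum(dm0@grid > 0), 0.8)
})

test_that("curvature estimates match analytic profiles and sign conventions", {
  mkProfile <- function(z, h = 1) new("HeightProfile",
    binCenters = seq_along(z) * h - h / 2, meanZ = z,
    sd = rep(NA_real_, length(z)), n = rep(10L, length(z)),
    missing = rep(FALSE, length(z)), leaflet = "upper", binWidth = h)
  ## linear profile: zero curvature
  lin <- curvatureEstimate(mkProfile(2 + 0.3 * (1:12)))
  expect_equal(max(abs(lin$curvature_per_nm), na.rm = TRUE), 0)
  ## circle arc of radius 10 nm: kappa = 1/R within discretisation error
  R <- 10
  x <- seq(-6, 6, by = 1)
  arc <- curvatureEstimate(mkProfile(sqrt(R^2 - x^2)))
  inner <- arc$curvature_per_nm[!is.na(arc$curvature_per_nm)]
  expect_equal(inner, rep(1 / R, length(inner)), tolerance = 0.01)
  ## mirroring in z flips the sign
  arcDown <- curvatureEstimate(mkProfile(-sqrt(R^2 - x^2)))
  expect_equal(arcDown$curvature_per_nm, -arc$curvature_per_nm)
  expect_error(curvatureEstimate(mkProfile(c(1, 2, 3))), "5 consecutive")
})
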