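test_that("group centroids are unweighted Calpha means", {
  a <- rbind(atomRow("CA", "C", "ALA", 1L, "A", 0, 0, 0),
             atomRow("CA", "C", "ALA", 2L, "A", 2, 0, 0),
             atomRow("N", "N", "ALA", 2L, "A", 9, 9, 9))   # ignored: not CA
  s <- memBAR:::newStructure(a)
  p <- coords(s)
  expect_equal(groupCentroid(p, s, list(chain = "A", resseq = 1L)), c(0, 0, 0))
  expect_equal(groupCentroid(p, s, list(chain = "A", resseq = 1:2)), c(1, 0, 0))
  set.seed(13)
  rows <- lapply(1:12, function(i)
    atomRow("CA", "C", "ALA", i, "A", rnorm(1), rnorm(1), rnorm(1)))
  s2 <- memBAR:::newStructure(do.call(rbind, rows))
  expect_equal(groupCentroid(coords(s2), s2, list(chain = "A", resseq = 1:12)),
               colMeans(coords(s2)), tolerance = 1e-12)
  expect_error(groupCentroid(p, s, list(chain = "Z", resseq = 1L)),
               "no Calpha")
})

test_that("angle series reproduces constructed geometries", {
  mkTopo <- function(pA, pC, pB) {
    a <- rbind(atomRow("CA", "C", "ALA", 1L, "A", pA[1], pA[2], pA[3]),
               atomRow("CA", "C", "ALA", 5L, "C", pC[1], pC[2], pC[3]),
               atomRow("CA", "C", "ALA", 9L, "B", pB[1], pB[2], pB[3]))
    memBAR:::newStructure(a)
  }
  grp <- list(tipA = list(chain = "A", resseq = 1L),
              center = list(chain = "C", resseq = 5L),
              tipB = list(chain = "B", resseq = 9L))
  ## collinear with the center between the tips: 180 degrees
  t1 <- mkTopo(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  tr1 <- trajectoryFrom(t1, list(coords(t1), coords(t1)))
  expect_equal(as.vector(angleSeries(tr1, grp)@angles), c(180, 180))
  ## equilateral triangle: 60 degrees
  t2 <- mkTopo(c(1, 0, 0), c(0, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tr2 <- trajectoryFrom(t2, list(coords(t2), coords(t2)))
  expect_equal(as.vector(angleSeries(tr2, grp)@angles), c(60, 60))
  ## coincident centroids abort naming the frame
  t3 <- mkTopo(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  tr3 <- trajectoryFrom(t3, list(coords(t3), coords(t3)))
  expect_error(angleSeries(tr3, grp), "frame 1")
})

test_that("the concave angle is rigid-motion invariant per frame", {
  spec <- syntheticSpec(seed = 61, system = "dimer_45x15x15", nFrames = 4L,
                        nReplicates = 1L, angleRamp = c(130, 110),
                        noiseSigma = 0)
  res <- scriptTrajectory(spec)
  tr <- res$trajectories[[1]]
  R <- randomRotation(17)
  rot <- lapply(tr@positions, function(p)
    sweep(p %*% t(R), 2, c(2, -1, 4), `+`))
  tr2 <- trajectoryFrom(res$topology, rot, dtPs = 200, box = c(45, 15, 15))
  a1 <- angleSeries(tr)@angles
  a2 <- angleSeries(tr2)@angles
  expect_lt(max(abs(a1 - a2)), 1e-6)
})

test_that("scripted ramps are exact without noise and recovered with noise", {
  specExact <- syntheticSpec(seed = 62, system = "dimer_45x15x15",
                             nFrames = 6L, nReplicates = 1L,
                             angleRamp = c(120, 100), noiseSigma = 0)
  as0 <- angleSeries(scriptTrajectory(specExact)$trajectories[[1]])
  expect_equal(as.vector(as0@angles), seq(120, 100, length.out = 6),
               tolerance = 1e-9)
  ## bit-stable across regeneration
  as1 <- angleSeries(scriptTrajectory(specExact)$trajectories[[1]])
  expect_identical(as0@angles, as1@angles)

  specNoisy <- syntheticSpec(seed = 63, system = "dimer_45x15x15",
                             nFrames = 10L, nReplicates = 3L,
                             angleRamp = c(120, 100), noiseSigma = 0.05)
  res <- scriptTrajectory(specNoisy)
  agg <- aggregateAngles(lapply(res$trajectories, angleSeries))
  expect_lt(abs(agg@mean[1] - 120), 2)
  expect_lt(abs(agg@mean[10] - 100), 2)
  expect_equal(dim(agg@angles), c(10L, 3L))
  expect_true(all(agg@sd >= 0))
  tb <- asTable(agg)
  expect_true(all(c("time_ps", "mean_deg", "sd_deg") %in% names(tb)))
})

test_that("smoothing uses a centered moving average and validates the window", {
  spec <- syntheticSpec(seed = 64, system = "dimer_45x15x15", nFrames = 6L,
                        nReplicates = 1L, angleRamp = c(120, 100),
                        noiseSigma = 0)
  tr <- scriptTrajectory(spec)$trajectories[[1]]
  sm <- angleSeries(tr, smoothWindow = 3L)
  raw <- seq(120, 100, length.out = 6)
  expect_equal(as.vector(sm@angles)[2:5],
               (raw[1:4] + raw[2:5] + raw[3:6]) / 3, tolerance = 1e-9)
  expect_error(angleSeries(tr, smoothWindow = 4L), "odd")
})
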