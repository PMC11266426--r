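test_that("built dimers round-trip the requested angle and length", {
  for (ang in c(20, 33.2, 54)) {
    d <- buildDimer(armAngleDeg = ang)
    got <- interhelixAngle(helixAxis(d, "A", c(64, 136)),
                           helixAxis(d, "B", c(64, 136)))
    expect_lt(abs(got - ang), 0.5)
  }
  d <- buildDimer(totalLengthNm = 15)
  expect_lt(abs(dimerExtent(d)$length - 150), 2)
  expect_error(buildDimer(armAngleDeg = 0), "0, 180")
  expect_error(buildDimer(residuesPerArm = 5L), ">= 10")
  ## deterministic construction -> byte-identical GRO output
  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeGRO(buildDimer(), f1)
  writeGRO(buildDimer(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("largest-remainder apportionment matches an independent oracle", {
  oracle <- function(fr, n) {
    # enumeration oracle: start at floors, hand out remaining seats one by
    # one to the currently most-underserved class
    cnt <- floor(fr * n)
    while (sum(cnt) < n) {
      deficit <- fr * n - cnt
      i <- which.max(deficit)
      cnt[i] <- cnt[i] + 1
    }
    as.integer(cnt)
  }
  expect_equal(unname(memBAR:::largestRemainderCounts(
    c(A = 0.4, B = 0.3, C = 0.3), 10)), c(4L, 3L, 3L))
  comp <- defaultComposition()
  got <- memBAR:::largestRemainderCounts(comp, 1000)
  expect_equal(unname(got), oracle(comp, 1000))
  expect_equal(sum(got), 1000)
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    fr <- runif(k); fr <- fr / sum(fr)
    names(fr) <- letters[seq_len(k)]
    n <- sample(50:2000, 1)
    got <- memBAR:::largestRemainderCounts(fr, n)
    expect_equal(sum(got), n)
    expect_true(all(abs(got - fr * n) < 1))
  }
})

test_that("bilayer composition, leaflets and markers honour the spec", {
  spec <- smallBilayerSpec(seed = 71)
  bl <- buildBilayer(spec, noise = FALSE)
  gt <- bl$groundTruth
  nLeaflet <- floor(45 * 15 / 0.65)
  expect_equal(nrow(gt), 2 * nLeaflet)
  perClass <- table(gt$class) / 2
  want <- memBAR:::largestRemainderCounts(defaultComposition(), nLeaflet)
  expect_equal(as.integer(perClass[names(want)]), unname(want))
  ## flat field, zero noise: upper markers at one z
  cls <- classifyLipids(bl$structure)
  mk <- markerPositions(cls, coords(bl$structure))
  up <- gt$leaflet == "upper"
  expect_equal(unname(mk[up, 3]), rep(7, sum(up)))
  expect_equal(unname(mk[!up, 3]), rep(3, sum(!up)))
  expect_error(buildBilayer(syntheticSpec(
    seed = 1, composition = c(POPC = 0.5, POPE = 0.4))), "sum to 1")
})

test_that("generators are deterministic and files re-read to generator precision", {
  spec <- syntheticSpec(seed = 81, system = "monomer_18nm", nFrames = 4L,
                        nReplicates = 2L, noiseSigma = 0.1)
  r1 <- scriptTrajectory(spec)
  r2 <- scriptTrajectory(spec)
  expect_identical(r1$trajectories[[1]]@positions, r2$trajectories[[1]]@positions)
  expect_identical(r1$trajectories[[2]]@positions, r2$trajectories[[2]]@positions)
  ## replicates differ (independent noise streams)
  expect_false(identical(r1$trajectories[[1]]@positions[[1]],
                         r1$trajectories[[2]]@positions[[1]]))
  ## round-trip through the interchange formats
  fg <- withr::local_tempfile(fileext = ".gro")
  writeGRO(r1$topology, fg)
  expect_lt(max(abs(coords(readGRO(fg)) - coords(r1$topology))), 1e-4)
  ff <- withr::local_tempfile(fileext = ".csv")
  writeFrameTable(r1$trajectories[[1]], ff)
  tr <- readFrameTable(ff, r1$topology)
  expect_lt(max(abs(tr@positions[[3]] - r1$trajectories[[1]]@positions[[3]])),
            1e-4)
})

test_that("schedules outside the run or without clearance are rejected", {
  schedLate <- data.frame(resseq = 107L, chain = "A", tOn = 0, tOff = 1e6,
                          class = "PIP2", stringsAsFactors = FALSE)
  spec <- syntheticSpec(seed = 1, system = "monomer_18nm", nFrames = 5L,
                        nReplicates = 1L, contactSchedule = schedLate)
  expect_error(scriptTrajectory(spec), "outside the run")
  schedOk <- data.frame(resseq = 107L, chain = "A", tOn = 0, tOff = 400,
                        class = "PIP2", stringsAsFactors = FALSE)
  lowOffset <- syntheticSpec(seed = 1, system = "dimer_45x15x15",
                             nFrames = 5L, nReplicates = 1L,
                             contactSchedule = schedOk)
  expect_error(scriptTrajectory(lowOffset), "proteinOffset")
  ## an angle ramp needs the dimer
  expect_error(scriptTrajectory(syntheticSpec(
    seed = 1, system = "monomer_18nm", nFrames = 5L, nReplicates = 1L,
    angleRamp = c(120, 100))), "dimer")
})

test_that("empty schedules give all-zero contact matrices and occupancies", {
  spec <- syntheticSpec(seed = 91, system = "monomer_18nm", nFrames = 4L,
                        nReplicates = 1L, noiseSigma = 0)
  tr <- scriptTrajectory(spec)$trajectories[[1]]
  cs <- contactSeries(tr, "ALL")
  expect_equal(sum(cs@contacts), 0)
  expect_true(is.na(cs@tFirstGlobal))
  expect_warning(op <- occupancyProfile(cs), "all-zero")
  expect_true(all(asTable(op)$occupancy == 0))
})
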