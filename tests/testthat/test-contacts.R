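test_that("minimum distance honours the minimum-image convention", {
  expect_equal(minDistance(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  a <- matrix(c(0.05, 0, 0), 1)
  b <- matrix(c(0.95, 0, 0), 1)
  expect_equal(minDistance(a, b, box = c(1, 1, 1), pbc = TRUE), 0.1)
  expect_equal(minDistance(a, b, pbc = FALSE), 0.9)
  expect_error(minDistance(matrix(numeric(0), 0, 3), b), "non-empty")
})

test_that("grid neighbour search equals the exhaustive all-pairs scan", {
  set.seed(123)
  for (i in 1:25) {
    box <- runif(3, 4, 8)
    na <- sample(20:60, 1); nb <- sample(20:60, 1)
    a <- cbind(runif(na, -2, box[1] + 2), runif(na, 0, box[2]),
               runif(na, 0, box[3]))
    b <- cbind(runif(nb, 0, box[1]), runif(nb, 0, box[2]),
               runif(nb, 0, box[3]))
    grp <- sample(0:4, na, replace = TRUE)
    cutoff <- runif(1, 0.3, 1.2)
    grid <- memBAR:::cpp_group_contact_grid(a, grp, 5L, b, cutoff, box, TRUE)
    brute <- memBAR:::cpp_group_min_dist_brute(a, grp, 5L, b, box, TRUE) <= cutoff
    expect_identical(as.logical(grid), as.logical(brute))
  }
})

test_that("contact matrices realise scripted schedules exactly", {
  sched <- data.frame(
    resseq = c(107L, 134L), chain = c("A", "A"),
    tOn = c(400, 1000), tOff = c(1200, 1800),
    class = c("PIP2", "CDL"), stringsAsFactors = FALSE)
  spec <- syntheticSpec(seed = 21, system = "monomer_18nm", nFrames = 10L,
                        nReplicates = 1L, contactSchedule = sched,
                        noiseSigma = 0.05)
  res <- scriptTrajectory(spec)
  tr <- res$trajectories[[1]]
  t <- frameTimes(tr)
  csP <- contactSeries(tr, "PIP2")
  csC <- contactSeries(tr, "CDL")
  r107 <- which(csP@residues$resseq == 107 & csP@residues$chain == "A")
  r134 <- which(csC@residues$resseq == 134 & csC@residues$chain == "A")
  expect_identical(csP@contacts[r107, ], t >= 400 & t < 1200)
  expect_identical(csC@contacts[r134, ], t >= 1000 & t < 1800)
  expect_equal(sum(csP@contacts[-r107, ]), 0)
  expect_equal(sum(csC@contacts[-r134, ]), 0)
  ## first global contact = earliest schedule onset, over all classes
  expect_equal(csC@tFirstGlobal, 400)
  ## brute-force path gives the identical matrix
  csB <- contactSeries(tr, "PIP2", method = "brute")
  expect_identical(csB@contacts, csP@contacts)
})

test_that("cutoff limits behave: tiny cutoff finds nothing, huge cutoff everything", {
  spec <- syntheticSpec(seed = 2, system = "monomer_18nm", nFrames = 3L,
                        nReplicates = 1L, noiseSigma = 0)
  res <- scriptTrajectory(spec)
  tr <- res$trajectories[[1]]
  tiny <- contactSeries(tr, "POPC", cutoff = 1e-6)
  expect_equal(sum(tiny@contacts), 0)
  huge <- contactSeries(tr, "POPC", cutoff = sqrt(3) * 18)
  expect_true(all(huge@contacts))
})

test_that("occupancy follows the normalised longest-run formula", {
  sched <- data.frame(resseq = 107L, chain = "A", tOn = 400, tOff = 1200,
                      class = "PIP2", stringsAsFactors = FALSE)
  spec <- syntheticSpec(seed = 3, system = "monomer_18nm", nFrames = 10L,
                        nReplicates = 1L, contactSchedule = sched,
                        noiseSigma = 0)
  res <- scriptTrajectory(spec)
  cs <- contactSeries(res$trajectories[[1]], "PIP2")
  op <- asTable(occupancyProfile(cs))
  r107 <- op$resseq == 107 & op$chain == "A"
  ## longest run 4 frames x 200 ps over (2000 - 400) ps
  expect_equal(op$occupancy[r107], 800 / 1600)
  expect_true(all(op$occupancy[!r107] == 0))

  ## always-in-contact residue from the first global contact onward -> 1
  schedFull <- data.frame(resseq = 110L, chain = "A", tOn = 0, tOff = 2000,
                          class = "POPC", stringsAsFactors = FALSE)
  spec2 <- syntheticSpec(seed = 4, system = "monomer_18nm", nFrames = 10L,
                         nReplicates = 1L, contactSchedule = schedFull,
                         noiseSigma = 0)
  cs2 <- contactSeries(scriptTrajectory(spec2)$trajectories[[1]], "POPC")
  op2 <- asTable(occupancyProfile(cs2))
  expect_equal(op2$occupancy[op2$resseq == 110 & op2$chain == "A"], 1.0)
})

test_that("occupancy equals the exhaustive run-length oracle on random series", {
  set.seed(77)
  for (i in 1:50) {
    nf <- sample(5:40, 1)
    dt <- sample(c(100, 200, 1000), 1)
    nres <- sample(2:6, 1)
    m <- matrix(runif(nres * nf) < 0.4, nres, nf)
    if (!any(m)) m[1, nf] <- TRUE
    f0 <- which(colSums(m) > 0)[1]
    tFirst <- (f0 - 1) * dt
    series <- new("ContactSeries",
                  residues = data.frame(chain = "A", resseq = seq_len(nres)),
                  lipidClass = "POPC", contacts = m,
                  times = (seq_len(nf) - 1) * dt, dt = dt,
                  tFirstGlobal = tFirst, cutoff = 0.4)
    got <- asTable(occupancyProfile(series))$occupancy
    want <- vapply(seq_len(nres), function(r)
      occupancyOracle(m[r, ], dt, tFirst), numeric(1))
    expect_equal(got, want)
  }
})

test_that("occupancy is monotone in contacts and invariant to time rescaling", {
  set.seed(5)
  base <- matrix(runif(3 * 20) < 0.3, 3, 20)
  base[1, 1] <- TRUE                    # pin tFirstGlobal at frame 1
  mkSeries <- function(m, dt) new("ContactSeries",
    residues = data.frame(chain = "A", resseq = 1:3), lipidClass = "POPC",
    contacts = m, times = (seq_len(ncol(m)) - 1) * dt, dt = dt,
    tFirstGlobal = 0, cutoff = 0.4)
  occ0 <- asTable(occupancyProfile(mkSeries(base, 200)))$occupancy
  ## flipping any single non-contact frame to contact never decreases occupancy
  off <- which(!base)
  for (j in sample(off, min(10, length(off)))) {
    m2 <- base; m2[j] <- TRUE
    occ2 <- asTable(occupancyProfile(mkSeries(m2, 200)))$occupancy
    expect_true(all(occ2 >= occ0 - 1e-12))
  }
  ## uniform time rescaling leaves occupancy unchanged
  occS <- asTable(occupancyProfile(mkSeries(base, 1700)))$occupancy
  expect_equal(occS, occ0)
})

test_that("replicate aggregation computes mean and sample SD", {
  mk <- function(v) new("OccupancyProfile",
    table = data.frame(chain = "A", resseq = 1:3, class = "POPC",
                       occupancy = v), nReplicates = 1L)
  one <- aggregateOccupancy(list(mk(c(0.2, 0.5, 1))))
  expect_equal(one@table$mean, c(0.2, 0.5, 1))
  expect_true(all(is.na(one@table$sd)))
  same <- aggregateOccupancy(list(mk(c(0.2, 0.5, 1)), mk(c(0.2, 0.5, 1)),
                                  mk(c(0.2, 0.5, 1))))
  expect_equal(same@table$sd, c(0, 0, 0))
  three <- aggregateOccupancy(list(mk(c(0, 0.4, 1)), mk(c(0.2, 0.5, 0.8)),
                                   mk(c(0.4, 0.6, 0.6))))
  expect_equal(three@table$mean, c(0.2, 0.5, 0.8))
  expect_equal(three@table$sd, c(sd(c(0, .2, .4)), sd(c(.4, .5, .6)),
                                 sd(c(1, .8, .6))))
  bad <- mk(c(0.1, 0.1, 0.1))
  bad@table$resseq <- 4:6
  expect_error(aggregateOccupancy(list(mk(c(0, 0, 0)), bad)), "mismatch")
})
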