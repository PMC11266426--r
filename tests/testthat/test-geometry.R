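test_that("helix axis recovers rod direction, oriented by residue order", {
  s <- rodStructure(30, direction = c(1, 0, 0))
  h <- helixAxis(s, "A", c(1, 30))
  expect_equal(h$axis, c(1, 0, 0), tolerance = 1e-9)
  ## reversed residue order flips the axis
  a <- atoms(s)
  a$resseq <- rev(a$resseq)
  h2 <- helixAxis(memBAR:::newStructure(a), "A", c(1, 30))
  expect_equal(h2$axis, c(-1, 0, 0), tolerance = 1e-9)
  expect_error(helixAxis(s, "A", c(1, 5)), ">= 10")
})

test_that("helix axis is equivariant under rotation", {
  s <- rodStructure(25, direction = c(1, 0, 0))
  R <- randomRotation(7)
  h0 <- helixAxis(s, "A", c(1, 25))
  h1 <- helixAxis(rigidTransform(s, R, c(1, -2, 3)), "A", c(1, 25))
  ang <- acos(min(1, abs(sum((R %*% h0$axis) * h1$axis))))
  expect_lt(ang, 1e-6)
})

test_that("helix axis of a noisy coil is recovered within 1 degree", {
  set.seed(42)
  axis <- c(2, 1, 2) / 3
  perp1 <- c(1, -2, 0) / sqrt(5)
  perp2 <- c(axis[2] * perp1[3] - axis[3] * perp1[2],
             axis[3] * perp1[1] - axis[1] * perp1[3],
             axis[1] * perp1[2] - axis[2] * perp1[1])
  t <- seq(0, 6, length.out = 40)          # 6 nm long coil
  th <- seq(0, 10 * pi, length.out = 40)
  r <- 0.23                                 # helix radius, nm
  pts <- outer(t, axis) + r * outer(cos(th), perp1) +
    r * outer(sin(th), perp2) + matrix(rnorm(120, 0, 0.02), 40, 3)
  a <- do.call(rbind, lapply(seq_len(40), function(i)
    atomRow("CA", "C", "ALA", i, "A", pts[i, 1], pts[i, 2], pts[i, 3])))
  h <- helixAxis(memBAR:::newStructure(a), "A", c(1, 40))
  ang <- acos(min(1, abs(sum(h$axis * axis)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("inter-helix angle uses the acute convention", {
  hx <- list(axis = c(1, 0, 0))
  hy <- list(axis = c(0, 1, 0))
  expect_equal(interhelixAngle(hx, hx), 0)
  expect_equal(interhelixAngle(hx, hy), 90)
  h135 <- list(axis = c(-1, 1, 0) / sqrt(2))
  expect_equal(interhelixAngle(hx, h135), 45)          # acute
  expect_equal(interhelixAngle(hx, h135, acute = FALSE), 135)
})

test_that("dimer extent measures principal-axis length in Angstrom", {
  a <- rbind(atomRow("CA", "C", "ALA", 1L, "A", 0, 0, 0),
             atomRow("CA", "C", "ALA", 2L, "A", 15, 0, 0),
             atomRow("CA", "C", "ALA", 3L, "A", 7.5, 0, 0))
  s <- memBAR:::newStructure(a)
  ex <- dimerExtent(s)
  expect_equal(ex$length, 150)
  expect_equal(ex$bundleDiameter, 0)
})

test_that("geometry operations are rigid-motion invariant", {
  d <- buildDimer()
  R <- randomRotation(3)
  d2 <- rigidTransform(d, R, c(5, -3, 2))
  ex1 <- dimerExtent(d)
  ex2 <- dimerExtent(d2)
  expect_lt(abs(ex1$length - ex2$length) / ex1$length, 1e-6)
  expect_lt(abs(ex1$bundleDiameter - ex2$bundleDiameter) /
              max(ex1$bundleDiameter, 1), 1e-6)
  a1 <- interhelixAngle(helixAxis(d, "A", c(64, 136)),
                        helixAxis(d, "B", c(64, 136)))
  a2 <- interhelixAngle(helixAxis(d2, "A", c(64, 136)),
                        helixAxis(d2, "B", c(64, 136)))
  expect_lt(abs(a1 - a2), 1e-6)
})
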