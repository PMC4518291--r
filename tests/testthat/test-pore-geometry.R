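test_that("toy PDB files round-trip through read_structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  txt <- make_toy_channel_structure(c(4, 4, 3, 4), atoms_per_ring = 8,
                                    path = f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 32L)
  expect_true(all(m$atoms$radius == 1.7))  # carbon from the packaged table
  # coordinates survive to PDB precision (first ring: radius 4, z = 0)
  ring1 <- m$atoms[m$atoms$residue_index == 1, ]
  expect_lt(max(abs(sort(ring1$x) - sort(4 * cos(2 * pi * (0:7) / 8)))), 2e-3)
  expect_equal(ring1$z, rep(0, 8))
  expect_error(read_structure(f, chain = "B"), "available chains: A")
})

test_that("cylinder profiles match the closed form R - r_atom", {
  m <- cylinder_model(c(4, 4, 4, 4))
  prof <- pore_radius_profile(m, axis = z_axis, span = c(0, 6), step = 2)
  expect_equal(prof$samples$radius, rep(2.3, 4), tolerance = 1e-6)
  expect_lt(max(prof$samples$offset), 1e-4)

  sq <- cylinder_model(c(4, 4, 3, 4))
  prof2 <- pore_radius_profile(sq, axis = z_axis, span = c(0, 6), step = 2)
  expect_equal(prof2$min_radius, 1.3, tolerance = 1e-6)
  expect_equal(prof2$min_position, 4)

  # randomized (ring radius, atom radius) pairs keep the closed form
  set.seed(99)
  for (i in 1:8) {
    R <- runif(1, 3, 6); ra <- runif(1, 1, min(2, R - 0.5))
    mm <- cylinder_model(rep(R, 3), atoms_per_ring = 16, atom_radius = ra)
    p <- pore_radius_profile(mm, axis = z_axis, span = c(2, 2), step = 1)
    expect_equal(p$samples$radius, R - ra, tolerance = 1e-6)
  }
})

test_that("profiles agree with an exhaustive fine-grid oracle on random toys", {
  set.seed(4)
  at <- data.frame(element = "C",
                   x = runif(30, -4, 4), y = runif(30, -4, 4),
                   z = runif(30, -3, 3), radius = runif(30, 1.2, 2))
  m <- structure_model(at)
  zs <- c(-2, 0, 2)
  prof <- pore_radius_profile(m, axis = z_axis, span = c(-2, 2), step = 2)
  for (i in seq_along(zs)) {
    expect_equal(prof$samples$radius[i],
                 oracle_pore_radius(at, zs[i]), tolerance = 0.05)
  }
})

test_that("removing atoms never shrinks the pore (side-chain pruning surrogate)", {
  set.seed(8)
  for (rep in 1:5) {
    at <- data.frame(element = "C",
                     x = runif(20, -4, 4), y = runif(20, -4, 4),
                     z = runif(20, -2, 2), radius = 1.7)
    full <- pore_radius_profile(structure_model(at), axis = z_axis,
                                span = c(-1, 1), step = 1)
    drop <- sample(20, 4)
    pruned <- pore_radius_profile(structure_model(at[-drop, ]),
                                  axis = z_axis, span = c(-1, 1), step = 1)
    expect_true(all(pruned$samples$radius >= full$samples$radius - 1e-9))
  }
})

test_that("profiles are invariant under rigid rotation plus translation", {
  m <- cylinder_model(c(4, 3.5, 4), atoms_per_ring = 10)
  p0 <- pore_radius_profile(m, axis = z_axis, span = c(0, 4), step = 2)
  th <- 0.7; ph <- 0.4
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  RO <- Rx %*% Rz
  shift <- c(5, -3, 2)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(RO)
  at2 <- m$atoms
  at2$x <- xyz[, 1] + shift[1]; at2$y <- xyz[, 2] + shift[2]
  at2$z <- xyz[, 3] + shift[3]
  ax2 <- list(origin = shift, direction = drop(RO %*% c(0, 0, 1)))
  p1 <- pore_radius_profile(structure_model(at2), axis = ax2,
                            span = c(0, 4), step = 2)
  expect_equal(p1$samples$radius, p0$samples$radius, tolerance = 1e-6)
})

test_that("constriction reporting respects the window and tracks atom removal", {
  sq <- cylinder_model(c(4, 4, 3, 4, 4))
  prof <- pore_radius_profile(sq, axis = z_axis, span = c(0, 8), step = 2)
  hit <- constriction_report(prof, window = c(3, 5))
  expect_equal(hit$min_radius, 1.3, tolerance = 1e-6)
  expect_equal(hit$position, 4)
  away <- constriction_report(prof, window = c(6, 8))
  expect_gt(away$min_radius, hit$min_radius)
  expect_error(constriction_report(prof, window = c(50, 60)), "outside")

  # His->Ala analogue: deleting the constriction ring's atoms widens the pore
  at <- sq$atoms
  wide <- pore_radius_profile(structure_model(at[at$z != 4, ]),
                              axis = z_axis, span = c(0, 8), step = 2)
  expect_gt(constriction_report(wide, c(3, 5))$min_radius, hit$min_radius)
})

test_that("degenerate inputs are handled: occlusion is radius 0, few atoms error", {
  occ <- suppressWarnings(cylinder_model(c(1.5), atom_radius = 1.7))
  prof <- pore_radius_profile(occ, axis = z_axis, span = c(0, 0), step = 1,
                              disc_radius = 1)
  expect_equal(prof$samples$radius, 0)
  expect_error(
    pore_radius_profile(structure_model(
      data.frame(element = "C", x = 0, y = 0, z = 0)), axis = z_axis),
    "at least 4 atoms")
  expect_error(structure_model(
    data.frame(element = "ZZ", x = 0, y = 0, z = 0)), "ZZ")
})
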