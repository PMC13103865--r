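test_that("minimum_image matches examples and the 27-image brute force", {
  expect_equal(sqrt(sum(minimum_image(10, c(1, 0, 0), c(9, 0, 0))^2)), 2)
  expect_equal(minimum_image(10, c(3, 4, 5), c(3, 4, 5)), c(0, 0, 0))
  # boundary convention: components lie in (-L/2, L/2]
  expect_equal(minimum_image(10, c(0, 0, 0), c(5, 0, 0))[1L], 5)
  expect_equal(minimum_image(10, c(0, 0, 0), c(-5, 0, 0))[1L], 5)
  set.seed(1)
  for (rep in 1:20) {
    L <- runif(1, 5, 60)
    a <- runif(3, -2 * L, 2 * L)
    b <- runif(3, -2 * L, 2 * L)
    d <- minimum_image(L, a, b)
    expect_equal(sqrt(sum(d^2)),
                 sqrt(sum(oracle_min_image(L, a, b)^2)), tolerance = 1e-10)
    expect_lte(sqrt(sum(d^2)), L * sqrt(3) / 2 + 1e-12)
    expect_equal(sqrt(sum(minimum_image(L, b, a)^2)), sqrt(sum(d^2)))
  }
})

test_that("molecule_com unwraps across the boundary and is translation invariant", {
  f <- make_frame(list(rbind(c(0, 0, 0), c(2, 0, 0))), "agent", 10)
  expect_equal(molecule_com(f, 1), c(1, 0, 0))
  # molecule split across the boundary: centre at 10 = 0, not 5
  fs <- make_frame(list(rbind(c(9.5, 1, 1), c(0.5, 1, 1))), "agent", 10)
  expect_equal(molecule_com(fs, 1), c(0, 1, 1))
  # invariance (mod L) under rigid translation of the whole frame
  set.seed(2)
  f3 <- make_frame(list(matrix(runif(15, 0, 10), 5L, 3L)), "agent", 10)
  for (rep in 1:10) {
    t0 <- runif(3, -20, 20)
    ft <- f3; ft$coords <- sweep(ft$coords, 2L, t0, "+")
    delta <- (molecule_com(ft, 1) - molecule_com(f3, 1) - t0) %% 10
    expect_true(all(pmin(abs(delta), abs(delta - 10)) < 1e-8))
  }
})

test_that("plane_normal is correct, rotation-covariant and order-invariant", {
  hex <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  f <- make_frame(list(hex), "xanthine", 50, plane = list(1:6))
  expect_equal(abs(plane_normal(f, 1)[3L]), 1, tolerance = 1e-10)
  set.seed(3)
  for (rep in 1:10) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]),
                  1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]),
                  1 - 2 * (q[2]^2 + q[3]^2)), 3L, 3L)
    fr <- f; fr$coords <- f$coords %*% t(R) + 25
    n0 <- plane_normal(f, 1); nr <- plane_normal(fr, 1)
    expect_equal(abs(sum((R %*% n0) * nr)), 1, tolerance = 1e-8)
  }
  # permuting the plane atoms leaves the normal unchanged up to sign
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  fp <- make_frame(list(hex[perm, ]), "xanthine", 50, plane = list(1:6))
  expect_equal(abs(sum(plane_normal(f, 1) * plane_normal(fp, 1))), 1,
               tolerance = 1e-10)
  # parallel stacked copies have parallel normals
  f2 <- make_frame(list(hex, sweep(hex, 2L, c(0, 0, 3.4), "+")),
                   c("xanthine", "xanthine"), 50, plane = list(1:6, 1:6))
  ang <- acos(min(1, abs(sum(plane_normal(f2, 1) * plane_normal(f2, 2)))))
  expect_lt(ang, 1e-6)
  fc <- make_frame(list(cbind(0:3, 0, 0)), "xanthine", 50, plane = list(1:4))
  expect_error(plane_normal(fc, 1), "collinear")
})

test_that("XYZ round trip is lossless and malformed input errors", {
  g <- generate_box(box_spec(box_edge = 30,
                             fibrils = list(c("XAN", "AGT", "XAN")),
                             n_free_xanthine = 3, n_water = 15, seed = 3))
  traj <- trajectory(list(g$frame, g$frame))
  traj[[2L]]$coords <- traj[[2L]]$coords + 0.37   # distinct second frame
  xyz <- withr::local_tempfile(fileext = ".xyz")
  smap <- withr::local_tempfile(fileext = ".csv")
  write_xyz(traj, xyz)
  write_species_map(g$frame, smap)
  back <- read_xyz(xyz, smap)
  expect_length(back, 2L)
  expect_lt(max(abs(back[[1L]]$coords - traj[[1L]]$coords)), 1e-6)
  expect_lt(max(abs(back[[2L]]$coords - traj[[2L]]$coords)), 1e-6)
  expect_identical(back[[1L]]$species, g$frame$species)
  expect_identical(molecule_roles(back[[1L]]), molecule_roles(g$frame))

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "box=10", "C 0 0 0", "C 1 0 0", "C 2 0 0", "C 3 0 0"),
             bad)
  expect_error(read_xyz(bad, smap), "mismatch")
  nobox <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "no box here", "C 0 0 0"), nobox)
  expect_error(read_xyz(nobox, smap), "box=")
})

test_that("PDB round trip is lossless at PDB precision; cell is validated", {
  g <- generate_box(box_spec(box_edge = 30,
                             fibrils = list(c("XAN", "AGT", "XAN")),
                             n_free_xanthine = 2, n_water = 10, seed = 4))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  smap <- withr::local_tempfile(fileext = ".csv")
  write_pdb(trajectory(list(g$frame, g$frame)), pdb)
  write_species_map(g$frame, smap)
  back <- read_pdb(pdb, smap)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$box_edge, 30)
  expect_lt(max(abs(back[[1L]]$coords - g$frame$coords)), 1e-3)

  lines <- readLines(pdb)
  noncubic <- withr::local_tempfile(fileext = ".pdb")
  lines[1L] <- "CRYST1   80.000   80.000   80.000  90.00  90.00 120.00 P 1           1"
  writeLines(lines, noncubic)
  expect_error(read_pdb(noncubic, smap), "cubic")
  nocryst <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-1L], nocryst)
  expect_error(read_pdb(nocryst, smap), "CRYST1")
})

test_that("XYZ and PDB round trips preserve the downstream census exactly", {
  g <- generate_box(box_spec(box_edge = 28,
                             fibrils = list(c("XAN", "AGT", "XAN", "XAN")),
                             n_free_xanthine = 3, n_water = 25, seed = 6))
  ref <- neighbor_census(g$frame)$per_obs
  smap <- withr::local_tempfile(fileext = ".csv")
  write_species_map(g$frame, smap)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g$frame, xyz)
  expect_identical(neighbor_census(read_xyz(xyz, smap))$per_obs[, -1L],
                   ref[, -1L])
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(g$frame, pdb)
  expect_identical(neighbor_census(read_pdb(pdb, smap))$per_obs[, -1L],
                   ref[, -1L])
})

test_that("trajectory construction enforces a shared topology", {
  g <- generate_box(box_spec(box_edge = 40, n_free_xanthine = 3, seed = 1))
  h <- generate_box(box_spec(box_edge = 40, n_free_xanthine = 4, seed = 1))
  expect_error(trajectory(list(g$frame, h$frame)), "topology")
  expect_error(trajectory(list()), "at least one")
})
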