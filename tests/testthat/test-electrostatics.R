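# The PB solver checks run on small grids chosen to finish in seconds while
# staying well inside the analytic tolerances.

test_that("uniform-dielectric solution matches screened Coulomb at 8-12 A", {
  ion <- make_point_charge_cluster(1, rbind(c(0, 0, 0)))
  g <- solve_potential(ion$assembly, radii = 1, probe = 0, spacing = 0.5,
                       extension = 13, uniform = TRUE, tol = 1e-5)
  r <- seq(8, 12, 1)
  num <- interp_potential(g, cbind(r, 0, 0))
  ana <- 332.0637 / (80 * r) / (0.0019872041 * 298)
  expect_true(all(abs(num - ana) / ana < 0.02))
})

test_that("zero charges give an identically zero potential", {
  none <- make_point_charge_cluster(0, rbind(c(0, 0, 0)))
  g <- solve_potential(none$assembly, radii = 1, probe = 0, spacing = 1,
                       extension = 5)
  expect_true(all(g$values == 0))
})

test_that("Born-ion reaction-field energy is within 5% of the closed form", {
  ion <- make_point_charge_cluster(1, rbind(c(0, 0, 0)))
  e <- pb_solvation_energy(ion$assembly, radii = 2, probe = 0, spacing = 0.35,
                           extension = 6, tol = 1e-4)
  analytic <- -0.5 * 332.0637 * (1 - 1 / 80) / 2
  expect_lt(abs(e - analytic) / abs(analytic), 0.05)
})

test_that("the linearized solver is linear and antisymmetric in the charges", {
  pos <- rbind(c(-2, 0, 0), c(2, 0, 0))
  mk <- function(q) make_point_charge_cluster(q, pos)$assembly
  solve2 <- function(q) solve_potential(mk(q), radii = 1.5, probe = 0,
                                        spacing = 0.5, extension = 5,
                                        tol = 1e-5)
  g_ab <- solve2(c(1, -0.5))
  g_a <- solve2(c(1, 0))
  g_b <- solve2(c(0, -0.5))
  expect_lt(max(abs(g_ab$values - (g_a$values + g_b$values))), 0.05)
  g_neg <- solve2(c(-1, 0.5))
  expect_equal(g_neg$values, -g_ab$values, tolerance = 1e-12)
})

test_that("the +10 kT/e isopotential of a point charge is a sphere", {
  ion <- make_point_charge_cluster(1, rbind(c(0, 0, 0)))
  g <- solve_potential(ion$assembly, radii = 0.1, probe = 0, spacing = 0.06,
                       extension = 1.6, uniform = TRUE, tol = 1e-5)
  iso <- suppressWarnings(isopotential_surfaces(g, levels = c(-10, 10)))
  m <- iso[["+10 kT/e"]]
  expect_gt(nrow(m$vertices), 100)
  r <- sqrt(rowSums(m$vertices^2))
  analytic <- 332.0637 / (80 * 10 * 0.0019872041 * 298)
  expect_lt(abs(mean(r) - analytic) / analytic, 0.05)
  expect_gt(min(r) / max(r), 0.95)
  expect_true(mesh_is_closed(m))
  # the -10 kT/e level does not exist for a positive-only system
  expect_equal(nrow(iso[["-10 kT/e"]]$vertices), 0)
})

test_that("the zero isopotential of a symmetric dipole is its bisecting plane", {
  dip <- make_point_charge_cluster(c(1, -1), rbind(c(-2, 0, 0), c(2, 0, 0)))
  g <- solve_potential(dip$assembly, radii = 0.5, probe = 0, spacing = 0.25,
                       extension = 4, uniform = TRUE, tol = 1e-5)
  m <- marching_tetrahedra(g$values, 0, g$origin, g$spacing)
  expect_gt(nrow(m$vertices), 100)
  expect_lt(max(abs(m$vertices[, 1])), 1e-6)
})

test_that("surface mapping reproduces a sphere's area and sign", {
  a <- atom_table(1, "CA", "C", "ALA", "A", 1, x = 0, y = 0, z = 0)
  asm <- new_assembly(a, "protomer")
  at <- assign_params(asm)
  at$charge <- 1   # a positive unit charge on the lone atom
  g <- solve_potential(at, spacing = 0.6, extension = 5)
  m <- map_to_surface(g, at, spacing = 0.2)
  vdw <- at$vdw[1]
  expect_lt(abs(mesh_area(m) - 4 * pi * vdw^2) / (4 * pi * vdw^2), 0.05)
  expect_true(mesh_is_closed(m))
  expect_true(all(m$potential > 0))
  expect_true(all(abs(m$potential_clamped) <= 0.3 + 1e-12))
  # selections outside the solved grid are rejected
  far <- at; far$x <- far$x + 100
  expect_error(map_to_surface(g, far), "extent")
})

test_that("grid refinement converges the surface-averaged potential", {
  dip <- make_point_charge_cluster(c(1, -0.5), rbind(c(-1.5, 0, 0), c(1.5, 0, 0)))
  avg_at <- function(h) {
    g <- solve_potential(dip$assembly, radii = 1.5, probe = 0, spacing = h,
                         extension = 5, tol = 1e-5)
    pts <- cbind(4 * cos(seq(0, 2 * pi, length.out = 50)),
                 4 * sin(seq(0, 2 * pi, length.out = 50)), 0)
    mean(interp_potential(g, pts))
  }
  v1 <- avg_at(0.8); v2 <- avg_at(0.4)
  expect_lt(abs(v2 - v1) / max(abs(v2), 1e-9), 0.05)
})

test_that("grid, mesh and charge exports are well-formed", {
  dip <- make_point_charge_cluster(c(1, -1), rbind(c(-2, 0, 0), c(2, 0, 0)))
  g <- solve_potential(dip$assembly, radii = 1, probe = 0, spacing = 1,
                       extension = 4)
  fdx <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, fdx)
  lines <- readLines(fdx)
  expect_true(any(grepl("gridpositions", lines)))
  nvals <- sum(vapply(grep("^[ -]?[0-9]", lines, value = TRUE),
                      function(l) length(strsplit(trimws(l), "\\s+")[[1]]),
                      integer(1)))
  expect_equal(nvals, prod(g$dims))
  m <- marching_tetrahedra(g$values, 1, g$origin, g$spacing)
  fply <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, fply)
  pl <- readLines(fply)
  expect_equal(pl[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(m$vertices)), pl)))
  fpqr <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(fix_tripeptide(), fpqr)
  pq <- readLines(fpqr)
  expect_true(all(startsWith(utils::head(pq, -1), "ATOM")))
  flds <- strsplit(trimws(pq[1]), "\\s+")[[1]]
  expect_length(flds, 11)  # name res chain resno xyz charge radius
})
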