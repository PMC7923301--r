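test_that("the C3 fixture is an exact symmetric trimer with a buried plant", {
  tri <- fix_trimer()
  expect_equal(tri$kind, "trimer")
  pr <- protomers(tri)
  expect_length(pr, 3)
  # exact symmetry: internal geometry identical across protomers
  d1 <- dist_xyz(coords(pr[[1]]))
  expect_equal(dist_xyz(coords(pr[[2]])), d1, tolerance = 1e-6)
  expect_equal(dist_xyz(coords(pr[[3]])), d1, tolerance = 1e-6)
  # generator-verified plant: the interface residue touches a neighbor
  expect_lt(tri$info$planted$min_interprotomer_dist, 4.5)
  planted <- pr[[1]][pr[[1]]$resno == tri$info$planted$resno, ]
  expect_equal(unique(planted$resname), "GLN")
  # at least 3 atoms of the planted residue in inter-protomer contact (< 4.5 A)
  others <- dplyr::bind_rows(pr[[2]], pr[[3]])
  mind <- apply(dist_xyz(coords(planted), coords(others)), 1, min)
  expect_gte(sum(mind < 4.5), 3)
})

test_that("generated operators reconstruct the generated trimer exactly", {
  tri <- fix_trimer()
  protA <- new_assembly(protomers(tri)[[1]], "protomer")
  again <- build_biological_unit(protA, tri$info$operators)
  expect_equal(coords(again), coords(tri), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fixtures are deterministic and round-trip through PDB", {
  t1 <- make_c3_trimer(seed = 7)
  t2 <- make_c3_trimer(seed = 7)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(t1, f1, operators = t1$info$operators)
  write_structure(t2, f2, operators = t2$info$operators)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- make_c3_trimer(seed = 8)
  expect_false(identical(coords(t1), coords(t3)))
  rd <- read_structure(f1)
  expect_equal(coords(rd$assembly), coords(t1), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_length(rd$operators, 3)
})

test_that("overly tight fixture geometry is rejected as a clash", {
  expect_error(make_c3_trimer(radius = 2.5), "clash")
  expect_error(make_c3_trimer(n_res = 4), "at least 8")
})

test_that("the trend pair contrasts interface and surface plants", {
  tp <- make_mutation_trend_pair(seed = 1)
  expect_identical(residue_table(tp$interface)$resname,
                   residue_table(tp$surface)$resname)
  # interface plant in contact, surface plant pointing away
  surf_pr <- protomers(tp$surface)
  planted <- surf_pr[[1]][surf_pr[[1]]$resno == 6 &
                            !surf_pr[[1]]$name %in% c("N", "CA", "C", "O"), ]
  others <- dplyr::bind_rows(surf_pr[[2]], surf_pr[[3]])
  expect_equal(sum(dist_xyz(coords(planted), coords(others)) < 4.5), 0)
  expect_lt(tp$interface$info$planted$min_interprotomer_dist, 4.5)
})

test_that("the head-to-head fixture separates two intact copies", {
  hh <- make_head_to_head_fixture(fix_trimer())
  expect_equal(hh$hexamer$kind, "hexamer")
  pr <- protomers(hh$hexamer)
  expect_equal(names(pr), c("A", "B", "C", "D", "E", "F"))
  # the two trimer groups have identical internal geometry
  g1 <- dplyr::bind_rows(pr[1:3]); g2 <- dplyr::bind_rows(pr[4:6])
  expect_equal(dist_xyz(coords(g1)), dist_xyz(coords(g2)), tolerance = 1e-6)
  # close enough to interact, no clashes
  gap <- min(dist_xyz(coords(g1), coords(g2)))
  expect_gt(gap, 1.5)
  expect_lt(gap, 6)
})
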