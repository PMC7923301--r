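test_that("PDB write/read round trip preserves atoms exactly", {
  asm <- fix_tripeptide()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm, f)
  rd <- read_structure(f)
  expect_equal(nrow(rd$assembly$atoms), nrow(asm$atoms))
  expect_equal(rd$assembly$atoms$name, asm$atoms$name)
  expect_equal(rd$assembly$atoms$resno, asm$atoms$resno)
  expect_equal(rd$assembly$atoms$resname, asm$atoms$resname)
  expect_equal(coords(rd$assembly), coords(asm), tolerance = 1e-3,
               ignore_attr = TRUE)
  # second trip is bit-stable at PDB precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rd$assembly, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("BIOMT operators are parsed and survive a round trip", {
  asm <- fix_tripeptide()
  ops <- list(symmetry_operator(diag(3), label = "identity"),
              symmetry_operator(rotation_about_axis(c(0, 0, 1), 120),
                                label = "rot120"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm, f, operators = ops)
  rd <- read_structure(f)
  expect_length(rd$operators, 2)
  expect_equal(rd$operators[[1]]$rotation, diag(3), tolerance = 1e-6)
  expect_equal(rd$operators[[2]]$rotation,
               rotation_about_axis(c(0, 0, 1), 120), tolerance = 1e-5)
})

test_that("malformed and empty inputs fail with informative errors", {
  asm <- fix_tripeptide()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm, f)
  lines <- readLines(f)
  bad <- which(startsWith(lines, "ATOM"))[2]
  lines[bad] <- paste0(substr(lines[bad], 1, 30), "  oops   ",
                       substr(lines[bad], 40, nchar(lines[bad])))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  expect_error(read_structure(f2), sprintf("line %d", bad))
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK none", "END"), f3)
  expect_error(read_structure(f3), "empty structure")
  expect_error(symmetry_operator(matrix(2 * diag(3), 3, 3)), "orthonormal")
})

test_that("biological-unit reconstruction yields an exact C3 trimer", {
  asm <- fix_tripeptide()
  ops <- list(symmetry_operator(diag(3), label = "id"),
              symmetry_operator(rotation_about_axis(c(0, 0, 1), 120),
                                translation = c(0, 0, 0), label = "r120"),
              symmetry_operator(rotation_about_axis(c(0, 0, 1), 240),
                                translation = c(0, 0, 0), label = "r240"))
  # place the chain off-axis so the copies are distinct
  off <- asm
  off$atoms <- set_coords(off$atoms, sweep(coords(off$atoms), 2, c(8, 0, 0), "+"))
  tri <- build_biological_unit(off, ops)
  expect_s3_class(tri, "assembly")
  expect_equal(tri$kind, "trimer")
  pr <- protomers(tri)
  expect_equal(names(pr), c("A", "B", "C"))
  # centroid of protomer centroids lies on the rotation axis
  cent <- colMeans(do.call(rbind, lapply(pr, function(p) colMeans(coords(p)))))
  expect_equal(cent[1:2], c(x = 0, y = 0), tolerance = 1e-6)
  # per-protomer internal geometry identical across copies
  d1 <- dist_xyz(coords(pr[[1]]))
  for (k in 2:3) expect_equal(dist_xyz(coords(pr[[k]])), d1, tolerance = 1e-6)
  # arity is enforced
  expect_error(build_biological_unit(off, ops[1]), "arity")
  # applying the C3 set to any copy reproduces the same three placements
  again <- build_biological_unit(new_assembly(pr[[2]], "protomer"), ops)
  key <- function(a) {
    m <- round(coords(a), 4)
    paste(sort(apply(m, 1, paste, collapse = ",")), collapse = ";")
  }
  expect_equal(key(as_tibble(again$atoms)), key(as_tibble(tri$atoms)))
})

test_that("protomer superposition pairs atoms by residue and name", {
  asm <- fix_tripeptide()
  a <- asm$atoms
  moved <- set_coords(a, sweep(coords(a), 2, c(1, 2, 3), "+"))
  tr <- superpose(moved, a)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  expect_equal(tr$translation, c(-1, -2, -3), tolerance = 1e-9)
  self <- superpose(a, a, atom_selection = "heavy")
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_error(superpose(a[a$name == "CA", ][1:2, ], a), "underdetermined")
})

test_that("head-to-head hexamer placement follows the template geometry", {
  tri <- fix_trimer()
  hh <- make_head_to_head_fixture(tri, separation = 40)
  hex <- hh$hexamer
  expect_equal(hex$kind, "hexamer")
  expect_length(protomers(hex), 6)
  a <- hex$atoms
  c1 <- colMeans(coords(a[a$chain %in% c("A", "B", "C"), ]))
  c2 <- colMeans(coords(a[a$chain %in% c("D", "E", "F"), ]))
  expect_equal(sqrt(sum((c1 - c2)^2)), 40, tolerance = 0.01)
  # a degenerate template (both units at the same place) must clash
  protA <- protomers(tri)[[1]]
  dup <- protA; dup$chain <- "X"
  tmpl <- new_assembly(renumber_serials(dplyr::bind_rows(protA, dup)), "protomer")
  expect_error(build_head_to_head(tri, tmpl), "clash")
})
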