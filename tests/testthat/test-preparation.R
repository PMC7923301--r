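water_at <- function(x, y, z, resno, chain = "W") {
  atom_table(serial = 1L, name = "O", element = "O", resname = "HOH",
             chain = chain, resno = resno, x = x, y = y, z = z, hetero = TRUE)
}

test_that("water pruning keeps waters near protein and drops water-only clusters", {
  asm <- fix_tripeptide()
  prot <- asm$atoms
  # an oxygen of the protein to anchor the "kept" water
  o1 <- prot[prot$name == "O", ][1, ]
  w_near <- water_at(o1$x + 3.0, o1$y, o1$z, 501L)       # 3.0 A from protein O
  w_far <- water_at(o1$x + 60, o1$y, o1$z, 502L)         # isolated, 60 A away
  # a chain of three waters 2.8 A apart, all > 3.5 A from any protein atom
  base <- c(o1$x, o1$y + 40, o1$z)
  wc <- dplyr::bind_rows(water_at(base[1], base[2], base[3], 503L),
                         water_at(base[1] + 2.8, base[2], base[3], 504L),
                         water_at(base[1] + 5.6, base[2], base[3], 505L))
  all_atoms <- renumber_serials(dplyr::bind_rows(prot, w_near, w_far, wc))
  asm2 <- new_assembly(all_atoms, "protomer")
  pruned <- prune_waters(asm2, cutoff = 3.5)
  expect_equal(pruned$deleted, 4L)   # far water + the 3-water chain
  left <- pruned$assembly$atoms
  expect_true(501 %in% left$resno[is_water(left)])
  expect_false(any(c(502, 503, 504, 505) %in% left$resno[is_water(left)]))
  # no waters at all -> nothing deleted
  expect_equal(prune_waters(asm)$deleted, 0L)
})

test_that("water pruning is order-independent", {
  asm <- fix_tripeptide()
  o1 <- asm$atoms[asm$atoms$name == "O", ][1, ]
  ws <- dplyr::bind_rows(water_at(o1$x + 3.0, o1$y, o1$z, 501L),
                         water_at(o1$x + 50, o1$y, o1$z, 502L),
                         water_at(o1$x + 52.8, o1$y, o1$z, 503L))
  a1 <- renumber_serials(dplyr::bind_rows(asm$atoms, ws))
  set.seed(3)
  a2 <- renumber_serials(a1[sample(nrow(a1)), ])
  r1 <- prune_waters(new_assembly(a1, "protomer"))
  r2 <- prune_waters(new_assembly(a2, "protomer"))
  expect_equal(r1$deleted, r2$deleted)
  key <- function(r) sort(paste(r$assembly$atoms$resno, r$assembly$atoms$name))
  expect_equal(key(r1), key(r2))
})

test_that("pH 7.5 protonation follows the standard states", {
  pep <- new_assembly(build_peptide("AEKRDA"), "protomer")
  pr <- assign_protonation(pep, ph = 7.5)
  st <- pr$assignments
  expect_equal(st$state[st$resname == "GLU"], "deprotonated")
  expect_equal(st$formal_charge[st$resname == "GLU"], -1)
  expect_equal(st$state[st$resname == "LYS"], "protonated")
  expect_equal(st$state[st$resname == "ARG"], "protonated")
  expect_equal(sum(st$formal_charge), 0)  # (K+R) - (D+E)
  expect_equal(formal_charge(new_assembly(build_peptide("EEK"), "protomer")), -1L)
  # implicit hydrogens are counted and non-negative
  expect_gt(pr$added_hydrogens, 0)
})

test_that("close S-gamma pairs are assigned as disulfides", {
  c1 <- build_peptide("C", chain = "A")
  c2 <- build_peptide("C", chain = "B", start_resno = 2L)
  sg1 <- unlist(c1[c1$name == "SG", c("x", "y", "z")])
  sg2 <- unlist(c2[c2$name == "SG", c("x", "y", "z")])
  # translate chain B so the S-S distance is 2.05 A along x
  c2 <- set_coords(c2, sweep(coords(c2), 2, sg1 + c(2.05, 0, 0) - sg2, "+"))
  both <- new_assembly(renumber_serials(dplyr::bind_rows(c1, c2)), "protomer")
  st <- assign_protonation(both)$assignments
  expect_true(all(st$state[st$resname == "CYS"] == "disulfide"))
  # far apart they stay thiols
  lone <- assign_protonation(new_assembly(c1, "protomer"))$assignments
  expect_equal(lone$state[lone$resname == "CYS"], "thiol")
})

rot_a_to_b <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c0 <- sum(a * b)
  if (s < 1e-12) return(diag(3))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

place_partner_at_nd1 <- function(his, partner, tip_name, dist = 2.9) {
  nd1 <- unlist(his[his$name == "ND1", c("x", "y", "z")])
  ne2 <- unlist(his[his$name == "NE2", c("x", "y", "z")])
  u <- (nd1 - ne2) / sqrt(sum((nd1 - ne2)^2))  # away from the other ring N
  ca <- unlist(partner[partner$name == "CA", c("x", "y", "z")])
  tip <- unlist(partner[partner$name == tip_name, c("x", "y", "z")])
  R <- rot_a_to_b(tip - ca, -u)   # side chain points back toward the ring
  rot <- coords(partner) %*% t(R)
  tip_new <- rot[which(partner$name == tip_name), ]
  set_coords(partner, sweep(rot, 2, nd1 + dist * u - tip_new, "+"))
}

test_that("His tautomer maximizes the local hydrogen-bond count", {
  his <- build_peptide("H", chain = "A")
  # an acceptor (Asp carboxylate O) near Nd1 -> Nd1 donates -> Nd1-H tautomer
  asp <- place_partner_at_nd1(his, build_peptide("D", chain = "B",
                                                 start_resno = 9L), "OD1")
  st1 <- assign_protonation(new_assembly(
    renumber_serials(dplyr::bind_rows(his, asp)), "protomer"))$assignments
  expect_equal(st1$state[st1$resname == "HIS"], "Nd1-H")
  # a donor (Lys N-zeta) near Nd1 -> Nd1 accepts -> Ne2-H tautomer
  lys <- place_partner_at_nd1(his, build_peptide("K", chain = "B",
                                                 start_resno = 9L), "NZ")
  st2 <- assign_protonation(new_assembly(
    renumber_serials(dplyr::bind_rows(his, lys)), "protomer"))$assignments
  expect_equal(st2$state[st2$resname == "HIS"], "Ne2-H")
})

test_that("capped minimization lowers energy without exceeding the cap", {
  asm <- fix_tripeptide()
  # stretch one terminal side-chain bond by displacing its tip atom
  a <- asm$atoms
  tip <- which(a$name == "CD1")[1]
  anchor <- which(a$name == "CG")[1]
  v <- unlist(a[tip, c("x", "y", "z")]) - unlist(a[anchor, c("x", "y", "z")])
  a[tip, c("x", "y", "z")] <- as.list(unlist(a[tip, c("x", "y", "z")]) +
                                        0.5 * v / sqrt(sum(v^2)))
  stretched <- new_assembly(a, "protomer")
  mn <- minimize_capped(stretched, rmsd_cap = 0.3, max_steps = 100)
  expect_lt(mn$report$energy_final, mn$report$energy_initial)
  expect_lte(mn$report$final_heavy_atom_rmsd, 0.3 + 1e-6)
  # zero cap returns coordinates unchanged
  mn0 <- minimize_capped(stretched, rmsd_cap = 0)
  expect_identical(coords(mn0$assembly), coords(stretched))
  expect_equal(mn0$report$minimization_steps, 0L)
})

test_that("a converged structure is a fixed point of the minimizer", {
  relaxed <- cached("relaxed_gxg", {
    minimize_capped(build_gxg("A"), rmsd_cap = 5, max_steps = 2000,
                    chunk = 100)$assembly
  })
  again <- minimize_capped(relaxed, rmsd_cap = 5, max_steps = 200, chunk = 100)
  expect_lt(again$report$final_heavy_atom_rmsd, 5e-3)
  expect_equal(again$report$energy_final, again$report$energy_initial,
               tolerance = 1e-6)
})

test_that("the preparation report assembles all stages", {
  asm <- fix_tripeptide()
  pp <- prepare_structure(asm, max_steps = 20)
  expect_s3_class(pp$report, "tbl_df")
  expect_gte(pp$report$added_hydrogens, 0)
  expect_equal(pp$report$deleted_waters, 0L)
  expect_lte(pp$report$final_heavy_atom_rmsd, 0.3 + 1e-6)
  expect_lte(pp$report$energy_final, pp$report$energy_initial)
})
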