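test_that("toy Coulomb energies match the closed form", {
  toy <- make_point_charge_cluster(c(1, -1), rbind(c(0, 0, 0), c(10, 0, 0)))
  e <- energy(toy$assembly)
  expect_equal(e$coulomb, 332.0637 * (-1) / 10, tolerance = 1e-12)
  expect_equal(e$total, e$coulomb, tolerance = 1e-12)
  expect_equal(e$bonded + e$vdw + e$gb_polar + e$sa_nonpolar, 0)
  expect_equal(toy$pairs$energy, -33.20637, tolerance = 1e-9)
  # a single neutral atom has no interactions
  single <- make_point_charge_cluster(0, rbind(c(0, 0, 0)))
  es <- energy(single$assembly)
  expect_true(all(abs(unlist(es)) < 1e-12))
  expect_error(make_point_charge_cluster(c(1, 1), rbind(c(0, 0, 0), c(0, 0, 0))),
               "singularity")
})

test_that("energy is invariant under chain reordering", {
  toy <- toy_two_trimers()
  a <- toy$assembly
  perm <- a
  set.seed(5)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  perm$atoms <- renumber_serials(perm$atoms)
  expect_equal(energy(a)$total, energy(perm)$total, tolerance = 1e-12)
})

test_that("breakdown components always sum to the total", {
  for (x in list(fix_tripeptide(), fix_trimer())) {
    e <- energy(x)
    expect_equal(e$total,
                 e$bonded + e$vdw + e$coulomb + e$gb_polar + e$sa_nonpolar,
                 tolerance = 1e-9)
  }
})

test_that("generalized Born reproduces the Born formula for a single ion", {
  a <- atom_table(1, "Q1", "C", "ION", "A", 1, x = 0, y = 0, z = 0)
  a$charge <- 1
  asm <- new_assembly(a, "toy")
  at <- assign_params(asm)
  rho <- at$vdw - 0.09
  gb <- oligovar:::gb_energy(at, coords(at))
  expect_equal(gb, -0.5 * 332.0637 * (1 - 1 / 80) / rho, tolerance = 1e-9)
})

test_that("toy binding ddG equals the brute-force pairwise Coulomb oracle", {
  wt <- toy_two_trimers()
  q_mut <- c(0.5, -0.3, 0.8, 0.4, -0.6, 0.2)
  q_mut[1] <- -q_mut[1]   # sign-flip "mutation" in chain A
  mut <- make_point_charge_cluster(q_mut,
                                   coords(wt$assembly),
                                   chains = rep(c("A", "B"), each = 3))
  rec <- ddg_bind(mut$assembly, wt$assembly, left = 1, right = 2)
  # oracle: cross-partition pairwise sums, difference mutant - WT
  aw <- assign_params(wt$assembly); am <- assign_params(mut$assembly)
  oracle <- brute_coulomb(am, 1:3, 4:6) - brute_coulomb(aw, 1:3, 4:6)
  expect_equal(rec$ddg_b_app, oracle, tolerance = 1e-9)
  expect_equal(rec$ddg_b_coulomb, oracle, tolerance = 1e-9)
  expect_equal(rec$ddg_b_solv, 0)
  expect_equal(rec$ddg_b_residual, 0)
  # folding leg: total pair-sum difference
  fold <- ddg_fold(mut$assembly, wt$assembly, fix_spec(), n_mut = 1)
  oracle_f <- brute_coulomb(am, 1:6) - brute_coulomb(aw, 1:6)
  expect_equal(fold$ddg_f_app, oracle_f, tolerance = 1e-9)
})

test_that("the all-WT composition closes the cycle at exactly zero", {
  wt <- toy_two_trimers()
  rec <- ddg_bind(wt$assembly, wt$assembly, left = 1, right = 2)
  expect_true(all(unlist(rec) == 0))
  fold <- ddg_fold(wt$assembly, wt$assembly, fix_spec(), n_mut = 0)
  expect_true(all(unlist(fold) == 0))
  tri <- fix_trimer()
  rec2 <- ddg_bind(tri, tri, left = 1, right = 2:3)
  expect_true(all(unlist(rec2) == 0))
})

test_that("binding ddG is invariant under swapping symmetric units", {
  wt <- toy_two_trimers(q = rep(c(0.4, -0.2, 0.6), 2))
  qm <- rep(c(0.4, -0.2, 0.6), 2)
  qm[c(1, 4)] <- -qm[c(1, 4)]   # same mutation in both units
  mut <- make_point_charge_cluster(qm, coords(wt$assembly),
                                   chains = rep(c("A", "B"), each = 3))
  r12 <- ddg_bind(mut$assembly, wt$assembly, left = 1, right = 2)
  r21 <- ddg_bind(mut$assembly, wt$assembly, left = 2, right = 1)
  expect_equal(r12$ddg_b_app, r21$ddg_b_app, tolerance = 1e-9)
})

test_that("thermodynamic-cycle closure: both legs agree identically", {
  wt <- toy_two_trimers()
  qm <- c(-0.5, -0.3, 0.8, 0.4, -0.6, 0.2)
  mut <- make_point_charge_cluster(qm, coords(wt$assembly),
                                   chains = rep(c("A", "B"), each = 3))
  msys <- ff_system(mut$assembly); wsys <- ff_system(wt$assembly)
  leg1 <- binding_dg(msys, 1, 2, assembly = mut$assembly)$total -
    binding_dg(wsys, 1, 2, assembly = wt$assembly)$total
  dcx <- energy(msys, subset = 1:6)$total - energy(wsys, subset = 1:6)$total
  dl <- energy(msys, subset = 1:3)$total - energy(wsys, subset = 1:3)$total
  dr <- energy(msys, subset = 4:6)$total - energy(wsys, subset = 4:6)$total
  leg2 <- dcx - dl - dr
  expect_equal(leg1, leg2, tolerance = 1e-9)
})

test_that("compositions related by the assembly symmetry score equally", {
  tri <- fix_trimer()
  sp <- fix_spec()
  singles <- lapply(1:3, function(k) {
    fl <- rep(FALSE, 3); fl[k] <- TRUE
    mut <- apply_mutation(tri, fl, sp)$assembly
    energy(mut)$total
  })
  expect_equal(singles[[1]], singles[[2]], tolerance = 0.1)
  expect_equal(singles[[1]], singles[[3]], tolerance = 0.1)
})

test_that("trimer scan emits 21 binding records with folding attached", {
  rec <- fix_trimer_scan()
  expect_equal(nrow(rec), 21)
  expect_equal(length(unique(rec$composition)), 7)
  expect_true(all(rec$mode == "protomer_vs_rest"))
  # folding value identical across a composition's three pairings
  per_comp <- tapply(rec$ddg_f_app, rec$composition,
                     function(v) diff(range(v)))
  expect_true(all(per_comp == 0))
  # empty composition list yields empty output via n=1 protomer scan path
  prot <- new_assembly(protomers(fix_trimer())[[1]], "protomer")
  rec1 <- scan_compositions(prot, fix_spec())
  expect_equal(nrow(rec1), 1)
  expect_true(is.na(rec1$ddg_b_app))
  expect_true(is.finite(rec1$ddg_f_app))  # fold-only record, no pairing
})

test_that("decomposition conservation holds for every scan record", {
  rec <- fix_trimer_scan()
  expect_equal(rec$ddg_b_app,
               rec$ddg_b_coulomb + rec$ddg_b_solv + rec$ddg_b_residual,
               tolerance = 1e-6)
  expect_equal(rec$ddg_f_app,
               rec$ddg_f_coulomb + rec$ddg_f_solv + rec$ddg_f_residual,
               tolerance = 1e-6)
})

test_that("pooling reports sample statistics with absent SD for n = 1", {
  toy <- tibble::tibble(flags = list(c(TRUE, FALSE, FALSE),
                                     c(FALSE, TRUE, FALSE),
                                     c(FALSE, FALSE, TRUE),
                                     c(TRUE, TRUE, TRUE)),
                        ddg_b_app = c(1, 2, 3, 9),
                        ddg_f_app = c(1, 2, 3, 9))
  p <- pool_ddg(toy)
  expect_equal(p$ddg_b_app_mean, c(2, 9))
  expect_equal(p$ddg_b_app_sd, c(1, NA))
  expect_equal(p$n, c(3L, 1L))
  # permutation invariance
  p2 <- pool_ddg(toy[c(4, 2, 1, 3), ])
  expect_equal(p, p2)
})
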