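# Synthetic fixtures: C3-symmetric toy trimers with a planted polar residue
# at the three-fold interface (the buried-glutamine analog), head-to-head
# hexamers of two such trimers, and point-charge toy systems with analytic
# interaction energies. Protomers are ideal poly-Ala helices with a few
# planted residues: the pipeline's contracts are topology- and
# chemistry-level, so no attempt is made to mimic a real beta-sandwich fold.
# A single integer seed determines each fixture byte-for-byte.

# orient an atom table so the principal axis of its CA trace lies along +z
orient_along_z <- function(atoms) {
  ca <- atoms[atoms$name == "CA", ]
  xyz <- coords(atoms)
  cxyz <- coords(ca)
  ctr <- colMeans(cxyz)
  sv <- svd(sweep(cxyz, 2, ctr))
  axis <- sv$v[, 1]
  if (axis[3] < 0) axis <- -axis
  # rotation taking axis -> z
  z <- c(0, 0, 1)
  v <- pracma_cross(axis, z)
  s <- sqrt(sum(v^2)); c0 <- sum(axis * z)
  R <- if (s < 1e-12) diag(3) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
  }
  set_coords(atoms, sweep(sweep(xyz, 2, ctr) %*% t(R), 2, c(0, 0, 0), "+"))
}

c3_operators <- function() {
  list(symmetry_operator(diag(3), label = "identity"),
       symmetry_operator(rotation_about_axis(c(0, 0, 1), 120), label = "C3_120"),
       symmetry_operator(rotation_about_axis(c(0, 0, 1), 240), label = "C3_240"))
}

#' Generate a C3-symmetric toy trimer with a planted interface residue
#'
#' Builds one ideal helical protomer, points the planted residue's side chain
#' at the three-fold axis, places the protomer at `radius` from the axis and
#' reconstructs the trimer with exact C3 operators. The generator verifies
#' its own plant: the planted residue must contact a neighboring protomer
#' within `contact_cutoff`, and no inter-protomer heavy atoms may clash.
#'
#' @param n_res residues per protomer (>= 8).
#' @param interface_pos residue number of the planted residue.
#' @param interface_aa one-letter code of the planted residue (default "Q",
#'   the buried-glutamine analog).
#' @param radius distance of the protomer helix axis from the C3 axis (A).
#' @param orientation "interface" points the planted side chain at the axis;
#'   "surface" points it away (the non-interface control).
#' @param contact_cutoff maximum allowed distance (A) of the planted residue
#'   to the nearest neighboring protomer (checked only for "interface").
#' @param seed integer seed controlling side-chain chi jitter.
#' @param jitter_sd standard deviation (degrees) of chi-angle jitter on
#'   unplanted side chains.
#' @return assembly of kind "trimer"; `info` holds the symmetry operators,
#'   the planted address and the generator spec.
#' @export
make_c3_trimer <- function(n_res = 12, interface_pos = 6, interface_aa = "Q",
                           radius = 5.8, orientation = c("interface", "surface"),
                           contact_cutoff = 4.5, seed = 1, jitter_sd = 4) {
  orientation <- match.arg(orientation)
  if (n_res < 8) abort("fixture protomers need at least 8 residues")
  seq1 <- rep("A", n_res)
  seq1[interface_pos] <- interface_aa
  # a hydrophobic neighbor flanking the plant, as in a zipper-like interface
  if (interface_pos + 2 <= n_res) seq1[interface_pos + 2] <- "L"
  set.seed(seed)
  chi <- list()
  for (i in seq_len(n_res)) {
    rn <- aa_three(seq1[i])
    nchi <- N_CHI[[rn]]
    if (nchi > 0 && i != interface_pos) {
      base <- rotamer_library(rn)$rotamer[[1]]
      chi[[as.character(i)]] <- base + stats::rnorm(nchi, 0, jitter_sd)
    }
  }
  prot <- build_peptide(paste(seq1, collapse = ""), phi = -57, psi = -47,
                        chain = "A", chi = chi)
  prot <- orient_along_z(prot)
  # point the planted side chain toward -x (the C3 axis sits at the origin
  # after the protomer is shifted to +x)
  res <- prot[prot$resno == interface_pos, ]
  ca <- unlist(res[res$name == "CA", c("x", "y", "z")])
  tip_name <- utils::tail(res$name, 1)
  tip <- unlist(res[res$name == tip_name, c("x", "y", "z")])
  v <- (tip - ca)[1:2]
  target <- if (orientation == "interface") c(-1, 0) else c(1, 0)
  ang <- atan2(target[2], target[1]) - atan2(v[2], v[1])
  Rz <- rotation_about_axis(c(0, 0, 1), rad2deg(ang))
  prot <- set_coords(prot, coords(prot) %*% t(Rz))
  prot <- set_coords(prot, sweep(coords(prot), 2, c(radius, 0, 0), "+"))
  asym <- new_assembly(prot, kind = "protomer")
  ops <- c3_operators()
  tri <- build_biological_unit(asym, ops)
  # generator self-checks
  pr <- protomers(tri)
  planted_a <- pr[[1]][pr[[1]]$resno == interface_pos, ]
  others <- dplyr::bind_rows(pr[[2]], pr[[3]])
  dmin_plant <- min(dist_xyz(coords(planted_a), coords(others)))
  dmin_all <- min(dist_xyz(coords(pr[[1]]), coords(others)))
  if (dmin_all < 1.6) {
    abort(sprintf("fixture generation error: inter-protomer clash (%.2f A); increase radius", dmin_all))
  }
  if (orientation == "interface" && dmin_plant > contact_cutoff) {
    abort(sprintf("fixture generation error: planted residue does not reach the interface (%.2f A)", dmin_plant))
  }
  tri$info <- list(
    operators = ops,
    planted = list(resno = interface_pos, aa = interface_aa,
                   orientation = orientation,
                   min_interprotomer_dist = dmin_plant),
    spec = list(kind = "c3_trimer", n_res = n_res, radius = radius,
                seed = seed, jitter_sd = jitter_sd)
  )
  tri
}

#' Head-to-head template and hexamer fixture
#'
#' Builds the two-unit template (a protomer and its 180-degree flipped,
#' axially translated copy) that defines a top-to-top trimer-trimer
#' arrangement, and the hexamer obtained by placing two copies of the trimer
#' on it with [build_head_to_head()].
#'
#' @param trimer a C3 trimer fixture (from [make_c3_trimer()]).
#' @param separation distance between the two trimer centroids along the C3
#'   axis (A). Default NULL chooses the smallest separation with a 4 A gap
#'   between closest heavy atoms.
#' @return list with `template` (2-chain assembly) and `hexamer`.
#' @export
make_head_to_head_fixture <- function(trimer, separation = NULL) {
  ta <- as_atoms(trimer)
  zspan <- range(ta$z)
  if (is.null(separation)) separation <- (zspan[2] - zspan[1]) + 4
  protA <- protomers(trimer)[[1]]
  flip <- rotation_about_axis(c(1, 0, 0), 180)
  mkcopy <- function(at) {
    cp <- set_coords(at, coords(at) %*% t(flip))
    ctr0 <- colMeans(coords(at)); ctr1 <- colMeans(coords(cp))
    # put the flipped copy directly above, separated along z
    set_coords(cp, sweep(coords(cp), 2,
                         c(ctr0[1] - ctr1[1], ctr0[2] - ctr1[2],
                           ctr0[3] - ctr1[3] + separation), "+"))
  }
  top <- mkcopy(protA)
  top$chain <- "X"
  tmpl_atoms <- renumber_serials(dplyr::bind_rows(protA, top))
  template <- new_assembly(tmpl_atoms, kind = "protomer",
                           info = list(separation = separation))
  hexamer <- build_head_to_head(trimer, template)
  hexamer$info$separation <- separation
  hexamer$info$planted <- trimer$info$planted
  list(template = template, hexamer = hexamer)
}

#' Point-charge toy system with analytic pairwise energies
#'
#' Produces a "toy" assembly scored by the Coulomb term alone, together with
#' the brute-force pairwise interaction table that serves as the analytic
#' oracle for the thermodynamic cycle.
#'
#' @param charges numeric charges (e).
#' @param positions n x 3 matrix of positions (A).
#' @param chains chain label per charge (defines subunit partitions).
#' @return list with `assembly` (kind "toy") and `pairs`, a tibble of all
#'   pairwise terms `332.0637 * qi * qj / rij`.
#' @export
make_point_charge_cluster <- function(charges, positions,
                                      chains = rep("A", length(charges))) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(charges)
  stopifnot(nrow(positions) == n)
  if (n > 1 && min(dist_xyz(positions)[upper.tri(matrix(0, n, n))]) < 1e-9) {
    abort("singularity error: coincident charge positions")
  }
  atoms <- atom_table(serial = seq_len(n), name = paste0("Q", seq_len(n)),
                      element = "C", resname = "ION", chain = chains,
                      resno = seq_len(n), x = positions[, 1],
                      y = positions[, 2], z = positions[, 3])
  atoms$charge <- as.numeric(charges)
  pairs <- if (n > 1) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    r <- sqrt(rowSums((positions[ij[, 1], , drop = FALSE] -
                       positions[ij[, 2], , drop = FALSE])^2))
    tibble(i = ij[, 1], j = ij[, 2], r = r,
           energy = ELEC_CONST * charges[ij[, 1]] * charges[ij[, 2]] / r)
  } else {
    tibble(i = integer(), j = integer(), r = numeric(), energy = numeric())
  }
  list(assembly = new_assembly(atoms, kind = "toy"), pairs = pairs)
}

#' Matched interface/surface fixture pair for trend tests
#'
#' Two C3 trimers identical except for the planted residue's orientation:
#' buried at the three-fold interface versus fully solvent-exposed. Used to
#' check that an interface charge swap destabilizes folding much more than
#' the same substitution at a surface site.
#'
#' @param seed fixture seed.
#' @param ... further arguments passed to [make_c3_trimer()].
#' @return list with `interface` and `surface` assemblies.
#' @export
make_mutation_trend_pair <- function(seed = 1, ...) {
  list(interface = make_c3_trimer(orientation = "interface", seed = seed, ...),
       surface = make_c3_trimer(orientation = "surface", seed = seed, ...))
}
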