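# Implicit-solvent scoring: Hawkins-Cramer-Truhlar (pairwise-descreening)
# generalized Born polar term with the Still interpolation formula, plus a
# linear solvent-accessible-surface-area nonpolar term (Shrake-Rupley SASA).
# energy() returns the additive breakdown used by the thermodynamic cycle:
# bonded + vdw + coulomb + gb_polar + sa_nonpolar = total.

# effective Born radii by HCT pairwise descreening
born_radii <- function(atoms, xyz) {
  rho <- pmax(atoms$vdw - GB_OFFSET, 0.5)
  s <- atoms$gb_screen * rho
  n <- nrow(xyz)
  if (n == 1) return(rho)
  D <- dist_xyz(xyz)
  inv_sum <- numeric(n)
  for (i in seq_len(n)) {
    r <- D[i, -i]; sj <- s[-i]
    ri <- rho[i]
    U <- r + sj
    descr <- ri < U            # atom j reaches outside rho_i
    if (!any(descr)) next
    r <- r[descr]; sj <- sj[descr]; U <- U[descr]
    L <- pmax(abs(r - sj), ri)
    H <- 0.5 * ((1 / L - 1 / U) +
                (r / 4) * (1 / U^2 - 1 / L^2) +
                (1 / (2 * r)) * log(L / U) +
                (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
    inv_sum[i] <- sum(H)
  }
  Rinv <- 1 / rho - inv_sum
  Rinv <- pmax(Rinv, 1 / 30)   # cap effective radii at 30 A
  1 / Rinv
}

gb_energy <- function(atoms, xyz) {
  q <- atoms$charge
  if (all(q == 0)) return(0)
  R <- born_radii(atoms, xyz)
  D <- dist_xyz(xyz)
  RR <- outer(R, R)
  f <- sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
  qq <- outer(q, q)
  -0.5 * ELEC_CONST * (1 / EPS_SOLUTE - 1 / EPS_SOLVENT) * sum(qq / f)
}

# deterministic unit-sphere points (golden spiral)
sphere_points <- function(n = 120) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' @param x assembly or atom tibble (parameters are assigned if absent).
#' @param probe probe radius in Angstrom.
#' @param n_points test points per atom sphere.
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa_atoms <- function(x, probe = 1.4, n_points = 120) {
  a <- as_atoms(x)
  if (!"vdw" %in% names(a)) a <- assign_params(x)
  xyz <- coords(a)
  dimnames(xyz) <- NULL
  r <- a$vdw + probe
  n <- nrow(a)
  # express coordinates in the molecule's principal-axis frame so that the
  # discretized sphere sampling - and hence the SASA - is invariant under
  # rigid-body motion of the whole structure
  if (n > 2) {
    ctr <- colMeans(xyz)
    X <- sweep(xyz, 2, ctr)
    V <- svd(X)$v
    # sign convention from molecule-intrinsic invariants (projection skewness,
    # falling back to an atom-order moment), so the frame rotates with the
    # molecule instead of depending on the lab axes
    for (k in 1:3) {
      proj <- X %*% V[, k]
      s <- sum(proj^3)
      if (abs(s) < 1e-8) s <- sum(proj * seq_along(proj))
      if (s < 0) V[, k] <- -V[, k]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    xyz <- X %*% V
  }
  pts <- sphere_points(n_points)
  out <- numeric(n)
  D <- dist_xyz(xyz)
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] < r[i] + r & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nbr) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nbr) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
        acc <- acc & (d2 > r[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * r[i]^2 * frac
  }
  out
}

#' Energy of an assembly (or a subset of its atoms)
#'
#' Evaluates the additive energy breakdown on fixed coordinates: harmonic
#' bonded terms, Lennard-Jones, Coulomb (solute dielectric 1), generalized
#' Born polar solvation (solvent dielectric 80) and linear-SASA nonpolar
#' solvation. Deterministic for fixed coordinates. A subset selection scores
#' the chosen atoms in their current (complex) geometry, which is what the
#' single-structure thermodynamic cycle requires.
#'
#' @param x assembly, atom tibble, or `ff_system`.
#' @param subset optional integer vector of atom rows to score.
#' @param solvation include GB + SASA terms (disabled automatically for toy
#'   point-charge systems unless requested).
#' @return one-row tibble: bonded, vdw, coulomb, gb_polar, sa_nonpolar, total.
#' @export
energy <- function(x, subset = NULL, solvation = NULL) {
  sys <- if (inherits(x, "ff_system")) x else ff_system(x)
  if (is.null(solvation)) solvation <- !sys$toy
  xyz <- coords(sys$atoms)
  if (is.null(subset)) subset <- seq_len(nrow(xyz))
  sub_atoms <- sys$atoms[subset, ]
  sub_xyz <- xyz[subset, , drop = FALSE]
  if (length(subset) == nrow(xyz)) {
    bonded <- mm_bond_energy(sys, xyz) + mm_angle_energy(sys, xyz)
  } else {
    bsel <- sys$bonds$i %in% subset & sys$bonds$j %in% subset
    asel <- sys$angles$i %in% subset & sys$angles$j %in% subset &
      sys$angles$k %in% subset
    sysb <- sys; sysb$bonds <- sys$bonds[bsel, ]; sysb$angles <- sys$angles[asel, ]
    bonded <- mm_bond_energy(sysb, xyz) + mm_angle_energy(sysb, xyz)
  }
  vdw <- mm_lj_energy(sys, xyz, subset)
  coul <- mm_coulomb_energy(sys, xyz, subset)
  gb <- 0; sa <- 0
  if (solvation) {
    gb <- gb_energy(sub_atoms, sub_xyz)
    sa <- SA_GAMMA * sum(sasa_atoms(sub_atoms))
  }
  tibble(bonded = bonded, vdw = vdw, coulomb = coul,
         gb_polar = gb, sa_nonpolar = sa,
         total = bonded + vdw + coul + gb + sa)
}
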