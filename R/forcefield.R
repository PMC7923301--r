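# The package's molecular-mechanics model: bonded terms (harmonic bonds and
# angles), Lennard-Jones and Coulomb nonbonded terms with 1-2/1-3 exclusions.
# Torsions are omitted: for fixed-backbone, comparative scoring of
# compositions the conformational strain relevant to the scan is carried by
# the nonbonded terms, and the displacement-capped minimizer keeps structures
# near their starting geometry. Charges/radii come from params.R; "toy"
# assemblies (point-charge clusters) carry their own charge column and are
# scored with the Coulomb term only.

K_BOND <- 300   # kcal/mol/A^2
K_ANGLE <- 50   # kcal/mol/rad^2
GB_OFFSET <- 0.09  # intrinsic radius = vdW - offset (A)
SA_GAMMA <- 0.0072 # kcal/mol/A^2
EPS_SOLVENT <- 80
EPS_SOLUTE <- 1

#' Assign force-field parameters to an atom table
#'
#' Joins per-atom charge, vdW radius, Lennard-Jones parameters and GB
#' screening factors onto the table. Protein atoms are matched by
#' (residue name, atom name); waters get zero charge; atoms of a "toy"
#' assembly keep the `charge` column they already carry.
#'
#' @param x assembly or atom tibble.
#' @return atom tibble with columns charge, vdw, lj_rmin2, lj_eps, gb_screen,
#'   n_h, sp2 added.
#' @export
assign_params <- function(x) {
  a <- as_atoms(x)
  toy <- is_assembly(x) && x$kind == "toy"
  param_cols <- c("vdw", "lj_rmin2", "lj_eps", "gb_screen", "charge", "n_h", "sp2")
  if (all(param_cols %in% names(a))) return(a)   # already parameterized
  keep_charge <- if (toy) a$charge else NULL
  a <- a[, setdiff(names(a), param_cols)]
  ep <- element_params()
  a2 <- a %>% left_join(ep, by = "element")
  if (!is.null(keep_charge)) a2$charge <- keep_charge
  if (anyNA(a2$vdw)) {
    a2$vdw[is.na(a2$vdw)] <- 1.70
    a2$lj_rmin2[is.na(a2$lj_rmin2)] <- 1.908
    a2$lj_eps[is.na(a2$lj_eps)] <- 0.086
    a2$gb_screen[is.na(a2$gb_screen)] <- 0.80
  }
  if (toy) {
    if (is.null(keep_charge)) abort("toy assembly atoms need a charge column")
    a2$n_h <- 0L; a2$sp2 <- FALSE
    return(a2)
  }
  rp <- residue_params()
  a2 <- a2 %>% left_join(rp[, c("resname", "name", "charge", "n_h", "sp2")],
                         by = c("resname", "name"))
  wat <- is_water(a2)
  a2$charge[wat] <- 0; a2$n_h[wat] <- 2L; a2$sp2[wat] <- FALSE
  bad <- is.na(a2$charge) & !a2$hetero
  if (any(bad)) {
    miss <- unique(paste0(a2$resname[bad], ":", a2$name[bad]))
    abort(paste0("no force-field parameters for: ",
                 paste(utils::head(miss, 8), collapse = ", ")))
  }
  a2$charge[is.na(a2$charge)] <- 0
  a2$n_h[is.na(a2$n_h)] <- 0L
  a2$sp2[is.na(a2$sp2)] <- FALSE
  a2
}

# bond list (i, j row indices, r0) for a parameterized atom table
topology_bonds <- function(atoms) {
  zm <- sidechain_zmat()
  res <- atoms %>% mutate(.row = row_number()) %>% filter(!is_water(atoms))
  out <- list()
  keyd <- split(seq_len(nrow(res)), paste(res$chain, res$resno, res$ins))
  # order groups as they appear
  ord <- unique(paste(res$chain, res$resno, res$ins))
  idx_of <- function(rows, nm) {
    i <- rows[res$name[rows] == nm]
    if (length(i) >= 1) i[1] else NA_integer_
  }
  add <- function(i, j, r0) {
    if (!is.na(i) && !is.na(j)) out[[length(out) + 1]] <<- c(res$.row[i], res$.row[j], r0)
  }
  prev_c <- NA_integer_; prev_chain <- ""
  for (k in ord) {
    rows <- keyd[[k]]
    rn <- res$resname[rows[1]]
    iN <- idx_of(rows, "N"); iCA <- idx_of(rows, "CA")
    iC <- idx_of(rows, "C"); iO <- idx_of(rows, "O"); iCB <- idx_of(rows, "CB")
    add(iN, iCA, BB_GEOM$n_ca); add(iCA, iC, BB_GEOM$ca_c)
    add(iC, iO, BB_GEOM$c_o); add(iCA, iCB, 1.530)
    zr <- zm[zm$resname == rn, , drop = FALSE]
    if (nrow(zr) > 0) {
      for (q in seq_len(nrow(zr))) add(idx_of(rows, zr$c[q]), idx_of(rows, zr$name[q]), zr$bond[q])
    }
    cl <- RING_CLOSURES[[rn]]
    if (!is.null(cl)) {
      for (pr in cl) {
        r0 <- CLOSURE_BOND_LENGTHS[[paste(pr[1], pr[2], sep = "-")]]
        add(idx_of(rows, pr[1]), idx_of(rows, pr[2]), r0)
      }
    }
    # peptide bond to previous residue in the same chain, if geometrically bonded
    ch <- res$chain[rows[1]]
    if (!is.na(prev_c) && identical(prev_chain, ch) && !is.na(iN)) {
      d <- sqrt(sum((c(res$x[prev_c], res$y[prev_c], res$z[prev_c]) -
                     c(res$x[iN], res$y[iN], res$z[iN]))^2))
      if (d < 1.8) add(prev_c, iN, BB_GEOM$c_n)
    }
    prev_c <- iC; prev_chain <- ch
  }
  # disulfides
  sg <- which(res$name == "SG")
  if (length(sg) > 1) {
    dm <- dist_xyz(cbind(res$x[sg], res$y[sg], res$z[sg]))
    for (i in seq_along(sg)) for (j in seq_along(sg)) {
      if (i < j && dm[i, j] < 2.5) add(sg[i], sg[j], 2.04)
    }
  }
  if (length(out) == 0) {
    return(tibble(i = integer(), j = integer(), r0 = numeric()))
  }
  m <- do.call(rbind, out)
  tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r0 = m[, 3])
}

topology_angles <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (nrow(bonds) == 0) {
    return(tibble(i = integer(), j = integer(), k = integer(), theta0 = numeric()))
  }
  nb <- vector("list", n)
  for (q in seq_len(nrow(bonds))) {
    nb[[bonds$i[q]]] <- c(nb[[bonds$i[q]]], bonds$j[q])
    nb[[bonds$j[q]]] <- c(nb[[bonds$j[q]]], bonds$i[q])
  }
  out <- list()
  for (cen in seq_len(n)) {
    nbs <- nb[[cen]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      th0 <- if (isTRUE(atoms$sp2[cen])) 120 else 109.5
      out[[length(out) + 1]] <- cbind(t(cmb), cen, th0)
    }
  }
  if (length(out) == 0) {
    return(tibble(i = integer(), j = integer(), k = integer(), theta0 = numeric()))
  }
  m <- do.call(rbind, out)
  tibble(i = as.integer(m[, 1]), j = as.integer(m[, 3]), k = as.integer(m[, 2]),
         theta0 = m[, 4])
}

# 1-2 and 1-3 exclusion mask (n x n logical, TRUE = excluded)
exclusion_mask <- function(n, bonds, angles) {
  ex <- matrix(FALSE, n, n)
  diag(ex) <- TRUE
  if (nrow(bonds) > 0) {
    ex[cbind(bonds$i, bonds$j)] <- TRUE; ex[cbind(bonds$j, bonds$i)] <- TRUE
  }
  if (nrow(angles) > 0) {
    ex[cbind(angles$i, angles$k)] <- TRUE; ex[cbind(angles$k, angles$i)] <- TRUE
  }
  ex
}

#' Build an energy system from an assembly
#'
#' Precomputes parameters, bond/angle topology and exclusion lists so that
#' repeated energy evaluations (scans, minimization) are cheap.
#'
#' @param x assembly or atom tibble.
#' @return list of class `ff_system`.
#' @export
ff_system <- function(x) {
  toy <- is_assembly(x) && x$kind == "toy"
  atoms <- assign_params(x)
  if (toy) {
    bonds <- tibble(i = integer(), j = integer(), r0 = numeric())
    angles <- tibble(i = integer(), j = integer(), k = integer(), theta0 = numeric())
  } else {
    bonds <- topology_bonds(atoms)
    angles <- topology_angles(atoms, bonds)
  }
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 excl = exclusion_mask(nrow(atoms), bonds, angles),
                 toy = toy),
            class = "ff_system")
}

# --- MM term evaluation (vectorized) -------------------------------------

mm_bond_energy <- function(sys, xyz) {
  b <- sys$bonds
  if (nrow(b) == 0) return(0)
  d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
  sum(K_BOND * (d - b$r0)^2)
}

mm_angle_energy <- function(sys, xyz) {
  a <- sys$angles
  if (nrow(a) == 0) return(0)
  v1 <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
  v2 <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
  cosv <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
  th <- acos(pmin(1, pmax(-1, cosv)))
  sum(K_ANGLE * (th - deg2rad(a$theta0))^2)
}

# pair distance matrix + masks shared by LJ and Coulomb
nb_pairs <- function(sys, xyz, subset = NULL) {
  n <- nrow(xyz)
  idx <- if (is.null(subset)) seq_len(n) else subset
  D <- dist_xyz(xyz[idx, , drop = FALSE])
  ex <- sys$excl[idx, idx, drop = FALSE]
  keep <- upper.tri(D) & !ex
  list(idx = idx, D = D, keep = keep)
}

mm_lj_energy <- function(sys, xyz, subset = NULL) {
  if (sys$toy) return(0)
  p <- nb_pairs(sys, xyz, subset)
  at <- sys$atoms[p$idx, ]
  rmin <- outer(at$lj_rmin2, at$lj_rmin2, "+")
  eps <- sqrt(outer(at$lj_eps, at$lj_eps))
  r <- p$D[p$keep]; rm <- rmin[p$keep]; ep <- eps[p$keep]
  s6 <- (rm / r)^6
  sum(ep * (s6^2 - 2 * s6))
}

mm_coulomb_energy <- function(sys, xyz, subset = NULL) {
  p <- nb_pairs(sys, xyz, subset)
  q <- sys$atoms$charge[p$idx]
  qq <- outer(q, q)
  sum(ELEC_CONST * qq[p$keep] / p$D[p$keep]) / EPS_SOLUTE
}

# analytic gradient of bonded + LJ + Coulomb (the minimization surface)
mm_energy_grad <- function(sys, xyz) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  e <- 0
  b <- sys$bonds
  if (nrow(b) > 0) {
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    e <- e + sum(K_BOND * (d - b$r0)^2)
    coef <- 2 * K_BOND * (d - b$r0) / d
    gi <- dv * coef
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] + tapply_add(n, b$i, gi[, c3]) - tapply_add(n, b$j, gi[, c3])
    }
  }
  a <- sys$angles
  if (nrow(a) > 0) {
    v1 <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    v2 <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    r1 <- sqrt(rowSums(v1^2)); r2 <- sqrt(rowSums(v2^2))
    cosv <- pmin(1 - 1e-10, pmax(-1 + 1e-10, rowSums(v1 * v2) / (r1 * r2)))
    th <- acos(cosv)
    dth <- th - deg2rad(a$theta0)
    e <- e + sum(K_ANGLE * dth^2)
    pref <- -2 * K_ANGLE * dth / sqrt(1 - cosv^2)
    # d cos / d xi and d cos / d xk
    dci <- (v2 / (r1 * r2)) - v1 * (cosv / r1^2)
    dck <- (v1 / (r1 * r2)) - v2 * (cosv / r2^2)
    gi <- dci * pref; gk <- dck * pref
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] + tapply_add(n, a$i, gi[, c3]) +
        tapply_add(n, a$k, gk[, c3]) - tapply_add(n, a$j, gi[, c3] + gk[, c3])
    }
  }
  # nonbonded
  D <- dist_xyz(xyz)
  keep <- upper.tri(D) & !sys$excl
  ij <- which(keep, arr.ind = TRUE)
  if (nrow(ij) > 0) {
    i <- ij[, 1]; j <- ij[, 2]
    r <- D[keep]
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    qq <- sys$atoms$charge[i] * sys$atoms$charge[j]
    ec <- ELEC_CONST * qq / r
    e <- e + sum(ec)
    dEdr <- -ec / r
    if (!sys$toy) {
      rm <- sys$atoms$lj_rmin2[i] + sys$atoms$lj_rmin2[j]
      ep <- sqrt(sys$atoms$lj_eps[i] * sys$atoms$lj_eps[j])
      s6 <- (rm / r)^6
      e <- e + sum(ep * (s6^2 - 2 * s6))
      dEdr <- dEdr + ep * 12 * (s6 - s6^2) / r
    }
    coef <- dEdr / r
    gi <- dv * coef
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] + tapply_add(n, i, gi[, c3]) - tapply_add(n, j, gi[, c3])
    }
  }
  list(energy = e, gradient = g)
}

tapply_add <- function(n, idx, vals) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}
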