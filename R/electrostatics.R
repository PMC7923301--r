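# Finite-difference solution of the linearized Poisson-Boltzmann equation at
# zero ionic strength: two-dielectric map (solute cavity = union of atom
# spheres, optionally probe-inflated), point charges spread to grid nodes by
# trilinear weights, Dirichlet boundary from the Coulomb far field in the
# solvent dielectric, red-black successive over-relaxation. Potentials are
# reported in kT/e at 298 K; figure-facing defaults (dielectrics 1/80, probe
# 1.4 A, 5 A grid extension) match the surface-map conventions used for
# trimer potential figures.

#' Solve the grid potential around an assembly
#'
#' @param x assembly (protein or toy) or atom tibble with a `charge` column.
#' @param spacing grid spacing (A).
#' @param extension grid margin beyond the atom spheres (A).
#' @param eps_in,eps_out solute/solvent dielectric constants.
#' @param probe cavity inflation radius (A); 0 gives the bare atom spheres
#'   (e.g. a Born sphere of its nominal radius).
#' @param radii optional per-atom cavity radii overriding the vdW set.
#' @param uniform solve with `eps_out` everywhere (no cavity) — the analytic
#'   Coulomb-screening regime used for solver validation.
#' @param tol convergence tolerance: maximum node update (kT/e) per sweep.
#' @param max_iter sweep budget.
#' @param omega SOR over-relaxation factor.
#' @return object of class `grid_potential`: origin, spacing, dims, `values`
#'   (3D array, kT/e), the dielectric parameters and the convergence record.
#' @export
solve_potential <- function(x, spacing = 0.8, extension = 5,
                            eps_in = 1, eps_out = 80, probe = 1.4,
                            radii = NULL, uniform = FALSE,
                            tol = 1e-3, max_iter = 3000, omega = 1.9) {
  a <- as_atoms(x)
  if (!"charge" %in% names(a) || !"vdw" %in% names(a)) a <- assign_params(x)
  xyz <- coords(a)
  q <- a$charge
  rad <- if (!is.null(radii)) rep_len(radii, nrow(a)) else a$vdw
  rad <- rad + probe
  lo <- apply(xyz - rad, 2, min) - extension
  hi <- apply(xyz + rad, 2, max) + extension
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  origin <- lo
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  gx <- origin[1] + (0:(nx - 1)) * spacing
  gy <- origin[2] + (0:(ny - 1)) * spacing
  gz <- origin[3] + (0:(nz - 1)) * spacing
  # dielectric at face midpoints: inside any atom sphere -> eps_in
  eps_at <- function(px, py, pz) {
    e <- array(eps_out, dim = c(length(px), length(py), length(pz)))
    if (uniform) return(e)
    charged <- which(rad > 0)
    for (i in charged) {
      dx2 <- (px - xyz[i, 1])^2
      dy2 <- (py - xyz[i, 2])^2
      dz2 <- (pz - xyz[i, 3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") < rad[i]^2
      e[inside] <- eps_in
    }
    e
  }
  ex <- eps_at(gx[-nx] + spacing / 2, gy, gz)   # faces along x
  ey <- eps_at(gx, gy[-ny] + spacing / 2, gz)
  ez <- eps_at(gx, gy, gz[-nz] + spacing / 2)
  # trilinear charge assignment (units: e)
  rho <- array(0, dim = dims)
  fi <- (xyz[, 1] - origin[1]) / spacing
  fj <- (xyz[, 2] - origin[2]) / spacing
  fk <- (xyz[, 3] - origin[3]) / spacing
  i0 <- pmin(pmax(floor(fi), 0), nx - 2); wi <- fi - i0
  j0 <- pmin(pmax(floor(fj), 0), ny - 2); wj <- fj - j0
  k0 <- pmin(pmax(floor(fk), 0), nz - 2); wk <- fk - k0
  for (n in seq_len(nrow(a))) {
    if (q[n] == 0) next
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wi[n] else 1 - wi[n]) *
           (if (dj) wj[n] else 1 - wj[n]) *
           (if (dk) wk[n] else 1 - wk[n])
      idx <- cbind(i0[n] + di + 1, j0[n] + dj + 1, k0[n] + dk + 1)
      rho[idx] <- rho[idx] + q[n] * w
    }
  }
  # Dirichlet boundary: Coulomb far field in the solvent dielectric (e/A)
  phi <- array(0, dim = dims)
  bset <- function(ii, jj, kk) {
    P <- as.matrix(expand.grid(gx[ii], gy[jj], gz[kk]))
    val <- numeric(nrow(P))
    for (n in which(q != 0)) {
      r <- sqrt((P[, 1] - xyz[n, 1])^2 + (P[, 2] - xyz[n, 2])^2 +
                (P[, 3] - xyz[n, 3])^2)
      val <- val + q[n] / (eps_out * pmax(r, 1e-6))
    }
    array(val, dim = c(length(ii), length(jj), length(kk)))
  }
  phi[1, , ] <- bset(1, 1:ny, 1:nz); phi[nx, , ] <- bset(nx, 1:ny, 1:nz)
  phi[, 1, ] <- bset(1:nx, 1, 1:nz); phi[, ny, ] <- bset(1:nx, ny, 1:nz)
  phi[, , 1] <- bset(1:nx, 1:ny, 1); phi[, , nz] <- bset(1:nx, 1:ny, nz)
  # red-black SOR on interior nodes
  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nz - 1)
  exm <- ex[ii - 1, jj, kk]; exp_ <- ex[ii, jj, kk]
  eym <- ey[ii, jj - 1, kk]; eyp <- ey[ii, jj, kk]
  ezm <- ez[ii, jj, kk - 1]; ezp <- ez[ii, jj, kk]
  den <- exm + exp_ + eym + eyp + ezm + ezp
  src <- 4 * pi * rho[ii, jj, kk] / spacing
  par3 <- outer(outer(ii, jj, "+"), kk, "+") %% 2
  iters <- 0L; delta <- Inf
  while (iters < max_iter && delta > tol / KTE_PER_EA) {
    delta <- 0
    for (color in 0:1) {
      num <- exm * phi[ii - 1, jj, kk] + exp_ * phi[ii + 1, jj, kk] +
             eym * phi[ii, jj - 1, kk] + eyp * phi[ii, jj + 1, kk] +
             ezm * phi[ii, jj, kk - 1] + ezp * phi[ii, jj, kk + 1] + src
      newv <- num / den
      cur <- phi[ii, jj, kk]
      upd <- cur + omega * (newv - cur)
      mask <- par3 == color
      cur[mask] <- upd[mask]
      delta <- max(delta, max(abs(upd[mask] - phi[ii, jj, kk][mask])))
      phi[ii, jj, kk] <- cur
    }
    iters <- iters + 1L
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = phi * KTE_PER_EA,
                 eps_in = eps_in, eps_out = eps_out, probe = probe,
                 temperature = 298, extension = extension,
                 iterations = iters, residual = delta * KTE_PER_EA),
            class = "grid_potential")
}

#' @export
print.grid_potential <- function(x, ...) {
  cat(sprintf("<grid_potential> %d x %d x %d, h = %.2f A, %d sweeps (resid %.2e kT/e)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$iterations, x$residual))
  invisible(x)
}

#' Trilinear interpolation of a grid potential
#' @param grid a `grid_potential`.
#' @param pts n x 3 matrix of positions (A).
#' @return potential at the points, kT/e.
#' @export
interp_potential <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  f <- sweep(pts, 2, grid$origin) / grid$spacing
  dm <- grid$dims
  i0 <- pmin(pmax(floor(f[, 1]), 0), dm[1] - 2)
  j0 <- pmin(pmax(floor(f[, 2]), 0), dm[2] - 2)
  k0 <- pmin(pmax(floor(f[, 3]), 0), dm[3] - 2)
  wi <- f[, 1] - i0; wj <- f[, 2] - j0; wk <- f[, 3] - k0
  out <- numeric(nrow(pts))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) wi else 1 - wi) * (if (dj) wj else 1 - wj) *
         (if (dk) wk else 1 - wk)
    out <- out + w * grid$values[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  out
}

#' Reaction-field (solvation) energy from two grid solutions
#'
#' Solves the two-dielectric problem and a uniform solute-dielectric
#' reference on the same grid; the grid self-energy cancels in the
#' difference, giving the polar solvation energy 0.5 * sum q_i * dphi(x_i).
#'
#' @param x assembly or atom tibble with charges.
#' @param ... arguments passed to [solve_potential()] (spacing, radii, ...).
#' @return energy in kcal/mol.
#' @export
pb_solvation_energy <- function(x, ...) {
  args <- list(...)
  g2 <- do.call(solve_potential, c(list(x), args, list(uniform = FALSE)))
  eps_in <- g2$eps_in
  gref <- do.call(solve_potential,
                  c(list(x), args,
                    list(uniform = TRUE),
                    if (is.null(args$eps_out)) list(eps_out = eps_in) else NULL))
  if (!is.null(args$eps_out)) {
    # uniform reference must use the solute dielectric
    args2 <- args; args2$eps_out <- eps_in
    gref <- do.call(solve_potential, c(list(x), args2, list(uniform = TRUE)))
  }
  a <- as_atoms(x)
  if (!"charge" %in% names(a)) a <- assign_params(x)
  pts <- coords(a)
  dphi <- interp_potential(g2, pts) - interp_potential(gref, pts)
  0.5 * sum(a$charge * dphi) * KT_KCAL
}

#' Map the potential onto a molecular surface
#'
#' Triangulates a probe-smoothed molecular surface (the union of atom
#' spheres, probe-rolled: the solvent-accessible surface shrunk back by the
#' probe radius — exact for isolated spheres, a smooth approximation of the
#' reentrant surface in crevices) and interpolates the grid potential at
#' each vertex. Raw vertex potentials are retained; a clamped copy respects
#' the color-scale bounds used for rendering.
#'
#' @param grid solved `grid_potential` covering the selection.
#' @param x assembly or atom tibble.
#' @param selection optional logical mask of atoms to include.
#' @param probe probe radius (A).
#' @param spacing triangulation grid spacing (A).
#' @param scale_bounds color-scale bounds in kT/e (default -0.3 .. 0.3).
#' @return `surface_mesh` with `potential` (raw) and `potential_clamped`.
#' @export
map_to_surface <- function(grid, x, selection = NULL, probe = 1.4,
                           spacing = 0.5, scale_bounds = c(-0.3, 0.3)) {
  a <- as_atoms(x)
  if (!"vdw" %in% names(a)) a <- assign_params(x)
  if (!is.null(selection)) a <- a[selection, , drop = FALSE]
  xyz <- coords(a); rad <- a$vdw
  glo <- grid$origin
  ghi <- grid$origin + (grid$dims - 1) * grid$spacing
  if (any(apply(xyz, 2, min) < glo) || any(apply(xyz, 2, max) > ghi)) {
    abort("extent error: selection lies outside the solved grid")
  }
  lo <- apply(xyz - rad, 2, min) - probe - 2 * spacing
  hi <- apply(xyz + rad, 2, max) + probe + 2 * spacing
  dims <- ceiling((hi - lo) / spacing) + 1L
  gx <- lo[1] + (0:(dims[1] - 1)) * spacing
  gy <- lo[2] + (0:(dims[2] - 1)) * spacing
  gz <- lo[3] + (0:(dims[3] - 1)) * spacing
  field <- array(Inf, dim = dims)
  for (i in seq_len(nrow(a))) {
    dx2 <- (gx - xyz[i, 1])^2; dy2 <- (gy - xyz[i, 2])^2; dz2 <- (gz - xyz[i, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - rad[i] - probe
    field <- pmin(field, d)
  }
  mesh <- marching_tetrahedra(field, level = -probe, origin = lo, spacing = spacing)
  if (nrow(mesh$vertices) > 0) {
    pot <- interp_potential(grid, mesh$vertices)
    mesh$potential <- pot
    mesh$potential_clamped <- pmin(pmax(pot, scale_bounds[1]), scale_bounds[2])
    mesh$scale_bounds <- scale_bounds
  }
  mesh
}

#' Isopotential surfaces at given levels
#'
#' @param grid solved `grid_potential`.
#' @param levels isovalues in kT/e (default -10 and +10).
#' @return named list of `surface_mesh`, one per level; a level outside the
#'   grid's value range yields an empty mesh with a warning.
#' @export
isopotential_surfaces <- function(grid, levels = c(-10, 10)) {
  out <- list()
  for (lv in levels) {
    if (lv <= min(grid$values) || lv >= max(grid$values)) {
      warn(sprintf("isopotential level %g kT/e outside grid range [%.3g, %.3g]",
                   lv, min(grid$values), max(grid$values)))
      m <- structure(list(vertices = matrix(numeric(0), 0, 3),
                          faces = matrix(integer(0), 0, 3), level = lv),
                     class = "surface_mesh")
    } else {
      m <- marching_tetrahedra(grid$values, level = lv,
                               origin = grid$origin, spacing = grid$spacing)
    }
    out[[sprintf("%+g kT/e", lv)]] <- m
  }
  out
}

#' Write a grid potential in OpenDX scalar format
#' @param grid a `grid_potential`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  hdr <- c(
    "# OpenDX scalar field (potential, kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.0 0.0", grid$spacing),
    sprintf("delta 0.0 %.6e 0.0", grid$spacing),
    sprintf("delta 0.0 0.0 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  )
  # OpenDX stores with z fastest
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))
  pad <- c(vals, rep(NA, (3 - length(vals) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  body <- apply(m, 1, function(r) paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(c(hdr, body,
               'attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), path)
  invisible(path)
}

#' Write charges and radii in PQR format
#' @param x assembly or atom tibble (parameters assigned if absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(x, path) {
  a <- as_atoms(x)
  if (!"charge" %in% names(a) || !"vdw" %in% names(a)) a <- assign_params(x)
  lines <- sprintf("ATOM  %5d %-4s %-3s %1s %3d    %8.3f %8.3f %8.3f %7.4f %6.3f",
                   a$serial, a$name, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, a$charge, a$vdw)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
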