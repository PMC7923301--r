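# Construction of residues and peptide chains from internal coordinates.
# Backbone geometry uses canonical bond lengths/angles; side chains are grown
# by NeRF from the templates in params.R. These builders serve both the
# synthetic-fixture generator and the mutagenesis machinery, so a side chain
# rebuilt at the chi angles measured from a template-built residue reproduces
# its coordinates exactly.

BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

#' Build side-chain heavy atoms for one residue
#'
#' @param resname three-letter residue code.
#' @param n,ca,c backbone N, CA, C positions (3-vectors).
#' @param chi chi angles in degrees (length [N_CHI] for the residue; missing
#'   entries take the most probable rotamer).
#' @return tibble with columns name, element, x, y, z (CB first). Empty for GLY.
#' @export
build_sidechain <- function(resname, n, ca, c, chi = NULL) {
  resname <- toupper(resname)
  nchi <- N_CHI[[resname]]
  if (is.null(nchi)) abort(paste0("unsupported residue: ", resname))
  if (resname == "GLY") {
    return(tibble(name = character(), element = character(),
                  x = numeric(), y = numeric(), z = numeric()))
  }
  if (is.null(chi)) chi <- rotamer_library(resname)$rotamer[[1]]
  if (length(chi) < nchi) {
    chi <- c(chi, rotamer_library(resname)$rotamer[[1]][seq(length(chi) + 1, nchi)])
  }
  pos <- list(N = n, CA = ca, C = c)
  # CB from the L-amino-acid improper C-N-CA-CB
  pos$CB <- place_atom(c, n, ca, 1.530, 110.5, 122.5)
  out <- list(tibble(name = "CB", element = "C",
                     x = pos$CB[1], y = pos$CB[2], z = pos$CB[3]))
  zm <- sidechain_zmat()
  zm <- zm[zm$resname == resname, , drop = FALSE]
  sc <- sidechain_def()
  elems <- stats::setNames(sc$element[sc$resname == resname],
                           sc$name[sc$resname == resname])
  for (i in seq_len(nrow(zm))) {
    row <- zm[i, ]
    dih <- if (row$chi_idx == 0) row$offset else chi[row$chi_idx] + row$offset
    p <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                    row$bond, row$angle, dih)
    pos[[row$name]] <- p
    out[[length(out) + 1]] <- tibble(name = row$name,
                                     element = unname(elems[row$name]),
                                     x = p[1], y = p[2], z = p[3])
  }
  dplyr::bind_rows(out)
}

#' Build a peptide chain from a sequence and backbone dihedrals
#'
#' @param sequence one-letter amino-acid string (e.g. "AAQAA").
#' @param phi,psi backbone dihedrals in degrees, recycled over residues.
#'   Defaults are ideal alpha-helix values.
#' @param chain chain identifier.
#' @param start_resno author number of the first residue.
#' @param chi optional named list: `chi[[as.character(resno)]]` gives chi
#'   angles for that residue (otherwise the most probable rotamer).
#' @return an atom tibble.
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chain = "A",
                          start_resno = 1L, chi = list()) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  nres <- length(seq1)
  if (nres < 1) abort("empty sequence")
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  g <- BB_GEOM
  # seed the first residue's backbone in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- CA1 + g$ca_c * c(cos(deg2rad(180 - g$ang_n_ca_c)),
                         sin(deg2rad(180 - g$ang_n_ca_c)), 0)
  bb <- vector("list", nres)
  bb[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(nres)) {
    if (i > 1) {
      prev <- bb[[i - 1]]
      Ni <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi[i - 1])
      CAi <- place_atom(prev$CA, prev$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
      Ci <- place_atom(prev$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
      bb[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
  }
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    rn <- aa_three(seq1[i])
    b <- bb[[i]]
    # carbonyl O: anti to the next N (trans peptide), psi + 180
    O <- place_atom(b$N, b$CA, b$C, g$c_o, g$ang_ca_c_o, psi[i] + 180)
    at <- tibble(name = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"),
                 x = c(b$N[1], b$CA[1], b$C[1], O[1]),
                 y = c(b$N[2], b$CA[2], b$C[2], O[2]),
                 z = c(b$N[3], b$CA[3], b$C[3], O[3]))
    sc <- build_sidechain(rn, b$N, b$CA, b$C,
                          chi = chi[[as.character(start_resno + i - 1L)]])
    at <- dplyr::bind_rows(at, sc)
    at$resname <- rn
    at$resno <- start_resno + i - 1L
    rows[[i]] <- at
  }
  a <- dplyr::bind_rows(rows)
  atom_table(serial = seq_len(nrow(a)), name = a$name, element = a$element,
             resname = a$resname, chain = chain, resno = a$resno,
             x = a$x, y = a$y, z = a$z)
}

#' Measure the chi angles of a residue in an atom table
#' @param atoms atom tibble containing exactly one residue's atoms.
#' @return numeric vector of chi angles in degrees (length N_CHI).
#' @export
measure_chi <- function(atoms) {
  rn <- atoms$resname[1]
  nchi <- N_CHI[[rn]]
  if (is.null(nchi) || nchi == 0) return(numeric(0))
  slot <- CHI_SLOT[[rn]]
  getp <- function(nm) {
    nm <- if (nm %in% names(slot)) slot[[nm]] else nm
    r <- atoms[atoms$name == nm, ]
    if (nrow(r) != 1) abort(paste0("atom ", nm, " not found for chi measurement"))
    c(r$x, r$y, r$z)
  }
  vapply(seq_len(nchi), function(k) {
    defs <- CHI_ATOMS[[k]]
    dihedral_deg(getp(defs[1]), getp(defs[2]), getp(defs[3]), getp(defs[4]))
  }, numeric(1))
}

#' Build an extended capped Gly-X-Gly tripeptide
#'
#' The unfolded-state reference used by the folding thermodynamic cycle: the
#' residue of interest flanked by glycines in an extended conformation. All
#' terms not local to X cancel in mutant-minus-wild-type differences.
#'
#' @param aa1 one-letter code of the central residue.
#' @param chi optional chi angles for the central residue.
#' @return an `assembly` of kind "protomer".
#' @export
build_gxg <- function(aa1, chi = NULL) {
  chil <- list()
  if (!is.null(chi)) chil[["2"]] <- chi
  at <- build_peptide(paste0("G", aa1, "G"), phi = -140, psi = 140,
                      chain = "A", start_resno = 1L, chi = chil)
  new_assembly(at, kind = "protomer", info = list(reference = "gxg"))
}
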