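# Embedded parameter set for the package's coarse united-atom protein model:
# per-residue heavy-atom charges (implicit hydrogens folded into the parent
# heavy atom), element Lennard-Jones and vdW radii, generalized-Born screening
# factors, side-chain internal-coordinate templates and a compact
# backbone-independent rotamer library. The set is deliberately simple — a
# fixed-charge model adequate for comparative (apparent) free-energy
# differences between compositions of the same assembly, not for absolute
# energetics.

ELEC_CONST <- 332.0637   # kcal * Angstrom / (mol * e^2)
KT_KCAL <- 0.0019872041 * 298  # kT at 298 K in kcal/mol
KTE_PER_EA <- ELEC_CONST / KT_KCAL  # converts potential in e/Angstrom to kT/e

# element -> vdW radius (A), LJ Rmin/2 (A), LJ epsilon (kcal/mol), GB screen
ELEMENT_PARAMS <- function() {
  tibble(
    element = c("C", "N", "O", "S", "H", "P"),
    vdw     = c(1.70, 1.55, 1.52, 1.80, 1.20, 1.80),
    lj_rmin2 = c(1.908, 1.824, 1.661, 2.000, 0.600, 2.100),
    lj_eps  = c(0.086, 0.170, 0.210, 0.250, 0.0157, 0.200),
    gb_screen = c(0.72, 0.79, 0.85, 0.96, 0.85, 0.86)
  )
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# backbone charges sum to zero per residue; amide/alpha hydrogens implicit
backbone_charge <- c(N = -0.25, CA = 0.25, C = 0.50, O = -0.50)
backbone_nh <- c(N = 1, CA = 1, C = 0, O = 0)

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Convert between 1- and 3-letter amino-acid codes
#' @param x character vector of codes.
#' @return converted codes.
#' @export
aa_three <- function(x) {
  out <- unname(AA3[toupper(x)])
  if (any(is.na(out))) abort(paste0("unknown amino acid code: ",
                                    paste(x[is.na(out)], collapse = ",")))
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  inv <- stats::setNames(names(AA3), AA3)
  out <- unname(inv[toupper(x)])
  if (any(is.na(out))) abort(paste0("unknown residue name: ",
                                    paste(x[is.na(out)], collapse = ",")))
  out
}

# side-chain heavy atoms: name, element, charge, implicit H count, sp2 flag
sidechain_def <- function() {
  L <- list(
    ALA = list(c("CB","C", 0.00,3,0)),
    SER = list(c("CB","C", 0.25,2,0), c("OG","O",-0.25,1,0)),
    CYS = list(c("CB","C", 0.15,2,0), c("SG","S",-0.15,1,0)),
    THR = list(c("CB","C", 0.25,1,0), c("OG1","O",-0.30,1,0), c("CG2","C",0.05,3,0)),
    VAL = list(c("CB","C",0,1,0), c("CG1","C",0,3,0), c("CG2","C",0,3,0)),
    LEU = list(c("CB","C",0,2,0), c("CG","C",0,1,0), c("CD1","C",0,3,0), c("CD2","C",0,3,0)),
    ILE = list(c("CB","C",0,1,0), c("CG1","C",0,2,0), c("CG2","C",0,3,0), c("CD1","C",0,3,0)),
    MET = list(c("CB","C",0,2,0), c("CG","C",0.05,2,0), c("SD","S",-0.10,0,0), c("CE","C",0.05,3,0)),
    PHE = list(c("CB","C",0,2,0), c("CG","C",0,0,1), c("CD1","C",0,1,1), c("CD2","C",0,1,1),
               c("CE1","C",0,1,1), c("CE2","C",0,1,1), c("CZ","C",0,1,1)),
    TYR = list(c("CB","C",0,2,0), c("CG","C",0,0,1), c("CD1","C",0,1,1), c("CD2","C",0,1,1),
               c("CE1","C",0,1,1), c("CE2","C",0,1,1), c("CZ","C",0.25,0,1), c("OH","O",-0.25,1,0)),
    TRP = list(c("CB","C",0,2,0), c("CG","C",0,0,1), c("CD1","C",0.10,1,1), c("CD2","C",0,0,1),
               c("NE1","N",-0.20,1,1), c("CE2","C",0.10,0,1), c("CE3","C",0,1,1),
               c("CZ2","C",0,1,1), c("CZ3","C",0,1,1), c("CH2","C",0,1,1)),
    ASP = list(c("CB","C",-0.10,2,0), c("CG","C",0.30,0,1), c("OD1","O",-0.60,0,1), c("OD2","O",-0.60,0,1)),
    GLU = list(c("CB","C",0,2,0), c("CG","C",-0.10,2,0), c("CD","C",0.30,0,1),
               c("OE1","O",-0.60,0,1), c("OE2","O",-0.60,0,1)),
    ASN = list(c("CB","C",0,2,0), c("CG","C",0.55,0,1), c("OD1","O",-0.55,0,1), c("ND2","N",0.00,2,1)),
    GLN = list(c("CB","C",0,2,0), c("CG","C",0,2,0), c("CD","C",0.55,0,1),
               c("OE1","O",-0.55,0,1), c("NE2","N",0.00,2,1)),
    LYS = list(c("CB","C",0,2,0), c("CG","C",0,2,0), c("CD","C",0.15,2,0),
               c("CE","C",0.25,2,0), c("NZ","N",0.60,3,0)),
    ARG = list(c("CB","C",0,2,0), c("CG","C",0,2,0), c("CD","C",0.10,2,0),
               c("NE","N",-0.10,1,1), c("CZ","C",0.50,0,1), c("NH1","N",0.25,2,1), c("NH2","N",0.25,2,1)),
    HIS = list(c("CB","C",0,2,0), c("CG","C",0.10,0,1), c("ND1","N",-0.40,0,1),
               c("CD2","C",0.10,1,1), c("CE1","C",0.35,1,1), c("NE2","N",-0.15,1,1)),
    PRO = list(c("CB","C",0,2,0), c("CG","C",0,2,0), c("CD","C",0.10,2,0)),
    GLY = list()
  )
  purrr::map_dfr(names(L), function(rn) {
    rows <- L[[rn]]
    if (length(rows) == 0) return(tibble())
    m <- do.call(rbind, rows)
    tibble(resname = rn, name = m[, 1], element = m[, 2],
           charge = as.numeric(m[, 3]), n_h = as.integer(m[, 4]),
           sp2 = as.logical(as.integer(m[, 5])))
  })
}

# full residue topology: backbone + side chain
residue_params_table <- function() {
  bb <- purrr::map_dfr(names(AA3), function(one) {
    rn <- AA3[[one]]
    tibble(resname = rn, name = BACKBONE_ATOMS,
           element = c("N", "C", "C", "O"),
           charge = unname(backbone_charge[BACKBONE_ATOMS]),
           n_h = unname(backbone_nh[BACKBONE_ATOMS]),
           sp2 = c(TRUE, FALSE, TRUE, TRUE))
  })
  bb$n_h[bb$resname == "GLY" & bb$name == "CA"] <- 2L
  bb$n_h[bb$resname == "PRO" & bb$name == "N"] <- 0L
  dplyr::bind_rows(bb, sidechain_def())
}

.param_env <- new.env(parent = emptyenv())

residue_params <- function() {
  if (is.null(.param_env$res)) .param_env$res <- residue_params_table()
  .param_env$res
}

element_params <- function() {
  if (is.null(.param_env$ele)) .param_env$ele <- ELEMENT_PARAMS()
  .param_env$ele
}

# side-chain construction templates (NeRF): each atom placed from references
# a-b-c with bond c-d, angle b-c-d, dihedral a-b-c-d = chi[chi_idx] + offset
# (chi_idx 0 means a fixed dihedral equal to offset). CB is placed first from
# (C, N, CA) with the L-amino-acid improper.
sidechain_zmat <- function() {
  z <- function(res, atom, a, b, c, bond, angle, chi, off)
    tibble(resname = res, name = atom, a = a, b = b, c = c,
           bond = bond, angle = angle, chi_idx = as.integer(chi), offset = off)
  dplyr::bind_rows(
    z("SER","OG","N","CA","CB",1.417,110.8,1,0),
    z("CYS","SG","N","CA","CB",1.808,113.8,1,0),
    z("THR","OG1","N","CA","CB",1.433,109.6,1,0),
    z("THR","CG2","N","CA","CB",1.521,110.5,1,-120),
    z("VAL","CG1","N","CA","CB",1.527,110.5,1,0),
    z("VAL","CG2","N","CA","CB",1.527,110.5,1,120),
    z("LEU","CG","N","CA","CB",1.530,116.3,1,0),
    z("LEU","CD1","CA","CB","CG",1.524,110.7,2,0),
    z("LEU","CD2","CA","CB","CG",1.525,110.7,2,120),
    z("ILE","CG1","N","CA","CB",1.530,110.4,1,0),
    z("ILE","CG2","N","CA","CB",1.521,110.5,1,-120),
    z("ILE","CD1","CA","CB","CG1",1.513,113.8,2,0),
    z("MET","CG","N","CA","CB",1.520,114.0,1,0),
    z("MET","SD","CA","CB","CG",1.803,112.7,2,0),
    z("MET","CE","CB","CG","SD",1.791,100.9,3,0),
    z("ASP","CG","N","CA","CB",1.516,112.6,1,0),
    z("ASP","OD1","CA","CB","CG",1.250,118.4,2,0),
    z("ASP","OD2","CA","CB","CG",1.250,118.4,2,180),
    z("ASN","CG","N","CA","CB",1.516,112.6,1,0),
    z("ASN","OD1","CA","CB","CG",1.231,120.8,2,0),
    z("ASN","ND2","CA","CB","CG",1.328,116.4,2,180),
    z("GLU","CG","N","CA","CB",1.520,114.1,1,0),
    z("GLU","CD","CA","CB","CG",1.516,112.6,2,0),
    z("GLU","OE1","CB","CG","CD",1.250,118.4,3,0),
    z("GLU","OE2","CB","CG","CD",1.250,118.4,3,180),
    z("GLN","CG","N","CA","CB",1.520,114.1,1,0),
    z("GLN","CD","CA","CB","CG",1.516,112.6,2,0),
    z("GLN","OE1","CB","CG","CD",1.231,120.8,3,0),
    z("GLN","NE2","CB","CG","CD",1.328,116.4,3,180),
    z("LYS","CG","N","CA","CB",1.520,114.1,1,0),
    z("LYS","CD","CA","CB","CG",1.520,111.3,2,0),
    z("LYS","CE","CB","CG","CD",1.520,111.3,3,0),
    z("LYS","NZ","CG","CD","CE",1.489,111.9,4,0),
    z("ARG","CG","N","CA","CB",1.520,114.1,1,0),
    z("ARG","CD","CA","CB","CG",1.520,111.3,2,0),
    z("ARG","NE","CB","CG","CD",1.461,112.0,3,0),
    z("ARG","CZ","CG","CD","NE",1.329,124.2,4,0),
    z("ARG","NH1","CD","NE","CZ",1.326,120.0,0,0),
    z("ARG","NH2","CD","NE","CZ",1.326,120.0,0,180),
    z("HIS","CG","N","CA","CB",1.504,113.8,1,0),
    z("HIS","ND1","CA","CB","CG",1.378,122.7,2,0),
    z("HIS","CD2","CA","CB","CG",1.354,131.2,2,180),
    z("HIS","CE1","CB","CG","ND1",1.321,109.3,0,180),
    z("HIS","NE2","CG","ND1","CE1",1.321,108.4,0,0),
    z("PHE","CG","N","CA","CB",1.510,113.8,1,0),
    z("PHE","CD1","CA","CB","CG",1.390,120.8,2,0),
    z("PHE","CD2","CA","CB","CG",1.390,120.8,2,180),
    z("PHE","CE1","CB","CG","CD1",1.390,120.8,0,180),
    z("PHE","CE2","CB","CG","CD2",1.390,120.8,0,180),
    z("PHE","CZ","CG","CD1","CE1",1.390,120.0,0,0),
    z("TYR","CG","N","CA","CB",1.510,113.8,1,0),
    z("TYR","CD1","CA","CB","CG",1.390,120.8,2,0),
    z("TYR","CD2","CA","CB","CG",1.390,120.8,2,180),
    z("TYR","CE1","CB","CG","CD1",1.390,120.8,0,180),
    z("TYR","CE2","CB","CG","CD2",1.390,120.8,0,180),
    z("TYR","CZ","CG","CD1","CE1",1.390,120.0,0,0),
    z("TYR","OH","CD1","CE1","CZ",1.376,120.0,0,180),
    z("TRP","CG","N","CA","CB",1.498,113.6,1,0),
    z("TRP","CD1","CA","CB","CG",1.365,126.9,2,0),
    z("TRP","CD2","CA","CB","CG",1.433,126.8,2,180),
    z("TRP","NE1","CB","CG","CD1",1.374,110.2,0,180),
    z("TRP","CE2","CB","CG","CD2",1.409,107.2,0,180),
    z("TRP","CE3","CB","CG","CD2",1.398,133.9,0,0),
    z("TRP","CZ2","CG","CD2","CE2",1.394,122.4,0,180),
    z("TRP","CZ3","CG","CD2","CE3",1.382,118.8,0,180),
    z("TRP","CH2","CD2","CE2","CZ2",1.400,117.5,0,0),
    z("PRO","CG","N","CA","CB",1.495,104.5,1,0),
    z("PRO","CD","CA","CB","CG",1.507,106.1,2,0)
  )
}

# extra ring-closure / special bonds not implied by the z-matrix parent chain
RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")), TYR = list(c("CE2", "CZ")),
  HIS = list(c("NE2", "CD2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

CLOSURE_BOND_LENGTHS <- c("CE2-CZ" = 1.39, "NE2-CD2" = 1.37, "NE1-CE2" = 1.37,
                          "CZ3-CH2" = 1.40, "CD-N" = 1.473)

# number of chi angles per residue type
N_CHI <- c(ALA = 0, GLY = 0, SER = 1, CYS = 1, THR = 1, VAL = 1,
           LEU = 2, ILE = 2, ASP = 2, ASN = 2, HIS = 2, PHE = 2, TYR = 2,
           TRP = 2, PRO = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4)

# chi atoms defining measured dihedrals, chi1..chi4 (subset per residue)
CHI_ATOMS <- list(
  chi1 = c("N", "CA", "CB", "G"),
  chi2 = c("CA", "CB", "G", "D"),
  chi3 = c("CB", "G", "D", "E"),
  chi4 = c("G", "D", "E", "Z")
)
# per-residue mapping of the generic G/D/E/Z slots to atom names
CHI_SLOT <- list(
  SER = c(G = "OG"), CYS = c(G = "SG"), THR = c(G = "OG1"), VAL = c(G = "CG1"),
  LEU = c(G = "CG", D = "CD1"), ILE = c(G = "CG1", D = "CD1"),
  ASP = c(G = "CG", D = "OD1"), ASN = c(G = "CG", D = "OD1"),
  HIS = c(G = "CG", D = "ND1"), PHE = c(G = "CG", D = "CD1"),
  TYR = c(G = "CG", D = "CD1"), TRP = c(G = "CG", D = "CD1"),
  PRO = c(G = "CG", D = "CD"),
  MET = c(G = "CG", D = "SD", E = "CE"),
  GLU = c(G = "CG", D = "CD", E = "OE1"),
  GLN = c(G = "CG", D = "CD", E = "OE1"),
  LYS = c(G = "CG", D = "CD", E = "CE", Z = "NZ"),
  ARG = c(G = "CG", D = "CD", E = "NE", Z = "CZ")
)

# coarse backbone-independent rotamer options per chi position
rotamer_chi_options <- function(resname, chi_pos) {
  sp3 <- list(vals = c(-60, 180, 60), probs = c(0.52, 0.33, 0.15))
  sp3_t <- list(vals = c(180, -60, 60), probs = c(0.60, 0.25, 0.15))
  aromatic <- list(vals = c(90, -90), probs = c(0.5, 0.5))
  sp2_term <- list(vals = c(0, 90, -90), probs = c(0.40, 0.30, 0.30))
  if (resname == "PRO") return(list(vals = c(25, -25), probs = c(0.5, 0.5)))
  if (chi_pos == 1) return(sp3)
  if (resname %in% c("PHE", "TYR", "TRP", "HIS") && chi_pos == 2) return(aromatic)
  if (resname %in% c("ASP", "ASN") && chi_pos == 2) return(sp2_term)
  if (resname %in% c("GLU", "GLN") && chi_pos == 3) return(sp2_term)
  sp3_t
}

#' Backbone-independent rotamer library for one residue type
#'
#' Expands per-chi canonical options into full rotamers with product
#' frequencies (normalized), sorted by decreasing probability with
#' lexicographic chi order as the deterministic tie-break.
#'
#' @param resname three-letter residue code.
#' @return tibble with columns `rotamer` (list of chi vectors, degrees) and
#'   `probability`.
#' @export
rotamer_library <- function(resname) {
  resname <- toupper(resname)
  nchi <- N_CHI[[resname]]
  if (is.null(nchi)) abort(paste0("no rotamer template for ", resname))
  if (nchi == 0) {
    return(tibble(rotamer = list(numeric(0)), probability = 1))
  }
  if (resname == "PRO") {
    return(tibble(rotamer = list(c(25, -35), c(-25, 35)),
                  probability = c(0.5, 0.5)))
  }
  opts <- lapply(seq_len(nchi), function(k) rotamer_chi_options(resname, k))
  grids <- expand.grid(lapply(opts, function(o) seq_along(o$vals)))
  chis <- lapply(seq_len(nrow(grids)), function(i) {
    vapply(seq_len(nchi), function(k) opts[[k]]$vals[grids[i, k]], numeric(1))
  })
  probs <- vapply(seq_len(nrow(grids)), function(i) {
    prod(vapply(seq_len(nchi), function(k) opts[[k]]$probs[grids[i, k]], numeric(1)))
  }, numeric(1))
  probs <- probs / sum(probs)
  key <- vapply(chis, function(v) paste(sprintf("%08.3f", v + 360), collapse = ","), character(1))
  ord <- order(-probs, key)
  tibble(rotamer = chis[ord], probability = probs[ord])
}

# theoretical maximum SASA per residue (A^2), for relative burial
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
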