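#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n distinct pull across all_of
#' @importFrom rlang .data abort warn
NULL

ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resno",
               "ins", "x", "y", "z", "occ", "b", "hetero")

#' Construct an atom table
#'
#' The package's elementary record is one row per atom: serial number, atom
#' name, element, residue name, chain identifier, author residue number,
#' insertion code, Cartesian coordinates in Angstrom, occupancy, B-factor and
#' a HETATM flag. Author residue numbering is preserved throughout so that a
#' residue printed as, say, 180 in the source structure is addressable as 180.
#'
#' @param serial integer atom serial numbers.
#' @param name atom name (PDB convention, e.g. "CA", "OE1").
#' @param element element symbol ("C", "N", "O", "S", ...).
#' @param resname three-letter residue code.
#' @param chain chain identifier (single character).
#' @param resno author residue number.
#' @param ins insertion code ("" if none).
#' @param x,y,z coordinates in Angstrom.
#' @param occ occupancy.
#' @param b isotropic B-factor (Angstrom^2).
#' @param hetero logical, TRUE for HETATM records.
#' @return a tibble with one row per atom.
#' @export
atom_table <- function(serial = integer(), name = character(),
                       element = character(), resname = character(),
                       chain = character(), resno = integer(),
                       ins = "", x = numeric(), y = numeric(), z = numeric(),
                       occ = 1, b = 0, hetero = FALSE) {
  tb <- tibble(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), resname = as.character(resname),
    chain = as.character(chain), resno = as.integer(resno),
    ins = as.character(ins), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), occ = as.numeric(occ), b = as.numeric(b),
    hetero = as.logical(hetero)
  )
  validate_atoms(tb)
  tb
}

validate_atoms <- function(atoms) {
  miss <- setdiff(ATOM_COLS, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      abort("atom coordinates must be finite")
    }
    if (any(!nzchar(atoms$element))) abort("element symbols must be non-empty")
  }
  invisible(atoms)
}

#' Create an assembly
#'
#' An assembly bundles an atom table with its oligomeric kind and the
#' provenance of how it was built (symmetry operators applied, superposition
#' transforms, fixture metadata). A `trimer` must contain exactly three
#' protomers (chains); a `hexamer` exactly six, understood as two trimer
#' groups (protomers 1-3 and 4-6).
#'
#' @param atoms an atom tibble (see [atom_table()]).
#' @param kind one of "protomer", "trimer", "hexamer", "toy".
#' @param provenance list of transforms/operators applied during construction.
#' @param info free-form metadata list (fixture ground truth, charges, ...).
#' @return an object of class `assembly`.
#' @export
new_assembly <- function(atoms, kind = c("protomer", "trimer", "hexamer", "toy"),
                         provenance = list(), info = list()) {
  kind <- match.arg(kind)
  validate_atoms(atoms)
  nch <- length(unique(atoms$chain[!atoms$hetero]))
  if (kind == "trimer" && nch != 3) {
    abort(sprintf("a trimer assembly needs exactly 3 protomer chains, found %d", nch))
  }
  if (kind == "hexamer" && nch != 6) {
    abort(sprintf("a hexamer assembly needs exactly 6 protomer chains, found %d", nch))
  }
  structure(list(atoms = as_tibble(atoms), kind = kind,
                 provenance = provenance, info = info),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  ch <- unique(x$atoms$chain[!x$atoms$hetero])
  cat(sprintf("<assembly: %s> %d atoms, %d chain(s) [%s], %d residues\n",
              x$kind, nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              nrow(residue_table(x$atoms))))
  invisible(x)
}

is_assembly <- function(x) inherits(x, "assembly")

as_atoms <- function(x) {
  if (is_assembly(x)) x$atoms else as_tibble(x)
}

#' Coordinates of an atom table as an n x 3 matrix
#' @param x an assembly or atom tibble.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x) {
  a <- as_atoms(x)
  cbind(x = a$x, y = a$y, z = a$z)
}

set_coords <- function(x, xyz) {
  if (is_assembly(x)) {
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    x
  } else {
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  }
}

#' Split an assembly's protein chains into protomers
#' @param x an assembly or atom tibble.
#' @return named list of atom tibbles, one per chain, in chain order.
#' @export
protomers <- function(x) {
  a <- as_atoms(x)
  a <- a[!a$hetero, , drop = FALSE]
  split(a, factor(a$chain, levels = unique(a$chain)))
}

#' One row per residue of an atom table
#' @param x an assembly or atom tibble.
#' @return tibble with chain, resno, ins, resname and atom counts.
#' @export
residue_table <- function(x) {
  a <- as_atoms(x)
  a %>%
    filter(!.data$hetero) %>%
    group_by(.data$chain, .data$resno, .data$ins, .data$resname) %>%
    summarise(n_atoms = n(), .groups = "drop") %>%
    arrange(.data$chain, .data$resno, .data$ins)
}

#' Select the atoms of one residue
#' @param x assembly or atom tibble.
#' @param chain chain id.
#' @param resno author residue number.
#' @return logical vector over the rows of the atom table.
#' @export
residue_mask <- function(x, chain, resno) {
  a <- as_atoms(x)
  a$chain == chain & a$resno == resno & !a$hetero
}

renumber_serials <- function(atoms) {
  atoms$serial <- seq_len(nrow(atoms))
  atoms
}

#' Heavy-atom mask (non-hydrogen)
#' @param x assembly or atom tibble.
#' @return logical vector.
#' @export
heavy_mask <- function(x) {
  a <- as_atoms(x)
  a$element != "H"
}

is_water <- function(atoms) atoms$resname %in% c("HOH", "WAT", "TIP3", "SOL")

#' Root-mean-square deviation between two coordinate sets
#' @param a,b n x 3 coordinate matrices (same n), or assemblies/atom tibbles.
#' @param fit if TRUE, superpose b onto a first.
#' @return RMSD in Angstrom.
#' @export
rmsd_xyz <- function(a, b, fit = FALSE) {
  if (!is.matrix(a)) a <- coords(a)
  if (!is.matrix(b)) b <- coords(b)
  stopifnot(nrow(a) == nrow(b))
  if (fit) {
    tr <- kabsch(b, a)
    b <- transform_xyz(b, tr)
  }
  sqrt(mean(rowSums((a - b)^2)))
}
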