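# Protein preparation: water pruning, rule-based protonation at a target pH,
# implicit-hydrogen bookkeeping and displacement-capped minimization.
# Empirical pKa-shift prediction is out of scope: at pH 7.5 the rules below
# reproduce the standard states (Asp/Glu deprotonated, Lys/Arg protonated,
# Cys thiol unless disulfide-bonded, His neutral with the tautomer that
# maximizes local hydrogen bonding). A config hook accepts externally
# supplied per-residue pKa values for the ionizable types.

#' Prune waters that touch only other waters
#'
#' A water is deleted iff every non-water heavy atom is farther than
#' `cutoff` from its oxygen — i.e. its only neighbors within the cutoff are
#' waters or nothing. Deletion is decided on the original structure and then
#' applied simultaneously, so a chain of mutually close waters away from the
#' protein is removed whole. Order-independent.
#'
#' @param assembly an assembly.
#' @param cutoff neighbor cutoff in Angstrom.
#' @return list with `assembly` (pruned) and `deleted` (water count removed).
#' @export
prune_waters <- function(assembly, cutoff = 3.5) {
  atoms <- as_atoms(assembly)
  wat <- is_water(atoms)
  watO <- wat & atoms$element == "O"
  if (!any(watO)) return(list(assembly = assembly, deleted = 0L))
  solute <- !wat & atoms$element != "H"
  drop_water <- rep(FALSE, sum(watO))
  if (any(solute)) {
    D <- dist_xyz(coords(atoms[watO, ]), coords(atoms[solute, ]))
    drop_water <- apply(D, 1, min) > cutoff
  } else {
    drop_water <- rep(TRUE, sum(watO))
  }
  okey <- paste(atoms$chain, atoms$resno, atoms$ins)[watO]
  dropped_res <- okey[drop_water]
  keep <- !(wat & paste(atoms$chain, atoms$resno, atoms$ins) %in% dropped_res)
  out <- assembly
  out$atoms <- renumber_serials(atoms[keep, ])
  list(assembly = out, deleted = as.integer(sum(drop_water)))
}

IONIZABLE <- c("ASP", "GLU", "LYS", "ARG", "CYS", "HIS")

hbond_partner_count <- function(atoms, pos, need, cutoff = 3.5) {
  # need = "acceptor" (for a donated H) or "donor" (for a lone pair)
  cand <- if (need == "acceptor") {
    atoms$element %in% c("O", "S") |
      (atoms$element == "N" & atoms$n_h == 0)
  } else {
    atoms$element %in% c("N", "O", "S") & atoms$n_h > 0
  }
  if (!any(cand)) return(0L)
  d <- sqrt((atoms$x[cand] - pos[1])^2 + (atoms$y[cand] - pos[2])^2 +
            (atoms$z[cand] - pos[3])^2)
  sum(d > 0.1 & d <= cutoff)
}

#' Assign protonation states at a given pH
#'
#' Rule-based assignment recorded per ionizable residue: Asp/Glu carboxylates
#' deprotonated (-1), Lys/Arg protonated (+1), Cys thiol unless its S-gamma
#' lies within 2.5 Angstrom of another S-gamma (disulfide, no H added), and
#' His neutral with the tautomer (Nd1-H vs Ne2-H) that maximizes the count
#' of geometric hydrogen-bond partners within 3.5 Angstrom — a protonated N
#' needs an acceptor nearby, a bare N a donor. Externally supplied pKa values
#' override the rule for their residue.
#'
#' @param assembly an assembly.
#' @param ph target pH.
#' @param pka optional tibble chain/resno/pka overriding the rules for
#'   Asp/Glu/Lys/Cys/His (state = charged iff pH vs pKa says so).
#' @return list with `assembly` (His tautomer recorded in `info`),
#'   `assignments` (tibble: chain, resno, resname, state, formal_charge) and
#'   `added_hydrogens` (implicit hydrogen count for the protein at this pH).
#' @export
assign_protonation <- function(assembly, ph = 7.5, pka = NULL) {
  atoms <- assign_params(assembly)
  res <- residue_table(atoms)
  nonstd <- !(res$resname %in% residue_params()$resname) &
    !(res$resname %in% c("HOH", "WAT"))
  if (any(nonstd)) {
    warn(paste0("non-standard residues get default templates: ",
                paste(unique(res$resname[nonstd]), collapse = ",")))
  }
  ion <- res[res$resname %in% IONIZABLE, ]
  pka_default <- c(ASP = 3.9, GLU = 4.1, LYS = 10.5, ARG = 12.5,
                   CYS = 8.3, HIS = 6.0)
  sg <- atoms[atoms$name == "SG", ]
  rows <- purrr::map_dfr(seq_len(nrow(ion)), function(i) {
    rn <- ion$resname[i]; ch <- ion$chain[i]; no <- ion$resno[i]
    pk <- pka_default[[rn]]
    if (!is.null(pka)) {
      hit <- pka[pka$chain == ch & pka$resno == no, ]
      if (nrow(hit) == 1) pk <- hit$pka
    }
    state <- NULL; q <- 0
    if (rn %in% c("ASP", "GLU")) {
      if (ph > pk) { state <- "deprotonated"; q <- -1 } else state <- "protonated"
    } else if (rn %in% c("LYS", "ARG")) {
      if (ph < pk) { state <- "protonated"; q <- 1 } else state <- "neutral"
    } else if (rn == "CYS") {
      mySG <- sg[sg$chain == ch & sg$resno == no, ]
      other <- sg[!(sg$chain == ch & sg$resno == no), ]
      ss <- nrow(mySG) == 1 && nrow(other) > 0 &&
        min(dist_xyz(coords(mySG), coords(other))) < 2.5
      state <- if (ss) "disulfide" else if (ph < pk) "thiol" else "thiolate"
      q <- if (identical(state, "thiolate")) -1 else 0
    } else if (rn == "HIS") {
      if (ph < pk) { state <- "protonated"; q <- 1 } else {
        rsel <- atoms$chain == ch & atoms$resno == no
        nd1 <- unlist(atoms[rsel & atoms$name == "ND1", c("x", "y", "z")])
        ne2 <- unlist(atoms[rsel & atoms$name == "NE2", c("x", "y", "z")])
        env <- atoms[!rsel & atoms$element != "H", ]
        # Nd1-H tautomer: Nd1 donates, Ne2 accepts; Ne2-H: vice versa
        hid <- hbond_partner_count(env, nd1, "acceptor") +
          hbond_partner_count(env, ne2, "donor")
        hie <- hbond_partner_count(env, ne2, "acceptor") +
          hbond_partner_count(env, nd1, "donor")
        state <- if (hid > hie) "Nd1-H" else "Ne2-H"
      }
    }
    tibble(chain = ch, resno = no, resname = rn, state = state,
           formal_charge = q)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(chain = character(), resno = integer(),
                   resname = character(), state = character(),
                   formal_charge = numeric())
  }
  prot <- atoms[!atoms$hetero, ]
  n_h <- sum(prot$n_h) - sum(rows$state %in% "disulfide")  # disulfide SG has no H
  out <- assembly
  out$info$protonation <- rows
  list(assembly = out, assignments = rows,
       added_hydrogens = as.integer(n_h))
}

#' Net formal charge of an assembly under the standard pH-7.5 rules
#' @param assembly an assembly.
#' @return integer charge: (#Arg + #Lys) - (#Asp + #Glu) + His adjustments.
#' @export
formal_charge <- function(assembly) {
  pr <- assign_protonation(assembly)
  as.integer(sum(pr$assignments$formal_charge))
}

#' Full preparation pipeline
#'
#' Water pruning, protonation assignment, implicit-hydrogen bookkeeping and
#' displacement-capped minimization, with a machine-readable report.
#'
#' @param assembly an assembly.
#' @param ph target pH.
#' @param water_cutoff water-pruning cutoff (A).
#' @param rmsd_cap heavy-atom displacement cap for minimization (A).
#' @param max_steps minimization iteration budget.
#' @return list with `assembly` (prepared) and `report`, a one-row tibble
#'   (added_hydrogens, deleted_waters, n_ionizable, final_heavy_atom_rmsd,
#'   minimization_steps, energy_initial, energy_final) with the protonation
#'   assignments nested in `protonation`.
#' @export
prepare_structure <- function(assembly, ph = 7.5, water_cutoff = 3.5,
                              rmsd_cap = 0.3, max_steps = 100) {
  pw <- prune_waters(assembly, cutoff = water_cutoff)
  pr <- assign_protonation(pw$assembly, ph = ph)
  mn <- minimize_capped(pr$assembly, rmsd_cap = rmsd_cap, max_steps = max_steps)
  rep <- tibble(
    added_hydrogens = pr$added_hydrogens,
    deleted_waters = pw$deleted,
    n_ionizable = nrow(pr$assignments),
    final_heavy_atom_rmsd = mn$report$final_heavy_atom_rmsd,
    minimization_steps = mn$report$minimization_steps,
    energy_initial = mn$report$energy_initial,
    energy_final = mn$report$energy_final,
    protonation = list(pr$assignments)
  )
  list(assembly = mn$assembly, report = rep)
}
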