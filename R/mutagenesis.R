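# Point mutagenesis by side-chain replacement: the flagged protomers' residue
# at the mutation address is stripped to the backbone and rebuilt as the
# mutant amino acid with the most probable clash-free rotamer from the
# embedded backbone-independent library. Backbone atoms never move here;
# local relaxation is a separate, optional step.

#' Parse a mutation specification
#'
#' @param x either a string "chain:resnum:WT>MUT" (e.g. "A:180:Q>E") or the
#'   individual fields.
#' @param chain,resno,wt,mut individual fields (used when `x` is missing).
#' @return tibble with chain, resno, wt, mut (one-letter codes).
#' @export
mutation_spec <- function(x = NULL, chain = "A", resno = NULL,
                          wt = NULL, mut = NULL) {
  if (!is.null(x)) {
    m <- regmatches(x, regexec("^([A-Za-z0-9]):(\\d+):([A-Z])>([A-Z])$", x))[[1]]
    if (length(m) != 5) abort(paste0("cannot parse mutation spec: ", x))
    chain <- m[2]; resno <- as.integer(m[3]); wt <- m[4]; mut <- m[5]
  }
  if (toupper(wt) == toupper(mut)) abort("wild-type and mutant amino acids must differ")
  tibble(chain = chain, resno = as.integer(resno),
         wt = toupper(wt), mut = toupper(mut))
}

clash_score <- function(sc_xyz, sc_vdw, env_xyz, env_vdw, factor = 0.7) {
  if (nrow(env_xyz) == 0 || nrow(sc_xyz) == 0) return(c(n = 0, score = 0))
  D <- dist_xyz(sc_xyz, env_xyz)
  lim <- factor * outer(sc_vdw, env_vdw, "+")
  ov <- pmax(lim - D, 0)
  c(n = sum(D < lim), score = sum(ov))
}

place_rotamer <- function(resname, bb, chi) {
  n <- unlist(bb[bb$name == "N", c("x", "y", "z")])
  ca <- unlist(bb[bb$name == "CA", c("x", "y", "z")])
  c0 <- unlist(bb[bb$name == "C", c("x", "y", "z")])
  build_sidechain(resname, n, ca, c0, chi = chi)
}

#' Introduce a point substitution into selected protomers
#'
#' Every protomer flagged TRUE in `flags` gets its residue at the mutation
#' address replaced by the mutant amino acid. Rotamers are decided against
#' the shared context (the assembly with all flagged side chains removed), so
#' symmetric environments receive identical rotamers; placements are then
#' applied simultaneously. The highest-probability rotamer without a heavy-
#' atom clash (overlap below 0.7 x summed vdW radii) wins; ties break by
#' lower clash score, then lexicographic chi order (the library order). If no
#' rotamer is clash-free the least-clashing one is used with a warning.
#'
#' @param assembly an assembly.
#' @param flags logical vector, one per protomer (chain order); TRUE =
#'   mutate. May also be a composition row's `flags` entry.
#' @param spec mutation spec from [mutation_spec()]; its residue number is
#'   applied to every flagged protomer. A `wt` mismatch at the address is an
#'   error (guards against numbering drift).
#' @param rotamer optional chi vector forced on all flagged protomers
#'   (used e.g. to revert a mutation with the original side-chain geometry).
#' @return list with `assembly` (mutated) and `rotamers`, a tibble with one
#'   row per mutated protomer: chain, resno, chi (list), probability, clashes.
#' @export
apply_mutation <- function(assembly, flags, spec, rotamer = NULL) {
  stopifnot(is_assembly(assembly))
  prots <- protomers(assembly)
  chains <- names(prots)
  flags <- unlist(flags)
  if (length(flags) != length(chains)) {
    abort(sprintf("composition length %d does not match %d protomers",
                  length(flags), length(chains)))
  }
  if (!any(flags)) {
    return(list(assembly = assembly,
                rotamers = tibble(chain = character(), resno = integer(),
                                  chi = list(), probability = numeric(),
                                  clashes = numeric())))
  }
  mut3 <- aa_three(spec$mut); wt3 <- aa_three(spec$wt)
  atoms <- as_atoms(assembly)
  tgt <- list()
  for (ch in chains[flags]) {
    sel <- atoms$chain == ch & atoms$resno == spec$resno & !atoms$hetero
    if (!any(sel)) abort(sprintf("no residue %d in protomer %s", spec$resno, ch))
    found <- unique(atoms$resname[sel])
    if (!identical(found, wt3)) {
      abort(sprintf("wild-type mismatch at %s:%d: expected %s, found %s",
                    ch, spec$resno, wt3, found))
    }
    tgt[[ch]] <- sel
  }
  side <- !(atoms$name %in% BACKBONE_ATOMS)
  strip <- Reduce(`|`, tgt) & side
  context <- atoms[!strip, ]
  ep <- element_params()
  vdw_of <- function(el) {
    v <- ep$vdw[match(el, ep$element)]
    v[is.na(v)] <- 1.7
    v
  }
  lib <- rotamer_library(mut3)
  if (!is.null(rotamer)) lib <- tibble(rotamer = list(rotamer), probability = NA_real_)
  placements <- list()
  rot_rows <- list()
  for (ch in chains[flags]) {
    res_bb <- context[context$chain == ch & context$resno == spec$resno & !context$hetero, ]
    env <- context[!(context$chain == ch & context$resno == spec$resno), ]
    env <- env[env$element != "H", ]
    env_xyz <- coords(env); env_vdw <- vdw_of(env$element)
    best <- NULL
    for (k in seq_len(nrow(lib))) {
      sc <- place_rotamer(mut3, res_bb, lib$rotamer[[k]])
      cs <- clash_score(as.matrix(sc[, c("x", "y", "z")]), vdw_of(sc$element),
                        env_xyz, env_vdw)
      cand <- list(sc = sc, chi = lib$rotamer[[k]], p = lib$probability[k],
                   n = cs["n"], score = cs["score"])
      if (cs["n"] == 0) { best <- cand; break }
      if (is.null(best) || cs["score"] < best$score) best <- cand
    }
    if (best$n > 0 && is.null(rotamer)) {
      warn(sprintf("no clash-free rotamer for %s at %s:%d; using least-clashing (overlap %.2f A)",
                   mut3, ch, spec$resno, best$score))
    }
    placements[[ch]] <- best
    rot_rows[[ch]] <- tibble(chain = ch, resno = spec$resno,
                             chi = list(best$chi), probability = best$p,
                             clashes = unname(best$score))
  }
  # apply simultaneously
  out <- atoms[!strip, ]
  for (ch in names(placements)) {
    b <- placements[[ch]]
    sel <- out$chain == ch & out$resno == spec$resno & !out$hetero
    out$resname[sel] <- mut3
    idx <- which(sel)
    tmpl <- out[idx[1], ]
    newrows <- purrr::map_dfr(seq_len(nrow(b$sc)), function(i) {
      r <- tmpl
      r$name <- b$sc$name[i]; r$element <- b$sc$element[i]
      r$x <- b$sc$x[i]; r$y <- b$sc$y[i]; r$z <- b$sc$z[i]
      r$resname <- mut3
      r
    })
    out <- dplyr::bind_rows(out[seq_len(max(idx)), ], newrows,
                            out[-seq_len(max(idx)), ])
  }
  out <- renumber_serials(out)
  res <- assembly
  res$atoms <- out
  list(assembly = res, rotamers = dplyr::bind_rows(rot_rows))
}

#' Relax side chains around a residue
#'
#' Minimizes the side-chain atoms of the centered residue and of all residues
#' with a side-chain atom within `radius` of it; every other atom is held
#' fixed. Backbone atoms never move. With `radius = 0` only the centered
#' residue's own side chain relaxes. Energy never increases.
#'
#' @param assembly an assembly.
#' @param chain,resno address of the central (e.g. mutated) residue.
#' @param radius neighborhood radius in Angstrom.
#' @param rmsd_cap heavy-atom displacement cap (A), as in [minimize_capped()].
#' @param max_steps iteration budget.
#' @return list with `assembly` and the minimization `report`.
#' @export
relax_environment <- function(assembly, chain, resno, radius = 5,
                              rmsd_cap = 0.3, max_steps = 100, chunk = 100) {
  atoms <- as_atoms(assembly)
  side <- !(atoms$name %in% BACKBONE_ATOMS) & !atoms$hetero
  ctr <- atoms$chain == chain & atoms$resno == resno & !atoms$hetero
  if (!any(ctr)) abort(sprintf("no residue %s:%d", chain, resno))
  free <- side & ctr
  if (radius > 0) {
    D <- dist_xyz(coords(atoms[side, ]), coords(atoms[ctr, ]))
    near <- rep(FALSE, nrow(atoms))
    near[which(side)[apply(D, 1, min) <= radius]] <- TRUE
    free <- side & (ctr | near)
  }
  minimize_capped(assembly, rmsd_cap = rmsd_cap, max_steps = max_steps,
                  chunk = chunk, free_mask = free)
}
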