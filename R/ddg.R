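# The MM/GBSA thermodynamic cycle over compositions. All quantities are
# "apparent" free-energy differences on fixed structures (single-structure
# convention: separated units keep their complex-geometry coordinates, no
# re-relaxation), so the cycle closes exactly and the all-WT composition is
# identically zero. Each ddG splits into a Coulomb contribution (C), a
# solvation contribution (S = generalized Born polar + SASA nonpolar) and a
# residual (bonded + van der Waals), mirroring the columns of a
# Table-3-style report.

atoms_of_protomers <- function(assembly, idx) {
  a <- as_atoms(assembly)
  chains <- unique(a$chain[!a$hetero])
  which(a$chain %in% chains[idx] & !a$hetero)
}

#' Binding energy of a partition (complex geometry)
#'
#' dG_b = E(complex) - E(left) - E(right), all three scored on the complex
#' coordinates (rigid separation).
#'
#' @param x assembly or prebuilt `ff_system`.
#' @param left,right protomer index sets partitioning the assembly.
#' @param assembly original assembly (needed when `x` is a system).
#' @return one-row tibble of the breakdown components of dG_b.
#' @export
binding_dg <- function(x, left, right, assembly = NULL) {
  if (inherits(x, "ff_system")) {
    sys <- x
    if (is.null(assembly)) abort("assembly required alongside a prebuilt system")
  } else {
    sys <- ff_system(x); assembly <- x
  }
  il <- atoms_of_protomers(assembly, left)
  ir <- atoms_of_protomers(assembly, right)
  if (length(intersect(il, ir)) > 0) abort("pairing units overlap")
  ec <- energy(sys, subset = c(il, ir))
  el <- energy(sys, subset = il)
  er <- energy(sys, subset = ir)
  ec - el - er
}

ddg_columns <- function(d, prefix) {
  out <- tibble(
    app = d$total,
    coulomb = d$coulomb,
    solv = d$gb_polar + d$sa_nonpolar,
    residual = d$bonded + d$vdw
  )
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Apparent binding ddG of a mutant composition
#'
#' ddG_b^app = dG_b(mutant) - dG_b(wild-type) for one evaluation pairing,
#' with the Coulomb/solvation/residual decomposition. Zero (all components)
#' when the mutant is the all-WT composition.
#'
#' @param mut,wt mutant and wild-type assemblies (same pairing applies).
#' @param left,right protomer index sets.
#' @param mut_sys,wt_sys optional prebuilt systems for `mut`/`wt`.
#' @return one-row tibble: ddg_b_app, ddg_b_coulomb, ddg_b_solv,
#'   ddg_b_residual.
#' @export
ddg_bind <- function(mut, wt, left, right, mut_sys = NULL, wt_sys = NULL) {
  dm <- binding_dg(mut_sys %||% mut, left, right, assembly = mut)
  dw <- binding_dg(wt_sys %||% wt, left, right, assembly = wt)
  ddg_columns(dm - dw, "ddg_b")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# energies of the unfolded-state reference (extended capped Gly-X-Gly)
gxg_reference <- function(aa1, solvation = TRUE) {
  g <- build_gxg(aa1)
  energy(g, solvation = solvation)
}

#' Apparent folding ddG of a mutant composition
#'
#' The folded-state term is E(mutant assembly) - E(WT assembly); the
#' unfolded-state reference is an extended Gly-X-Gly tripeptide per mutated
#' residue, whose mutant-minus-WT difference is subtracted once per flagged
#' protomer. Everything not local to the mutation cancels, so the all-WT
#' composition gives exactly zero.
#'
#' @param mut,wt mutant and wild-type assemblies.
#' @param spec mutation spec (defines the WT and mutant residue for the
#'   unfolded reference).
#' @param n_mut number of mutated protomers in `mut`.
#' @param mut_sys,wt_sys optional prebuilt systems.
#' @param gxg optional cached list(wt=, mut=) of reference energies.
#' @return one-row tibble: ddg_f_app, ddg_f_coulomb, ddg_f_solv,
#'   ddg_f_residual.
#' @export
ddg_fold <- function(mut, wt, spec, n_mut, mut_sys = NULL, wt_sys = NULL,
                     gxg = NULL) {
  toy <- is_assembly(wt) && wt$kind == "toy"
  solv <- !toy
  em <- energy(mut_sys %||% ff_system(mut))
  ew <- energy(wt_sys %||% ff_system(wt))
  if (toy) {
    # point-charge systems have no unfolded-state reference: every term not
    # shared between mutant and WT is the charge difference itself
    return(ddg_columns(em - ew, "ddg_f"))
  }
  if (n_mut > 0) {
    if (is.null(gxg)) {
      gxg <- list(wt = gxg_reference(spec$wt, solv),
                  mut = gxg_reference(spec$mut, solv))
    }
    d <- (em - ew) - n_mut * (gxg$mut - gxg$wt)
  } else {
    d <- em - ew   # identically zero
  }
  ddg_columns(d, "ddg_f")
}

#' Composition scan of an assembly
#'
#' Enumerates every non-wild-type composition, applies the mutation to the
#' flagged protomers (optionally relaxing side chains around each site),
#' scores the thermodynamic cycle and returns one record per
#' (composition, pairing). Trimers are evaluated protomer-vs-rest (3 pairings
#' per composition, 21 records); hexamers trimer-vs-trimer (63 records);
#' single protomers give folding records only. The folding ddG of a
#' composition is attached to each of its pairing records, which is the
#' grouping pooled in a Table-3-style report. One mutated structure per
#' composition is built and re-used across its pairings.
#'
#' @param assembly wild-type assembly (protomer, trimer or hexamer fixture,
#'   or a prepared structure).
#' @param spec mutation spec from [mutation_spec()].
#' @param relax relax side chains around each mutated site before scoring.
#' @param relax_radius,relax_steps relaxation controls (see
#'   [relax_environment()]).
#' @return tibble of ddG records with composition labels, mutation counts,
#'   pairing index sets and the six ddG columns plus residuals.
#' @export
scan_compositions <- function(assembly, spec, relax = FALSE,
                              relax_radius = 5, relax_steps = 40) {
  nprot <- length(protomers(assembly))
  if (!nprot %in% c(1, 3, 6)) {
    abort("scan supports protomer (1), trimer (3) or hexamer (6) assemblies")
  }
  comps <- enumerate_compositions(nprot, include_all_wt = FALSE)
  pair <- switch(as.character(nprot),
    "1" = comps %>% mutate(left = list(integer(0)), right = list(integer(0)),
                           mode = "fold_only"),
    "3" = protomer_pairings(comps),
    "6" = trimer_pairings(comps))
  wt_sys <- ff_system(assembly)
  solv <- assembly$kind != "toy"
  gxg <- list(wt = gxg_reference(spec$wt, solv),
              mut = gxg_reference(spec$mut, solv))
  wt_bind_cache <- list()
  records <- purrr::map_dfr(seq_len(nrow(comps)), function(ci) {
    flags <- comps$flags[[ci]]
    mut <- apply_mutation(assembly, flags, spec)$assembly
    if (relax) {
      chains <- names(protomers(assembly))
      for (ch in chains[flags]) {
        mut <- relax_environment(mut, ch, spec$resno, radius = relax_radius,
                                 max_steps = relax_steps)$assembly
      }
    }
    mut_sys <- ff_system(mut)
    fold <- ddg_fold(mut, assembly, spec, n_mut = comps$n_mut[ci],
                     mut_sys = mut_sys, wt_sys = wt_sys, gxg = gxg)
    prs <- pair[pair$composition == comps$composition[ci], ]
    purrr::map_dfr(seq_len(nrow(prs)), function(pi) {
      if (identical(prs$mode[pi], "fold_only")) {
        bind <- tibble(ddg_b_app = NA_real_, ddg_b_coulomb = NA_real_,
                       ddg_b_solv = NA_real_, ddg_b_residual = NA_real_)
      } else {
        key <- paste(prs$left[[pi]], collapse = ",")
        if (is.null(wt_bind_cache[[key]])) {
          wt_bind_cache[[key]] <<- binding_dg(wt_sys, prs$left[[pi]],
                                              prs$right[[pi]], assembly = assembly)
        }
        dm <- binding_dg(mut_sys, prs$left[[pi]], prs$right[[pi]], assembly = mut)
        bind <- ddg_columns(dm - wt_bind_cache[[key]], "ddg_b")
      }
      dplyr::bind_cols(
        tibble(composition = prs$composition[pi], flags = prs$flags[pi],
               n_mut = prs$n_mut[pi], left = prs$left[pi],
               right = prs$right[pi], mode = prs$mode[pi]),
        bind, fold)
    })
  })
  class(records) <- c("ddg_scan", class(records))
  attr(records, "spec") <- spec
  attr(records, "assembly_kind") <- assembly$kind
  records
}

#' Pool scan records by mutation count
#'
#' Mean and sample standard deviation (n-1) of every ddG column, grouped by
#' the number of mutated protomers; the SD of an n = 1 group is reported as
#' absent (NA), matching the convention of printing no SD for a single
#' combination.
#'
#' @param records tibble from [scan_compositions()].
#' @return tibble with one row per mutation count: n_mut, n, then mean/sd
#'   pairs for ddg_b_app, ddg_b_coulomb, ddg_b_solv, ddg_f_app,
#'   ddg_f_coulomb, ddg_f_solv.
#' @export
pool_ddg <- function(records) {
  cols <- c("ddg_b_app", "ddg_b_coulomb", "ddg_b_solv",
            "ddg_f_app", "ddg_f_coulomb", "ddg_f_solv")
  cols <- intersect(cols, names(records))
  g <- group_by_mutation_count(records)
  out <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    d <- g$data[[i]]
    row <- tibble(n_mut = g$n_mut[i], n = g$n[i])
    for (cl in cols) {
      v <- d[[cl]]
      row[[paste0(cl, "_mean")]] <- mean(v)
      row[[paste0(cl, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    row
  })
  class(out) <- c("ddg_pooled", class(out))
  out
}
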