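# Enumeration of wild-type/mutant compositions of an oligomer and the
# pairings over which binding energies are evaluated. For a dominant variant
# every protomer of an assembly independently carries the mutation or not, so
# a trimer has 2^3 - 1 = 7 non-wild-type states and a head-to-head hexamer
# 2^6 - 1 = 63; each trimer state is scored protomer-vs-rest (3 pairings,
# 21 evaluations), each hexamer state trimer-vs-trimer.

composition_label <- function(flags) {
  s <- paste(ifelse(flags, "M", "W"), collapse = "")
  if (length(flags) == 6) s <- paste0(substr(s, 1, 3), "-", substr(s, 4, 6))
  s
}

#' Enumerate WT/mutant compositions of an n-protomer assembly
#'
#' @param n_protomers number of protomers (3 for a trimer, 6 for a hexamer;
#'   any positive n accepted).
#' @param include_all_wt keep the all-wild-type composition?
#' @return tibble with columns `composition` (label, "M" = mutant protomer),
#'   `flags` (list of logical vectors), `n_mut`, `assembly_kind`. Rows are in
#'   deterministic lexicographic order of the flags.
#' @export
enumerate_compositions <- function(n_protomers, include_all_wt = FALSE) {
  if (!is.numeric(n_protomers) || n_protomers < 1) {
    abort("n_protomers must be a positive integer")
  }
  n <- as.integer(n_protomers)
  ids <- 0:(2^n - 1)
  flags <- lapply(ids, function(i) as.logical(bitwAnd(bitwShiftR(i, (n - 1):0), 1L)))
  tb <- tibble(
    composition = vapply(flags, composition_label, character(1)),
    flags = flags,
    n_mut = vapply(flags, sum, numeric(1)),
    assembly_kind = if (n == 3) "trimer" else if (n == 6) "hexamer" else paste0("n", n)
  )
  if (!include_all_wt) tb <- tb[tb$n_mut > 0, ]
  tb
}

#' Protomer-vs-rest evaluation pairings for trimer compositions
#'
#' Each trimer composition is evaluated three times: every protomer against
#' the complementary dimer. Seven non-WT compositions therefore yield 21
#' pairings, pooled downstream by mutation count.
#'
#' @param compositions tibble from [enumerate_compositions()] with 3-protomer
#'   flags (all-WT excluded).
#' @return tibble with one row per (composition, pairing): composition label,
#'   flags, n_mut, `left` and `right` protomer index sets (list columns), and
#'   `mode = "protomer_vs_rest"`.
#' @export
protomer_pairings <- function(compositions) {
  lens <- lengths(compositions$flags)
  if (any(lens != 3)) abort("protomer pairings are defined for trimer compositions")
  if (any(compositions$n_mut == 0)) {
    abort("all-WT composition must be excluded upstream")
  }
  purrr::map_dfr(seq_len(nrow(compositions)), function(r) {
    purrr::map_dfr(1:3, function(p) {
      tibble(composition = compositions$composition[r],
             flags = compositions$flags[r],
             n_mut = compositions$n_mut[r],
             left = list(p), right = list(setdiff(1:3, p)),
             mode = "protomer_vs_rest")
    })
  })
}

#' Trimer-vs-trimer pairings for hexamer compositions
#'
#' @param compositions tibble of 6-protomer compositions.
#' @return one pairing per composition: protomers 1-3 against 4-6.
#' @export
trimer_pairings <- function(compositions) {
  lens <- lengths(compositions$flags)
  if (any(lens != 6)) abort("trimer-vs-trimer pairings need hexamer compositions")
  compositions %>%
    mutate(left = list(1:3), right = list(4:6), mode = "trimer_vs_trimer")
}

#' Group records by mutation count
#'
#' @param records tibble carrying a `flags` list column (or an `n_mut`
#'   column).
#' @return tibble with one row per mutation count: `n_mut`, group size `n`
#'   and the group's rows nested in `data`.
#' @export
group_by_mutation_count <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(n_mut = numeric(), n = integer(), data = list()))
  }
  if (!"n_mut" %in% names(records)) {
    records$n_mut <- vapply(records$flags, sum, numeric(1))
  }
  records %>%
    tidyr::nest(data = -dplyr::all_of("n_mut")) %>%
    mutate(n = vapply(.data$data, nrow, integer(1))) %>%
    select(dplyr::all_of(c("n_mut", "n", "data"))) %>%
    arrange(.data$n_mut)
}

check_permutation_group <- function(perms, n) {
  key <- function(p) paste(p, collapse = ",")
  keys <- vapply(perms, key, character(1))
  if (!key(seq_len(n)) %in% keys) abort("permutations do not include the identity")
  for (p in perms) for (q in perms) {
    if (!key(p[q]) %in% keys) abort("permutations are not closed under composition")
  }
  invisible(TRUE)
}

#' Reduce compositions to orbit representatives under a symmetry group
#'
#' An opt-in accelerator: compositions related by an exact symmetry of the
#' assembly have equal energies, so only one representative per orbit needs
#' scoring. Re-expansion by the returned multiplicities reproduces the full
#' composition multiset.
#'
#' @param compositions tibble from [enumerate_compositions()].
#' @param perms list of integer permutation vectors acting on protomer
#'   indices; must form a group (identity included, closed).
#' @return tibble of orbit representatives with a `multiplicity` column.
#' @export
symmetry_reduce <- function(compositions, perms) {
  n <- length(compositions$flags[[1]])
  check_permutation_group(perms, n)
  canon <- vapply(compositions$flags, function(f) {
    imgs <- vapply(perms, function(p) composition_label(f[p]), character(1))
    min(imgs)
  }, character(1))
  compositions$`.orbit` <- canon
  reps <- compositions %>%
    group_by(.data$.orbit) %>%
    summarise(row = dplyr::first(dplyr::cur_group_rows()),
              multiplicity = n(), .groups = "drop")
  out <- compositions[reps$row, setdiff(names(compositions), ".orbit")]
  out$multiplicity <- reps$multiplicity
  out
}
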