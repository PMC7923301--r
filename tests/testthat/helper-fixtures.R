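# Shared fixtures, built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

fix_trimer <- function() cached("trimer", make_c3_trimer(seed = 1))

fix_surface_trimer <- function() {
  cached("surface", make_c3_trimer(seed = 1, orientation = "surface"))
}

fix_spec <- function() mutation_spec("A:6:Q>E")

fix_trimer_scan <- function() {
  cached("trimer_scan", scan_compositions(fix_trimer(), fix_spec()))
}

fix_surface_scan <- function() {
  cached("surface_scan", scan_compositions(fix_surface_trimer(), fix_spec()))
}

# a 3-residue single-chain peptide used for cheap I/O and prep tests
fix_tripeptide <- function() {
  cached("tripep", new_assembly(build_peptide("AQL", phi = -57, psi = -47),
                                kind = "protomer"))
}

# independent brute-force Coulomb sum (the oracle; deliberately naive)
brute_coulomb <- function(atoms, rows_a, rows_b = NULL) {
  e <- 0
  if (is.null(rows_b)) {
    for (i in rows_a) for (j in rows_a) {
      if (j > i) {
        r <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
        e <- e + 332.0637 * atoms$charge[i] * atoms$charge[j] / r
      }
    }
  } else {
    for (i in rows_a) for (j in rows_b) {
      r <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
      e <- e + 332.0637 * atoms$charge[i] * atoms$charge[j] / r
    }
  }
  e
}

# a toy "hexamer" of point charges in two chains of three
toy_two_trimers <- function(q = c(0.5, -0.3, 0.8, 0.4, -0.6, 0.2)) {
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0),
               c(0, 0, 8), c(4, 0, 8), c(2, 3, 8))
  make_point_charge_cluster(q, pos, chains = rep(c("A", "B"), each = 3))
}
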