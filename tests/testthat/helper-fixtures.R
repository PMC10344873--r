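# Shared synthetic fixtures and independent oracles used across tests.

# toy dimer reused by several files (cheap to rebuild, but cached anyway)
toy_dimer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_complex(fixture_recipe(
        n_residues_per_partner = 3, interface_gap = 4, seed = 1,
        sequence_a = c("ALA", "SER", "GLY"), sequence_b = "ALA"))
    }
    cache
  }
})

# hand-rolled PDB ATOM line (independent of the fixture generator's writer)
pdb_atom_line <- function(serial, name, restype, chain, resnum, x, y, z) {
  sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    serial, sprintf(" %-3s", name), restype, chain, resnum, x, y, z,
    substr(name, 1, 1))
}

# minimal structure: one GLY (CA only) per listed position
point_structure <- function(coords_a, coords_b) {
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(coords_a))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", "A", i,
                                    coords_a[i, 1], coords_a[i, 2],
                                    coords_a[i, 3]))
  }
  for (i in seq_len(nrow(coords_b))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", "B", i,
                                    coords_b[i, 1], coords_b[i, 2],
                                    coords_b[i, 3]))
  }
  read_structure(paste(c(lines, "END"), collapse = "\n"), "A", "B")
}

# Independent all-atom energy oracle: same physics as the package states
# (LJ 12-6 + Coulomb/4r^2, clash cap, intra-residue 1-2/1-3 exclusions)
# but coded as a plain double loop over assembled atoms.
direct_energy_oracle <- function(atoms) {
  n <- nrow(atoms)
  # intra-residue bond graph by distance
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (atoms$site[i] == atoms$site[j]) {
        d <- sqrt(sum((c(atoms$x[i], atoms$y[i], atoms$z[i]) -
                         c(atoms$x[j], atoms$y[j], atoms$z[j]))^2))
        if (d < 1.9) bonded[i, j] <- bonded[j, i] <- TRUE
      }
    }
  }
  one3 <- (bonded %*% bonded) > 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (atoms$site[i] == atoms$site[j] &&
          (bonded[i, j] || one3[i, j])) next
      d <- sqrt(sum((c(atoms$x[i], atoms$y[i], atoms$z[i]) -
                       c(atoms$x[j], atoms$y[j], atoms$z[j]))^2))
      d <- max(d, 1e-6)
      rm_ <- atoms$rmin[i] + atoms$rmin[j]
      if (d < 0.6 * rm_) {
        total <- total + 1000
        next
      }
      eps_ <- sqrt(atoms$eps[i] * atoms$eps[j])
      sr6 <- (rm_ / d)^6
      total <- total + eps_ * (sr6^2 - 2 * sr6) +
        332.0636 * atoms$charge[i] * atoms$charge[j] / (4 * d^2)
    }
  }
  total
}

# assemble the full-atom coordinate set of one assignment of a conf space
assemble_assignment <- function(space, idx) {
  cols <- c("site", "x", "y", "z", "charge", "rmin", "eps")
  parts <- list(space$template[, cols])
  for (i in seq_along(space$positions)) {
    ch <- space$positions[[i]]$choices[[idx[i]]]
    if (nrow(ch$atoms) > 0) {
      a <- ch$atoms
      a$site <- space$positions[[i]]$site
      parts[[length(parts) + 1]] <- a[, cols]
    }
  }
  do.call(rbind, parts)
}

RT_TEST <- 0.0019872 * 298.15

# log10 of the exhaustive Boltzmann sum, computed independently
log10_Z_oracle <- function(m) {
  nc <- vapply(m$singles, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(nc, seq_len)))
  e <- apply(grid, 1, function(idx) {
    tot <- m$template
    for (i in seq_along(idx)) tot <- tot + m$singles[[i]][idx[i]]
    if (length(idx) >= 2) {
      for (i in seq_len(length(idx) - 1)) {
        for (j in (i + 1):length(idx)) {
          tot <- tot + m$pairs[[i]][[j]][idx[i], idx[j]]
        }
      }
    }
    tot
  })
  w <- -e / RT_TEST
  mx <- max(w)
  (mx + log(sum(exp(w - mx)))) / log(10)
}

minimal_job_yaml <- function(extra = "") {
  paste0("structure_path: unused\npartner_a_chains: [A]\n",
         "partner_b_chains: [B]\n", extra)
}
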