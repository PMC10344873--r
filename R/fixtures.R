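# Deterministic synthetic-data generators: toy dimer structures, toy genes
# and toy signature catalogs. These define the study conditions under which
# the protocol is exercised and make every module testable offline.

# run `expr` under a private RNG seed, restoring the caller's RNG state
with_fixture_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Recipe for a synthetic two-chain complex
#'
#' @param n_residues_per_partner residues per chain.
#' @param interface_gap closest heavy-atom distance between the two chains
#'   in Angstrom (default 4, i.e. in contact under the 5 Angstrom interface
#'   criterion).
#' @param seed integer seed controlling the (small) coordinate jitter.
#' @param sequence_a,sequence_b 3-letter residue types per chain, recycled
#'   to length; defaults to poly-alanine so every residue faces its
#'   counterpart at exactly the requested gap.
#' @param perturbed_mutations optional data frame with columns `site`,
#'   `target_aa`, `offset` (kcal/mol added to the mutant complex template
#'   energy) recording which mutations a scan should find disruptive by
#'   construction.
#' @export
fixture_recipe <- function(n_residues_per_partner = 3, interface_gap = 4,
                           seed = 1, sequence_a = "ALA", sequence_b = "ALA",
                           perturbed_mutations = NULL) {
  stopifnot(n_residues_per_partner >= 1, interface_gap > 0)
  if (!is.null(perturbed_mutations)) {
    stopifnot(is.data.frame(perturbed_mutations),
              all(c("site", "target_aa", "offset") %in%
                    names(perturbed_mutations)),
              all(is.finite(perturbed_mutations$offset)))
  }
  structure(list(n_residues_per_partner = n_residues_per_partner,
                 interface_gap = interface_gap, seed = seed,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 perturbed_mutations = perturbed_mutations),
            class = "fixture_recipe")
}

# one residue's heavy atoms (backbone + first-rotamer side chain) in a
# local frame, as a name/x/y/z data frame
ideal_residue_atoms <- function(restype) {
  N <- c(0, 0, 0)
  CA <- c(1.46, 0, 0)
  # angle N-CA-C = 110 deg in the xy-plane
  C <- CA + 1.52 * c(cos(deg2rad(70)), sin(deg2rad(70)), 0)
  O <- place_atom(N, CA, C, 1.23, 120.5, 135)
  bb <- data.frame(name = c("N", "CA", "C", "O"),
                   x = c(N[1], CA[1], C[1], O[1]),
                   y = c(N[2], CA[2], C[2], O[2]),
                   z = c(N[3], CA[3], C[3], O[3]),
                   stringsAsFactors = FALSE)
  if (restype == "GLY") return(bb)
  chis <- rotamers_for(restype)[[1]]
  sc <- build_sidechain(restype, list(N = N, CA = CA, C = C), chis)
  rbind(bb, sc)
}

#' Generate a synthetic two-chain complex in PDB format
#'
#' Builds two short peptide chains (A and B) facing each other: chain A
#' residues spaced 3.8 Angstrom along x, chain B a mirror image across a
#' plane placed so the closest heavy-atom pair sits at exactly the recipe's
#' `interface_gap`. Coordinates get a seeded jitter of a few thousandths of
#' an Angstrom, so the output is byte-reproducible at a fixed seed and
#' distinct across seeds. Ground-truth notes record which residues are
#' interface residues by construction and which mutations carry an
#' injected complex-energy perturbation.
#'
#' @param recipe a [fixture_recipe()].
#' @return list with `pdb_text` (character scalar), `structure` (the parsed
#'   `kstar_structure`), and `ground_truth` (interface sites at the 5
#'   Angstrom criterion and the perturbed mutations).
#' @export
make_toy_complex <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  n <- recipe$n_residues_per_partner
  seq_a <- toupper(rep_len(recipe$sequence_a, n))
  seq_b <- toupper(rep_len(recipe$sequence_b, n))
  build_chain <- function(seqs) {
    parts <- lapply(seq_along(seqs), function(i) {
      a <- ideal_residue_atoms(seqs[i])
      a$x <- a$x + 6.0 * (i - 1L)
      a$resnum <- i
      a$restype <- seqs[i]
      a
    })
    do.call(rbind, parts)
  }
  ca <- build_chain(seq_a)
  cb <- build_chain(seq_b)
  ca$chain <- "A"; cb$chain <- "B"
  # mirror chain B across a y-plane so that the closest approach between
  # the chains equals interface_gap exactly (before jitter)
  ymax_a <- max(ca$y)
  ymax_b <- max(cb$y)
  cb$y <- (ymax_a + ymax_b + recipe$interface_gap) - cb$y
  atoms <- rbind(ca, cb)
  atoms <- with_fixture_seed(recipe$seed, {
    atoms$x <- round(atoms$x + stats::runif(nrow(atoms), -0.002, 0.002), 3)
    atoms$y <- round(atoms$y + stats::runif(nrow(atoms), -0.002, 0.002), 3)
    atoms$z <- round(atoms$z + stats::runif(nrow(atoms), -0.002, 0.002), 3)
    atoms
  })
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, sprintf(" %-3s", a$name), a$restype, a$chain, a$resnum,
      a$x, a$y, a$z, substr(a$name, 1, 1))
  }
  pdb_text <- paste(c(lines, "END"), collapse = "\n")
  s <- read_structure(pdb_text, "A", "B")
  # ground truth by direct double loop over atoms (independent of the
  # vectorised interface detector)
  iface <- character(0)
  for (k in s$sites$site) {
    ak <- s$atoms[s$atoms$site == k, , drop = FALSE]
    opp_chains <- if (ak$chain[1] %in% s$partner_a) s$partner_b else
      s$partner_a
    opp <- s$atoms[s$atoms$chain %in% opp_chains, , drop = FALSE]
    dmin <- Inf
    for (ii in seq_len(nrow(ak))) {
      for (jj in seq_len(nrow(opp))) {
        dd <- sqrt((ak$x[ii] - opp$x[jj])^2 + (ak$y[ii] - opp$y[jj])^2 +
                     (ak$z[ii] - opp$z[jj])^2)
        if (dd < dmin) dmin <- dd
      }
    }
    if (dmin <= 5) iface <- c(iface, k)
  }
  list(pdb_text = pdb_text, structure = s,
       ground_truth = list(interface_sites = iface,
                           perturbed_mutations = recipe$perturbed_mutations),
       recipe = recipe)
}

#' Toy signature catalogs
#'
#' `make_uniform_catalog()` returns a single signature with every one of
#' the 96 substitution classes at exactly 1/96.
#' `make_random_catalog()` draws `n_signatures` random distributions over
#' the 96 classes (normalised exponential variates), reproducible at a
#' fixed seed.
#'
#' @param n_signatures number of signatures.
#' @param seed integer seed.
#' @return matrix `96 x n_signatures` with class row names.
#' @export
make_uniform_catalog <- function() {
  m <- matrix(1 / 96, nrow = 96, ncol = 1,
              dimnames = list(signature_classes(), "UNIFORM"))
  validate_catalog(m)
}

#' @rdname make_uniform_catalog
#' @export
make_random_catalog <- function(n_signatures = 2, seed = 1) {
  m <- with_fixture_seed(seed, {
    raw <- matrix(stats::rexp(96 * n_signatures), nrow = 96)
    sweep(raw, 2, colSums(raw), "/")
  })
  dimnames(m) <- list(signature_classes(),
                      paste0("SIG", seq_len(n_signatures)))
  validate_catalog(m)
}

#' Toy coding gene
#'
#' Random stop-free coding sequence of `n_codons` codons with single-base
#' flanks, reproducible at a fixed seed.
#'
#' @param n_codons number of codons (>= 1).
#' @param seed integer seed.
#' @return a `gene_sequence`.
#' @export
make_toy_gene <- function(n_codons = 8, seed = 1) {
  stopifnot(n_codons >= 1)
  gc <- Biostrings::GENETIC_CODE
  coding <- names(gc)[gc != "*"]
  with_fixture_seed(seed, {
    codons <- sample(coding, n_codons, replace = TRUE)
    gene_sequence(paste(codons, collapse = ""),
                  sample(BASES, 1), sample(BASES, 1))
  })
}

#' Random synthetic energy matrix
#'
#' Conformation space with `n_positions` flexible positions and
#' `n_rotamers` choices each; singles and pairwise energies drawn i.i.d.
#' normal with standard deviation `sd` (kcal/mol), template energy fixed.
#' Draws from the caller's RNG state, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param n_positions,n_rotamers space dimensions.
#' @param sd energy standard deviation, kcal/mol.
#' @param template template energy, kcal/mol.
#' @export
random_energy_matrix <- function(n_positions = 4, n_rotamers = 4, sd = 2,
                                 template = 0) {
  singles <- lapply(seq_len(n_positions),
                    function(i) stats::rnorm(n_rotamers, 0, sd))
  pairs <- rep(list(NULL), n_positions)
  if (n_positions >= 2L) {
    for (i in seq_len(n_positions - 1L)) {
      pairs[[i]] <- rep(list(NULL), n_positions)
      for (j in (i + 1L):n_positions) {
        pairs[[i]][[j]] <- matrix(stats::rnorm(n_rotamers^2, 0, sd),
                                  n_rotamers, n_rotamers)
      }
    }
  }
  new_energy_matrix(template, singles, pairs)
}

#' Write the standard fixture tree
#'
#' Regenerates the synthetic inputs (toy dimer PDB, toy gene FASTA, uniform
#' and random signature catalogs, cancer weights) under a directory.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_complex(fixture_recipe(seed = seed))
  writeLines(toy$pdb_text, file.path(dir, "toy_dimer.pdb"))
  gene <- make_toy_gene(8, seed = seed)
  writeLines(c(">toy_gene coding sequence with 1-base flanks",
               paste0(gene$flank5, gene$sequence, gene$flank3)),
             file.path(dir, "toy_gene.fa"))
  for (cat_spec in list(list(make_uniform_catalog(), "uniform_catalog.tsv"),
                        list(make_random_catalog(2, seed), "random_catalog.tsv"))) {
    m <- cat_spec[[1]]
    d <- data.frame(class = rownames(m), m, check.names = FALSE)
    utils::write.table(d, file.path(dir, cat_spec[[2]]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(data.frame(signature = colnames(make_random_catalog(2, seed)),
                                weight = c(0.6, 0.4)),
                     file.path(dir, "cancer_weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
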