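# Pairwise-decomposable energy model.
#
# The physics is a deliberately simple pairwise potential on heavy atoms:
# Lennard-Jones 12-6 with Lorentz-Berthelot combining (r_min = r_i + r_j,
# eps = sqrt(eps_i eps_j)) plus Coulomb with a distance-dependent
# dielectric eps(r) = 4r. Atom pairs closer than 0.6 (r_i + r_j) are
# clash-capped at +1000 kcal/mol so Boltzmann weights stay finite.
# 1-2 and 1-3 bonded pairs within a residue are excluded; inter-residue
# pairs are always counted.

COULOMB_K <- 332.0636   # kcal A / (mol e^2)
CLASH_CAP <- 1000       # kcal/mol per capped atom pair
CLASH_FRACTION <- 0.6

# Pairwise energy between atom sets A and B (data frames with x,y,z,charge,
# rmin,eps). `exclude` is an optional logical matrix [nrow(A) x nrow(B)]
# marking pairs to skip (bonded 1-2/1-3). `self = TRUE` computes the internal
# energy of A (A against itself, each pair once).
pairwise_energy <- function(A, B = NULL, exclude = NULL, self = is.null(B)) {
  if (self) B <- A
  na <- nrow(A); nb <- nrow(B)
  if (na == 0L || nb == 0L) return(0)
  xa <- atoms_xyz(A); xb <- atoms_xyz(B)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 1e-12] <- 1e-12
  r <- sqrt(d2)
  rm <- outer(A$rmin, B$rmin, "+")
  epsij <- sqrt(outer(A$eps, B$eps))
  qq <- outer(A$charge, B$charge)
  sr6 <- (rm / r)^6
  e <- epsij * (sr6^2 - 2 * sr6) + COULOMB_K * qq / (4 * d2)
  e[r < CLASH_FRACTION * rm] <- CLASH_CAP
  if (!is.null(exclude)) e[exclude] <- 0
  if (self) {
    sum(e[upper.tri(e)])
  } else {
    sum(e)
  }
}

# Bonded exclusion mask for the atoms of ONE residue: TRUE for 1-2 (bonded)
# and 1-3 (sharing a bonded neighbour) pairs. Bonds inferred from ideal
# heavy-atom distances (< 1.9 A).
residue_exclusions <- function(atoms) {
  n <- nrow(atoms)
  if (n == 0L) return(matrix(logical(0), 0, 0))
  x <- atoms_xyz(atoms)
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
  bonded <- d2 < 1.9^2
  diag(bonded) <- FALSE
  one3 <- (bonded %*% bonded) > 0
  excl <- bonded | one3
  diag(excl) <- TRUE   # self pairs never counted
  excl
}

# internal energy of a residue's atom set with 1-2/1-3 exclusions
residue_internal_energy <- function(atoms) {
  pairwise_energy(atoms, exclude = residue_exclusions(atoms))
}

#' Compute the pairwise-decomposed energy matrix of a conformation space
#'
#' Produces the template (rigid-rigid) energy, per-choice single energies
#' (rotamer internal energy plus rotamer-against-template interaction), and
#' pairwise rotamer-rotamer energies for every pair of flexible positions.
#' The decomposition is exact: for any full assignment, template + singles +
#' pairs equals the direct all-atom energy of the assembled coordinates.
#'
#' @param space a `conf_space` from [build_conf_spaces()].
#' @return object of class `energy_matrix` with elements `template`
#'   (kcal/mol), `singles` (list of numeric vectors), `pairs` (list of
#'   matrices, upper-triangular indexing `pairs[[i]][[j]]`, i < j), and
#'   `choices` (list of data frames with columns `type`, `rot`).
#' @export
compute_energy_matrix <- function(space) {
  stopifnot(inherits(space, "conf_space"))
  tpl <- space$template
  np <- length(space$positions)

  # template energy: inter-residue all pairs, intra-residue with exclusions
  template_e <- 0
  keys <- unique(tpl$site)
  by_site <- split(tpl, factor(tpl$site, levels = keys))
  for (i in seq_along(keys)) {
    template_e <- template_e + residue_internal_energy(by_site[[i]])
    if (i < length(keys)) {
      rest <- tpl[tpl$site %in% keys[(i + 1):length(keys)], , drop = FALSE]
      template_e <- template_e + pairwise_energy(by_site[[i]], rest)
    }
  }

  singles <- vector("list", np)
  choices <- vector("list", np)
  for (i in seq_len(np)) {
    pos <- space$positions[[i]]
    own_bb <- tpl[tpl$site == pos$site, , drop = FALSE]
    other_tpl <- tpl[tpl$site != pos$site, , drop = FALSE]
    e <- numeric(length(pos$choices))
    for (ci in seq_along(pos$choices)) {
      rot <- pos$choices[[ci]]$atoms
      if (nrow(rot) > 0L) {
        combined <- rbind(own_bb[, c("name", "x", "y", "z", "charge",
                                     "rmin", "eps")],
                          rot[, c("name", "x", "y", "z", "charge",
                                  "rmin", "eps")])
        excl <- residue_exclusions(combined)
        nb <- nrow(own_bb)
        idx_rot <- (nb + 1):nrow(combined)
        e_int <- pairwise_energy(rot, exclude = excl[idx_rot, idx_rot,
                                                     drop = FALSE])
        e_bb <- pairwise_energy(rot, own_bb,
                                exclude = excl[idx_rot, seq_len(nb),
                                               drop = FALSE])
        e_tpl <- pairwise_energy(rot, other_tpl)
        e[ci] <- e_int + e_bb + e_tpl
      }
    }
    singles[[i]] <- e
    choices[[i]] <- data.frame(
      type = vapply(pos$choices, function(ch) ch$type, character(1)),
      rot = vapply(pos$choices, function(ch) ch$rot, integer(1)),
      stringsAsFactors = FALSE)
  }

  pairs <- rep(list(NULL), np)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      pairs[[i]] <- rep(list(NULL), np)
      for (j in (i + 1L):np) {
        ni <- length(space$positions[[i]]$choices)
        nj <- length(space$positions[[j]]$choices)
        m <- matrix(0, ni, nj)
        for (ci in seq_len(ni)) {
          ai <- space$positions[[i]]$choices[[ci]]$atoms
          for (cj in seq_len(nj)) {
            m[ci, cj] <- pairwise_energy(ai,
                                         space$positions[[j]]$choices[[cj]]$atoms)
          }
        }
        pairs[[i]][[j]] <- m
      }
    }
  }
  new_energy_matrix(template_e, singles, pairs, choices,
                    sites = vapply(space$positions, function(p) p$site,
                                   character(1)))
}

#' Construct an energy matrix directly
#'
#' Low-level constructor, used for externally supplied energies (e.g. from
#' the TSV interface) and for synthetic conformation spaces in simulations.
#'
#' @param template template (rigid-rigid) energy, kcal/mol.
#' @param singles list (one element per position) of numeric single
#'   energies, one per (type, rotamer) choice.
#' @param pairs list of lists of matrices: `pairs[[i]][[j]]` for i < j is
#'   the matrix of pairwise energies, rows = choices at i, columns = choices
#'   at j. May be `NULL`-free for spaces with < 2 positions.
#' @param choices optional list of data frames (`type`, `rot`) labelling
#'   each position's choices; defaults to a single type `"X"`.
#' @param sites optional character vector of site labels per position.
#' @export
new_energy_matrix <- function(template, singles, pairs = NULL,
                              choices = NULL, sites = NULL) {
  np <- length(singles)
  if (is.null(choices)) {
    choices <- lapply(singles, function(sv) {
      data.frame(type = rep("X", length(sv)), rot = seq_along(sv),
                 stringsAsFactors = FALSE)
    })
  }
  if (is.null(sites)) sites <- paste0("pos", seq_len(np))
  if (is.null(pairs)) pairs <- rep(list(NULL), np)
  # symmetry: store upper triangle only, validate shapes
  for (i in seq_len(np)) {
    if (nrow(choices[[i]]) != length(singles[[i]])) {
      stop("choices/singles length mismatch at position ", i)
    }
    if (i < np && !is.null(pairs[[i]])) {
      for (j in (i + 1L):np) {
        m <- pairs[[i]][[j]]
        if (!is.null(m) && any(!is.finite(m))) stop("non-finite pair energy")
        if (!is.null(m) &&
            !all(dim(m) == c(length(singles[[i]]), length(singles[[j]])))) {
          stop("pair matrix dimension mismatch at (", i, ",", j, ")")
        }
      }
    }
  }
  structure(list(template = template, singles = singles, pairs = pairs,
                 choices = choices, sites = sites, n_positions = np),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat("energy_matrix:", x$n_positions, "position(s),",
      conformation_count(x), "conformations, template",
      format(x$template, digits = 6), "kcal/mol\n")
  invisible(x)
}

pair_entry <- function(m, i, j, ci, cj) {
  if (i == j) stop("pair energies need two distinct positions")
  if (i < j) m$pairs[[i]][[j]][ci, cj] else m$pairs[[j]][[i]][cj, ci]
}

#' Total energy of a full assignment
#'
#' @param m an `energy_matrix`.
#' @param assignment integer vector of choice indices, one per position, or
#'   a data frame with columns `type` and `rot` matched against the
#'   matrix's choice tables.
#' @return energy in kcal/mol: template + sum of singles + sum of pairs.
#' @export
assignment_energy <- function(m, assignment) {
  stopifnot(inherits(m, "energy_matrix"))
  idx <- assignment_index(m, assignment)
  e <- m$template
  np <- m$n_positions
  for (i in seq_len(np)) e <- e + m$singles[[i]][idx[i]]
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        e <- e + m$pairs[[i]][[j]][idx[i], idx[j]]
      }
    }
  }
  e
}

assignment_index <- function(m, assignment) {
  np <- m$n_positions
  if (is.data.frame(assignment)) {
    if (nrow(assignment) != np) {
      stop("assignment must cover every position exactly once (",
           np, " positions, got ", nrow(assignment), ")")
    }
    idx <- integer(np)
    for (i in seq_len(np)) {
      hit <- which(m$choices[[i]]$type == assignment$type[i] &
                     m$choices[[i]]$rot == assignment$rot[i])
      if (length(hit) != 1L) {
        stop("no choice (", assignment$type[i], ", rot ",
             assignment$rot[i], ") at position ", i)
      }
      idx[i] <- hit
    }
    idx
  } else {
    idx <- as.integer(assignment)
    if (length(idx) != np || anyNA(idx)) {
      stop("assignment must cover every position exactly once")
    }
    for (i in seq_len(np)) {
      if (idx[i] < 1L || idx[i] > length(m$singles[[i]])) {
        stop("choice index out of range at position ", i)
      }
    }
    idx
  }
}

# Restrict an energy matrix to a subset of residue types per position
# (named by position index); used to score one sequence of a multi-type
# space.
restrict_energy_matrix <- function(m, types) {
  stopifnot(inherits(m, "energy_matrix"), length(types) == m$n_positions)
  keep <- lapply(seq_len(m$n_positions), function(i) {
    k <- which(m$choices[[i]]$type %in% types[[i]])
    if (length(k) == 0L) {
      stop("no choices of type ", paste(types[[i]], collapse = "/"),
           " at position ", i)
    }
    k
  })
  singles <- lapply(seq_len(m$n_positions),
                    function(i) m$singles[[i]][keep[[i]]])
  choices <- lapply(seq_len(m$n_positions),
                    function(i) m$choices[[i]][keep[[i]], , drop = FALSE])
  np <- m$n_positions
  pairs <- rep(list(NULL), np)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      pairs[[i]] <- rep(list(NULL), np)
      for (j in (i + 1L):np) {
        pairs[[i]][[j]] <- m$pairs[[i]][[j]][keep[[i]], keep[[j]],
                                             drop = FALSE]
      }
    }
  }
  new_energy_matrix(m$template, singles, pairs, choices, m$sites)
}

#' Write / read an energy matrix as TSV
#'
#' Plain-text interchange layout so externally computed force-field energies
#' can be injected. Rows carry `kind` = `template`, `single` or `pair`;
#' positions are 1-based indices; `type`/`rot` identify the choice.
#'
#' @param m an `energy_matrix`.
#' @param path file path.
#' @export
write_energy_matrix <- function(m, path) {
  stopifnot(inherits(m, "energy_matrix"))
  rows <- list(data.frame(kind = "template", pos_i = NA, type_i = NA,
                          rot_i = NA, pos_j = NA, type_j = NA, rot_j = NA,
                          energy = m$template, stringsAsFactors = FALSE))
  for (i in seq_len(m$n_positions)) {
    ch <- m$choices[[i]]
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "single", pos_i = i, type_i = ch$type,
                 rot_i = ch$rot, pos_j = NA, type_j = NA, rot_j = NA,
                 energy = m$singles[[i]], stringsAsFactors = FALSE)
  }
  if (m$n_positions >= 2L) {
    for (i in seq_len(m$n_positions - 1L)) {
      for (j in (i + 1L):m$n_positions) {
        ci <- m$choices[[i]]; cj <- m$choices[[j]]
        grid <- expand.grid(a = seq_len(nrow(ci)), b = seq_len(nrow(cj)))
        rows[[length(rows) + 1L]] <-
          data.frame(kind = "pair", pos_i = i, type_i = ci$type[grid$a],
                     rot_i = ci$rot[grid$a], pos_j = j,
                     type_j = cj$type[grid$b], rot_j = cj$rot[grid$b],
                     energy = m$pairs[[i]][[j]][cbind(grid$a, grid$b)],
                     stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  template <- d$energy[d$kind == "template"]
  if (length(template) != 1L) stop("expected exactly one template row")
  sg <- d[d$kind == "single", , drop = FALSE]
  np <- if (nrow(sg)) max(sg$pos_i) else 0L
  singles <- vector("list", np)
  choices <- vector("list", np)
  for (i in seq_len(np)) {
    si <- sg[sg$pos_i == i, , drop = FALSE]
    singles[[i]] <- si$energy
    choices[[i]] <- data.frame(type = si$type_i, rot = si$rot_i,
                               stringsAsFactors = FALSE)
  }
  pairs <- rep(list(NULL), np)
  pr <- d[d$kind == "pair", , drop = FALSE]
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      pairs[[i]] <- rep(list(NULL), np)
      for (j in (i + 1L):np) {
        pij <- pr[pr$pos_i == i & pr$pos_j == j, , drop = FALSE]
        m <- matrix(0, length(singles[[i]]), length(singles[[j]]))
        a <- match(paste(pij$type_i, pij$rot_i),
                   paste(choices[[i]]$type, choices[[i]]$rot))
        b <- match(paste(pij$type_j, pij$rot_j),
                   paste(choices[[j]]$type, choices[[j]]$rot))
        m[cbind(a, b)] <- pij$energy
        pairs[[i]][[j]] <- m
      }
    }
  }
  new_energy_matrix(template, singles, pairs, choices)
}
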