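#' Enumerate candidate point mutations at a residue site
#'
#' Expands an allowed amino-acid set at one protein site into mutation
#' specifications. The wildtype is included once as the reference entry.
#' Histidine targets expand into the three protonation variants H1
#' (N-delta protonated), H2 (N-epsilon protonated) and H3 (doubly
#' protonated), each scored separately downstream.
#'
#' @param site a row of `structure$sites` (or a list with elements `site`,
#'   `resnum` and `restype`).
#' @param allowed character vector of 1-letter amino-acid codes, or `"ALL"`
#'   for all 19 non-wildtype amino acids.
#' @return list of mutation specs (class `mutation_spec`), reference entry
#'   first.
#' @export
enumerate_mutations <- function(site, allowed) {
  restype <- toupper(site$restype)
  if (!is_protein_restype(restype)) {
    stop("site ", site$site, " is not a protein residue (", restype,
         "); only protein-side mutations are supported")
  }
  wt <- aa_one(restype)
  if (identical(toupper(allowed), "ALL")) {
    allowed <- setdiff(names(AA3), wt)
  }
  allowed <- unique(toupper(allowed))
  if (length(allowed) == 0L) stop("allowed mutation set is empty")
  bad <- setdiff(allowed, names(AA3))
  if (length(bad) > 0L) {
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  out <- list(new_mutation_spec(site, wt, wt, "none"))
  for (aa in setdiff(allowed, wt)) {
    if (aa == "H") {
      for (v in names(HIS_VARIANTS)) {
        out[[length(out) + 1L]] <- new_mutation_spec(site, wt, "H", v)
      }
    } else {
      out[[length(out) + 1L]] <- new_mutation_spec(site, wt, aa, "none")
    }
  }
  out
}

new_mutation_spec <- function(site, wildtype_aa, target_aa, variant) {
  label <- paste0(wildtype_aa, site$resnum,
                  if (nzchar(site$icode %||% "")) site$icode else "",
                  target_aa,
                  if (variant != "none") paste0(".", variant) else "")
  structure(list(site = site$site, chain = site$chain, resnum = site$resnum,
                 icode = site$icode %||% "", wildtype_aa = wildtype_aa,
                 target_aa = target_aa, protonation_variant = variant,
                 is_reference = target_aa == wildtype_aa, label = label),
            class = "mutation_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation:", x$label, if (x$is_reference) "(wildtype reference)" else "",
      "\n")
  invisible(x)
}

# residue template type actually used for a mutation target
target_restype <- function(target_aa, variant) {
  if (target_aa == "H" && variant != "none") {
    unname(HIS_VARIANTS[variant])
  } else {
    aa_three(target_aa)
  }
}

backbone_names <- c("N", "CA", "C", "O", "OXT")

# Build the rotamer choice list for one site and one residue type:
# side-chain atoms placed from chi angles on the site's backbone.
site_choices <- function(s, key, restype) {
  bb <- s$atoms[s$atoms$site == key & s$atoms$name %in% c("N", "CA", "C"), ,
                drop = FALSE]
  need <- setdiff(c("N", "CA", "C"), bb$name)
  if (length(need) > 0L) {
    stop("site ", key, " lacks backbone atom(s) ",
         paste(need, collapse = ", "))
  }
  backbone <- lapply(c(N = "N", CA = "CA", C = "C"), function(nm) {
    a <- bb[bb$name == nm, ][1, ]
    c(a$x, a$y, a$z)
  })
  rots <- rotamers_for(restype)
  lapply(seq_along(rots), function(r) {
    sc <- build_sidechain(restype, backbone, rots[[r]])
    atoms <- if (nrow(sc) == 0L) {
      s$atoms[0, c("name", "x", "y", "z", "charge", "rmin", "eps")]
    } else {
      pr <- lookup_params(restype, sc$name)
      data.frame(name = sc$name, x = sc$x, y = sc$y, z = sc$z,
                 charge = pr$charge, rmin = pr$rmin, eps = pr$eps,
                 stringsAsFactors = FALSE)
    }
    list(type = restype, rot = r, atoms = atoms)
  })
}

#' Build conformation spaces for complex and unbound partners
#'
#' Constructs the three discrete conformation spaces used by the K* score:
#' the bound complex, unbound partner A, and unbound partner B. Mutable
#' residues are flexible (side chains sampled over the rotamer library,
#' backbone rigid); all other residues form the rigid template. At a mutated
#' position the allowed residue types are the wildtype and the mutation
#' target; other flexible positions keep their wildtype type.
#'
#' @param s a `kstar_structure` (already trimmed as desired).
#' @param mutable character vector of 1 or 2 site keys.
#' @param mutation a single `mutation_spec`, a list of them (pair scans), or
#'   `NULL` for a wildtype-only space.
#' @return list with elements `complex`, `partner_A`, `partner_B`, each of
#'   class `conf_space`.
#' @export
build_conf_spaces <- function(s, mutable, mutation = NULL) {
  stopifnot(inherits(s, "kstar_structure"))
  mutable <- as.character(mutable)
  if (!length(mutable) %in% c(1L, 2L)) {
    stop("mutable site count must be 1 or 2, got ", length(mutable))
  }
  if (!all(mutable %in% s$sites$site)) {
    stop("mutable site(s) not in structure: ",
         paste(setdiff(mutable, s$sites$site), collapse = ", "))
  }
  muts <- if (is.null(mutation)) list() else
    if (inherits(mutation, "mutation_spec")) list(mutation) else mutation
  for (m in muts) {
    if (!m$site %in% mutable) {
      stop("mutation ", m$label, " targets site ", m$site,
           " which is not listed as mutable")
    }
  }
  # deterministic position order: chain, residue number, insertion code
  rows <- s$sites[match(mutable, s$sites$site), , drop = FALSE]
  ord <- order(rows$chain, rows$resnum, rows$icode)
  mutable <- mutable[ord]

  positions <- lapply(mutable, function(key) {
    row <- s$sites[s$sites$site == key, ]
    if (!is_protein_restype(row$restype)) {
      stop("flexible site ", key, " is not a protein residue; ",
           "nucleic-acid partners are kept rigid")
    }
    wt_type <- toupper(row$restype)
    types <- wt_type
    for (m in muts) {
      if (m$site == key && !m$is_reference) {
        types <- unique(c(types, target_restype(m$target_aa,
                                                m$protonation_variant)))
      }
    }
    choices <- list()
    for (tp in types) {
      choices <- c(choices, site_choices(s, key, tp))
    }
    list(site = key, chain = row$chain, resnum = row$resnum,
         wildtype = wt_type, types = types, choices = choices)
  })

  template_atoms <- function(atoms) {
    flex <- atoms$site %in% mutable & !(atoms$name %in% backbone_names)
    atoms[!flex, , drop = FALSE]
  }
  space_for <- function(state, chains) {
    atoms <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
    pos <- Filter(function(p) p$chain %in% chains, positions)
    structure(list(state = state, positions = pos,
                   template = template_atoms(atoms)),
              class = "conf_space")
  }
  list(complex = space_for("complex", c(s$partner_a, s$partner_b)),
       partner_A = space_for("partner_A", s$partner_a),
       partner_B = space_for("partner_B", s$partner_b))
}

#' @export
print.conf_space <- function(x, ...) {
  nc <- conformation_count(x)
  cat("conf_space [", x$state, "]: ", length(x$positions),
      " flexible position(s), ", nrow(x$template), " template atoms, ",
      nc, " conformations\n", sep = "")
  invisible(x)
}

#' Total number of conformations of a conformation space
#'
#' Product over flexible positions of the number of (residue type, rotamer)
#' choices.
#'
#' @param space a `conf_space` or an `energy_matrix`.
#' @export
conformation_count <- function(space) {
  if (inherits(space, "energy_matrix")) {
    return(prod(vapply(space$choices, nrow, integer(1))))
  }
  prod(vapply(space$positions, function(p) length(p$choices), integer(1)))
}
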