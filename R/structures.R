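#' Read a two-partner complex from PDB text
#'
#' Parses a PDB-format structure (via bio3d), keeps the chains belonging to
#' the two designated binding partners, drops waters, buffer components and
#' any chain outside the partner sets, discards hydrogens (the energy model
#' is united-atom on heavy atoms), resolves alternate locations to the
#' highest-occupancy conformer, and attaches per-atom charge and van der
#' Waals parameters from the embedded template table.
#'
#' @param pdb_text character scalar with PDB-format content, or a file path.
#' @param partner_a_chains,partner_b_chains disjoint non-empty character
#'   vectors of author chain identifiers for the two binding partners.
#' @return An object of class `kstar_structure`: a list with `atoms`
#'   (data frame of parameterised heavy atoms), `sites` (one row per
#'   residue), and the two partner chain sets.
#' @examples
#' pdb <- make_toy_complex(fixture_recipe(n_residues_per_partner = 2))
#' s <- read_structure(pdb$pdb_text, "A", "B")
#' nrow(s$sites)
#' @export
read_structure <- function(pdb_text, partner_a_chains, partner_b_chains) {
  partner_a_chains <- as.character(partner_a_chains)
  partner_b_chains <- as.character(partner_b_chains)
  if (length(partner_a_chains) == 0L || length(partner_b_chains) == 0L) {
    stop("both partner chain sets must be non-empty")
  }
  overlap <- intersect(partner_a_chains, partner_b_chains)
  if (length(overlap) > 0L) {
    stop("partner chain sets overlap: ", paste(overlap, collapse = ", "))
  }
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    path <- pdb_text
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(pdb_text, collapse = "\n"), path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  keep <- at$chain %in% c(partner_a_chains, partner_b_chains)
  at <- at[keep, , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD", "SO4", "GOL",
                                      "EDO", "PEG", "PO4", "CL", "NA")), ,
           drop = FALSE]
  # united-atom model: drop hydrogens/deuteriums
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 trimws(at$elesy), substr(trimws(at$elety), 1, 1))
  at <- at[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering")

  # alternate locations: highest occupancy wins, ties by altloc letter order
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(akey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]
  # restore file order of residues/atoms
  at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]

  site <- site_key(at$chain, at$resno, at$insert)
  usite <- unique(site)
  sites <- at[match(usite, site), c("chain", "resno", "insert", "resid")]
  names(sites) <- c("chain", "resnum", "icode", "restype")
  sites$site <- usite
  rownames(sites) <- NULL

  parts <- vector("list", length(usite))
  for (i in seq_along(usite)) {
    a <- at[site == usite[i], , drop = FALSE]
    restype <- toupper(a$resid[1])
    if (is.na(match(restype, ff_param_table()$restype))) {
      stop("residue type '", restype, "' at site ", usite[i],
           " has no parameter template")
    }
    pr <- lookup_params(restype, trimws(a$elety))
    parts[[i]] <- data.frame(site = usite[i], chain = a$chain,
                             resnum = a$resno, icode = a$insert,
                             restype = restype, name = trimws(a$elety),
                             x = a$x, y = a$y, z = a$z,
                             charge = pr$charge, rmin = pr$rmin,
                             eps = pr$eps, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, parts)
  for (pset in list(partner_a_chains, partner_b_chains)) {
    if (!any(sites$chain %in% pset)) {
      stop("partner chain set {", paste(pset, collapse = ","),
           "} has no residues in the structure")
    }
  }
  new_structure(atoms, sites, partner_a_chains, partner_b_chains)
}

site_key <- function(chain, resnum, icode = "") {
  icode <- ifelse(is.na(icode) | !nzchar(icode), "", icode)
  ifelse(nzchar(icode),
         paste(chain, resnum, icode, sep = ":"),
         paste(chain, resnum, sep = ":"))
}

new_structure <- function(atoms, sites, partner_a, partner_b) {
  rownames(atoms) <- NULL
  rownames(sites) <- NULL
  structure(list(atoms = atoms, sites = sites,
                 partner_a = partner_a, partner_b = partner_b),
            class = "kstar_structure")
}

#' @export
print.kstar_structure <- function(x, ...) {
  cat("kstar_structure:", nrow(x$sites), "residues,", nrow(x$atoms),
      "heavy atoms\n")
  cat("  partner A chains:", paste(x$partner_a, collapse = ", "),
      "(", sum(x$sites$chain %in% x$partner_a), "residues )\n")
  cat("  partner B chains:", paste(x$partner_b, collapse = ", "),
      "(", sum(x$sites$chain %in% x$partner_b), "residues )\n")
  invisible(x)
}

#' Write a structure back to PDB format
#'
#' @param s a `kstar_structure`.
#' @param file output path; when `NULL` the PDB text is returned invisibly
#'   as a character vector of lines.
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(inherits(s, "kstar_structure"))
  a <- s$atoms
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resnum, resid = a$restype, chain = a$chain,
                   insert = ifelse(nzchar(a$icode), a$icode, ""),
                   eleno = seq_len(nrow(a)), elety = a$name,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  if (is.null(file)) {
    txt <- readLines(path)
    unlink(path)
    invisible(txt)
  } else {
    invisible(file)
  }
}

atoms_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# minimum heavy-atom distance between two coordinate matrices
min_cross_dist <- function(xa, xb) {
  sqrt(max(0, min(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                    2 * xa %*% t(xb))))
}

#' Detect interface residues between the two partners
#'
#' A residue is part of the binding interface if any of its heavy atoms lies
#' within `cutoff` of any heavy atom of the opposite partner (closed
#' boundary). Residues from both partners are returned.
#'
#' @param s a `kstar_structure`.
#' @param cutoff heavy-atom contact distance in Angstrom (default 5).
#' @return character vector of site keys (`"chain:resnum[:icode]"`), in
#'   structure order; possibly empty.
#' @export
find_interface_residues <- function(s, cutoff = 5) {
  stopifnot(inherits(s, "kstar_structure"), cutoff > 0)
  in_a <- s$atoms$chain %in% s$partner_a
  xa <- atoms_xyz(s$atoms[in_a, , drop = FALSE])
  xb <- atoms_xyz(s$atoms[!in_a, , drop = FALSE])
  sa <- s$atoms$site[in_a]
  sb <- s$atoms$site[!in_a]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  found <- unique(c(sa[hit[, 1]], sb[hit[, 2]]))
  s$sites$site[s$sites$site %in% found]
}

#' Trim a structure to a shell around the interface
#'
#' Retains exactly the residues having at least one heavy atom within
#' `radius` of at least one heavy atom of any interface residue; interface
#' residues themselves are always retained (their self-distance is zero).
#'
#' @param s a `kstar_structure`.
#' @param interface character vector of interface site keys (subset of
#'   `s$sites$site`), e.g. from [find_interface_residues()].
#' @param radius shell radius in Angstrom (default 12, the retention shell
#'   used around binding interfaces).
#' @return trimmed `kstar_structure`.
#' @export
trim_to_shell <- function(s, interface, radius = 12) {
  stopifnot(inherits(s, "kstar_structure"), radius > 0)
  if (length(interface) == 0L) stop("empty interface: nothing to trim against")
  if (!all(interface %in% s$sites$site)) {
    stop("interface sites not in structure: ",
         paste(setdiff(interface, s$sites$site), collapse = ", "))
  }
  xi <- atoms_xyz(s$atoms[s$atoms$site %in% interface, , drop = FALSE])
  keep_site <- vapply(s$sites$site, function(k) {
    if (k %in% interface) return(TRUE)
    xs <- atoms_xyz(s$atoms[s$atoms$site == k, , drop = FALSE])
    min_cross_dist(xs, xi) <= radius + 1e-12
  }, logical(1))
  kept <- s$sites$site[keep_site]
  atoms <- s$atoms[s$atoms$site %in% kept, , drop = FALSE]
  sites <- s$sites[keep_site, , drop = FALSE]
  new_structure(atoms, sites, s$partner_a, s$partner_b)
}
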