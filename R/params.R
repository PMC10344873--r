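# Embedded parameter tables: simplified united-atom charges/vdW parameters,
# rotamer library, and side-chain internal coordinates. All are plain-text
# TSV files under extdata, loaded once per session.

.pkg_cache <- new.env(parent = emptyenv())

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "kstarscan")
  if (!nzchar(p)) {
    # during development (pkgload), fall back to the source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("missing embedded data file: ", file)
  p
}

read_embedded_tsv <- function(file) {
  utils::read.delim(extdata_path(file), comment.char = "#",
                    stringsAsFactors = FALSE)
}

ff_param_table <- function() {
  if (is.null(.pkg_cache$ff)) .pkg_cache$ff <- read_embedded_tsv("ff_params.tsv")
  .pkg_cache$ff
}

rotamer_table <- function() {
  if (is.null(.pkg_cache$rot)) {
    .pkg_cache$rot <- read_embedded_tsv("rotamers.tsv")
  }
  .pkg_cache$rot
}

zmatrix_table <- function() {
  if (is.null(.pkg_cache$zm)) {
    .pkg_cache$zm <- read_embedded_tsv("sidechain_zmatrix.tsv")
  }
  .pkg_cache$zm
}

# amino-acid code maps
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)
HIS_VARIANTS <- c(H1 = "HID", H2 = "HIE", H3 = "HIP")
DNA_TYPES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T", "U", "DU")

aa_three <- function(code1) {
  out <- AA3[toupper(code1)]
  if (any(is.na(out))) {
    stop("unknown amino-acid code: ",
         paste(code1[is.na(out)], collapse = ", "))
  }
  unname(out)
}

aa_one <- function(code3) {
  code3 <- toupper(code3)
  code3[code3 %in% HIS_VARIANTS] <- "HIS"
  out <- AA1[code3]
  if (any(is.na(out))) {
    stop("unknown residue type: ", paste(code3[is.na(out)], collapse = ", "))
  }
  unname(out)
}

is_protein_restype <- function(code3) {
  toupper(code3) %in% c(names(AA1), HIS_VARIANTS)
}

# Look up (charge, rmin, eps) for every atom of one residue type.
# Backbone atoms match wildcard rows; residue-specific rows take precedence.
lookup_params <- function(restype, atom_names) {
  ff <- ff_param_table()
  own <- ff[ff$restype == restype, , drop = FALSE]
  wild <- ff[ff$restype == "*", , drop = FALSE]
  idx_own <- match(atom_names, own$atom)
  idx_wild <- match(atom_names, wild$atom)
  charge <- ifelse(!is.na(idx_own), own$charge[idx_own], wild$charge[idx_wild])
  rmin <- ifelse(!is.na(idx_own), own$rmin[idx_own], wild$rmin[idx_wild])
  eps <- ifelse(!is.na(idx_own), own$eps[idx_own], wild$eps[idx_wild])
  if (anyNA(charge)) {
    bad <- atom_names[is.na(charge)]
    stop("no parameters for atom(s) ", paste(bad, collapse = ", "),
         " in residue type '", restype, "'")
  }
  data.frame(name = atom_names, charge = charge, rmin = rmin, eps = eps,
             stringsAsFactors = FALSE)
}

# Rotamers for a residue type: list of numeric chi vectors (possibly length 0).
rotamers_for <- function(restype) {
  rt <- rotamer_table()
  rows <- rt[rt$restype == restype, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rotamers for residue type '", restype, "'")
  rows <- rows[order(rows$rot), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    chis <- as.numeric(rows[i, c("chi1", "chi2", "chi3", "chi4")])
    chis[!is.na(chis)]
  })
}
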