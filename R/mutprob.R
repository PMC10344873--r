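# Relative probabilities of mutation formation from mutational signatures.
#
# Signatures are probability distributions over the 96 pyrimidine-centred
# trinucleotide substitution classes. A cancer type weights the signatures
# by their contribution to its mutational burden; the weighted class value
# is the per-base-exchange probability. Amino-acid mutations are scored by
# summing over all codon substitution paths of at most two base exchanges;
# mutations reachable only by changing all three codon bases are excluded
# as extremely unlikely.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-centred classes in the conventional order: substitution types
#' C>A, C>G, C>T, T>A, T>C, T>G, each across the 16 flanking-base contexts,
#' keyed like `"A[C>A]A"`.
#' @return character vector of length 96.
#' @export
signature_classes <- function() {
  out <- character(0)
  for (ref in c("C", "T")) {
    for (alt in setdiff(BASES, ref)) {
      for (five in BASES) {
        for (three in BASES) {
          out <- c(out, sprintf("%s[%s>%s]%s", five, ref, alt, three))
        }
      }
    }
  }
  out
}

validate_catalog <- function(catalog) {
  if (!is.matrix(catalog)) stop("signature catalog must be a matrix")
  cls <- signature_classes()
  if (!setequal(rownames(catalog), cls)) {
    stop("signature catalog must have exactly the 96 substitution classes ",
         "as row names")
  }
  catalog <- catalog[cls, , drop = FALSE]
  sums <- colSums(catalog)
  if (any(catalog < 0) || any(abs(sums - 1) > 1e-6)) {
    stop("each signature must be a probability distribution over the 96 ",
         "classes (non-negative, summing to 1 within 1e-6)")
  }
  catalog
}

normalize_weights <- function(weights, catalog) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("cancer weights must be named by signature id")
  }
  missing <- setdiff(names(weights), colnames(catalog))
  if (length(missing) > 0L) {
    stop("weights refer to signatures absent from the catalog: ",
         paste(missing, collapse = ", "))
  }
  if (any(weights < 0)) stop("signature weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("signature weights sum to zero")
  weights / tot   # relative-probability semantics: renormalise
}

#' Probability of a single base exchange in trinucleotide context
#'
#' Looks up the signature-catalog class of the substitution
#' `five[ref>alt]three`, collapsing purine-centred contexts onto their
#' reverse complement first, and returns the cancer-weighted mixture of the
#' signature values.
#'
#' @param five,ref,three,alt single bases (`A`/`C`/`G`/`T`); `alt != ref`.
#' @param weights named non-negative signature weights (renormalised to sum
#'   to 1).
#' @param catalog matrix `96 classes x signatures`, rows keyed like
#'   `"A[C>A]A"`.
#' @return scalar probability.
#' @export
base_change_probability <- function(five, ref, three, alt, weights, catalog) {
  for (b in c(five, ref, three, alt)) {
    if (!b %in% BASES) stop("invalid base: ", b)
  }
  if (alt == ref) stop("alternative base equals the reference base")
  if (ref %in% c("A", "G")) {   # collapse to the pyrimidine strand
    tmp <- five
    five <- unname(COMP[three])
    three <- unname(COMP[tmp])
    ref <- unname(COMP[ref])
    alt <- unname(COMP[alt])
  }
  catalog <- validate_catalog(catalog)
  weights <- normalize_weights(weights, catalog)
  key <- sprintf("%s[%s>%s]%s", five, ref, alt, three)
  sum(weights * catalog[key, names(weights)])
}

#' Codon substitution paths to a target amino acid
#'
#' All codons encoding `target_aa`, each annotated with the base changes
#' required from `codon` and classified `single`, `double` or `triple` by
#' Hamming distance. Paths are listed in codon-table order.
#'
#' @param codon character scalar of 3 bases.
#' @param target_aa 1-letter amino-acid code, different from the codon's
#'   own translation.
#' @return list of paths: each has `codon_to`, `changes` (data frame with
#'   `pos`, `ref`, `alt`), `n_changes`, `class`.
#' @export
codon_paths <- function(codon, target_aa) {
  codon <- toupper(codon)
  target_aa <- toupper(target_aa)
  if (nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in% BASES)) {
    stop("codon must be 3 bases of A/C/G/T")
  }
  gc <- Biostrings::GENETIC_CODE
  wt_aa <- unname(gc[codon])
  if (is.na(wt_aa)) stop("codon ", codon, " does not translate")
  if (wt_aa == target_aa) {
    stop("target amino acid equals the codon's own translation (", wt_aa, ")")
  }
  if (!target_aa %in% names(AA3)) stop("unknown amino acid: ", target_aa)
  targets <- names(gc)[gc == target_aa]
  from <- strsplit(codon, "")[[1]]
  lapply(targets, function(to) {
    tob <- strsplit(to, "")[[1]]
    pos <- which(tob != from)
    n <- length(pos)
    list(codon_to = to,
         changes = data.frame(pos = pos, ref = from[pos], alt = tob[pos],
                              stringsAsFactors = FALSE),
         n_changes = n,
         class = c("single", "double", "triple")[n])
  })
}

#' Coding gene sequence with single-base flanks
#'
#' @param sequence coding DNA (A/C/G/T), length divisible by 3, no stop
#'   codons required internally.
#' @param flank5,flank3 single bases giving trinucleotide context for the
#'   first and last codon position.
#' @export
gene_sequence <- function(sequence, flank5, flank3) {
  sequence <- toupper(sequence)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% BASES)) stop("coding sequence must be A/C/G/T only")
  if (length(chars) %% 3L != 0L) {
    stop("coding sequence length must be divisible by 3")
  }
  if (!flank5 %in% BASES || !flank3 %in% BASES) {
    stop("flanks must be single A/C/G/T bases")
  }
  structure(list(sequence = sequence, flank5 = flank5, flank3 = flank3,
                 n_codons = length(chars) %/% 3L),
            class = "gene_sequence")
}

#' Read a coding sequence (with 1-base flanks) from FASTA
#'
#' The FASTA record must contain the coding sequence plus exactly one
#' flanking base on each side (first and last character).
#' @param path FASTA file.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 1L) stop("no sequence in ", path)
  x <- as.character(seqs[[1]])
  if (nchar(x) < 5L) stop("sequence too short to carry flanks and a codon")
  gene_sequence(substr(x, 2, nchar(x) - 1L), substr(x, 1, 1),
                substr(x, nchar(x), nchar(x)))
}

gene_translate <- function(gene) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(gene$sequence, seq(1, nchar(gene$sequence), 3),
                      seq(3, nchar(gene$sequence), 3))
  unname(gc[codons])
}

#' Relative probability that an amino-acid mutation is formed
#'
#' Sums signature-derived probabilities over every codon substitution path
#' of at most two base exchanges that converts the codon at
#' `protein_position` into a codon encoding `target_aa`. Single exchanges
#' are scored in their genomic trinucleotide context. Double exchanges are
#' scored as the sum over both substitution orders of the product of the
#' two stepwise probabilities, the second step evaluated in the context
#' left behind by the first. Mutations reachable only by substituting all
#' three codon bases carry no probability and are flagged
#' `excluded_triple`.
#'
#' @param gene a `gene_sequence`.
#' @param protein_position 1-based codon index.
#' @param target_aa 1-letter code of the target amino acid.
#' @param weights,catalog see [base_change_probability()].
#' @return object of class `mutation_probability` with `relative_probability`
#'   (`NA` when excluded), `excluded_triple`, and a `paths` data frame.
#' @export
mutation_probability <- function(gene, protein_position, target_aa,
                                 weights, catalog) {
  stopifnot(inherits(gene, "gene_sequence"))
  if (protein_position < 1L || protein_position > gene$n_codons) {
    stop("protein position ", protein_position, " outside gene (",
         gene$n_codons, " codons)")
  }
  padded <- paste0(gene$flank5, gene$sequence, gene$flank3)
  off <- 3L * (protein_position - 1L)   # codon starts at padded index off+2
  codon <- substr(gene$sequence, off + 1L, off + 3L)
  paths <- codon_paths(codon, target_aa)
  wt_aa <- unname(Biostrings::GENETIC_CODE[codon])

  step_prob <- function(chars, gpos, alt) {
    # chars: padded sequence as character vector; gpos: index in the
    # unpadded sequence
    base_change_probability(chars[gpos], chars[gpos + 1L], chars[gpos + 2L],
                            alt, weights, catalog)
  }

  rows <- list()
  total <- 0
  any_kept <- FALSE
  for (p in paths) {
    if (p$n_changes > 2L) {
      rows[[length(rows) + 1L]] <-
        data.frame(codon_to = p$codon_to, n_changes = p$n_changes,
                   probability = NA_real_, stringsAsFactors = FALSE)
      next
    }
    any_kept <- TRUE
    gpos <- off + p$changes$pos   # 1-based in unpadded; padded index gpos+1
    if (p$n_changes == 1L) {
      chars <- strsplit(padded, "")[[1]]
      pp <- step_prob(chars, gpos[1], p$changes$alt[1])
    } else {
      orders <- list(c(1L, 2L), c(2L, 1L))
      pp <- 0
      for (ord in orders) {
        chars <- strsplit(padded, "")[[1]]
        p1 <- step_prob(chars, gpos[ord[1]], p$changes$alt[ord[1]])
        chars[gpos[ord[1]] + 1L] <- p$changes$alt[ord[1]]
        p2 <- step_prob(chars, gpos[ord[2]], p$changes$alt[ord[2]])
        pp <- pp + p1 * p2
      }
    }
    total <- total + pp
    rows[[length(rows) + 1L]] <-
      data.frame(codon_to = p$codon_to, n_changes = p$n_changes,
                 probability = pp, stringsAsFactors = FALSE)
  }
  structure(list(protein_position = protein_position,
                 wildtype_aa = wt_aa, target_aa = toupper(target_aa),
                 codon = codon,
                 paths = do.call(rbind, rows),
                 excluded_triple = !any_kept,
                 relative_probability = if (any_kept) total else NA_real_),
            class = "mutation_probability")
}

#' @export
print.mutation_probability <- function(x, ...) {
  lab <- paste0(x$wildtype_aa, x$protein_position, x$target_aa)
  if (x$excluded_triple) {
    cat(lab, ": excluded (all paths require a triple contiguous mutation)\n",
        sep = "")
  } else {
    cat(sprintf("%s: relative probability %.6g over %d codon path(s)\n",
                lab, x$relative_probability,
                sum(!is.na(x$paths$probability))))
  }
  invisible(x)
}

#' Rank mutation probabilities
#'
#' Descending by relative probability; excluded-triple entries last; ties
#' broken by protein position, then target residue alphabetically.
#'
#' @param mutations list of `mutation_probability` objects.
#' @return data frame with one row per mutation, ranked.
#' @export
rank_probabilities <- function(mutations) {
  if (length(mutations) == 0L) {
    return(data.frame(protein_position = integer(), wildtype_aa = character(),
                      target_aa = character(), relative_probability = numeric(),
                      excluded_triple = logical()))
  }
  d <- do.call(rbind, lapply(mutations, function(m) {
    data.frame(protein_position = m$protein_position,
               wildtype_aa = m$wildtype_aa, target_aa = m$target_aa,
               relative_probability = m$relative_probability,
               excluded_triple = m$excluded_triple,
               stringsAsFactors = FALSE)
  }))
  key <- ifelse(d$excluded_triple, -Inf, d$relative_probability)
  d <- d[order(-key, d$protein_position, d$target_aa), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a signature catalog / cancer weights from TSV
#'
#' Catalog layout: wide table, first column `class` keyed `"A[C>A]A"`-style,
#' remaining columns one per signature. Weights layout: columns `signature`
#' and `weight`.
#' @param path TSV file.
#' @export
read_signature_catalog <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  validate_catalog(m)
}

#' @rdname read_signature_catalog
#' @export
read_cancer_weights <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$weight, d$signature)
}
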