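uniform <- make_uniform_catalog()
uw <- c(UNIFORM = 1)

test_that("uniform catalog gives every single base exchange probability 1/96", {
  for (ref in c("C", "T", "A", "G")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      expect_equal(base_change_probability("A", ref, "C", alt, uw, uniform),
                   1 / 96)
    }
  }
  expect_error(base_change_probability("A", "C", "C", "C", uw, uniform),
               "equals")
})

test_that("two equally weighted signatures average their class values", {
  classes <- signature_classes()
  sig1 <- matrix(0, 96, 1, dimnames = list(classes, "S1"))
  sig1["A[C>A]A", 1] <- 0.7
  sig1["T[T>G]T", 1] <- 0.3
  sig2 <- matrix(0, 96, 1, dimnames = list(classes, "S2"))
  sig2["A[C>A]A", 1] <- 0.1
  sig2["G[C>T]C", 1] <- 0.9
  cat2 <- cbind(sig1, sig2)
  colnames(cat2) <- c("S1", "S2")
  w <- c(S1 = 0.5, S2 = 0.5)
  expect_equal(base_change_probability("A", "C", "A", "A", w, cat2),
               (0.7 + 0.1) / 2)
  expect_equal(base_change_probability("G", "C", "C", "T", w, cat2),
               (0 + 0.9) / 2)
  # weights renormalise: 2/2 scale gives the same answer
  expect_equal(base_change_probability("A", "C", "A", "A",
                                       c(S1 = 2, S2 = 2), cat2), 0.4)
})

test_that("purine-centred contexts collapse onto their reverse complement", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  catal <- make_random_catalog(2, seed = 5)
  w <- c(SIG1 = 0.3, SIG2 = 0.7)
  bases <- c("A", "C", "G", "T")
  for (ref in c("A", "G")) {
    for (alt in setdiff(bases, ref)) {
      for (five in bases) {
        for (three in bases) {
          p_pur <- base_change_probability(five, ref, three, alt, w, catal)
          p_pyr <- base_change_probability(comp[[three]], comp[[ref]],
                                           comp[[five]], comp[[alt]], w,
                                           catal)
          expect_equal(p_pur, p_pyr, tolerance = 1e-15)
        }
      }
    }
  }
})

test_that("codon paths carry the Hamming distance to each target codon", {
  p <- codon_paths("AAA", "R")
  dist_to_aga <- p[[which(vapply(p, function(x) x$codon_to,
                                 character(1)) == "AGA")]]
  expect_equal(dist_to_aga$n_changes, 1)
  expect_equal(dist_to_aga$class, "single")

  p2 <- codon_paths("ATG", "W")     # ATG -> TGG
  expect_length(p2, 1)
  expect_equal(p2[[1]]$n_changes, 2)

  expect_error(codon_paths("AAA", "K"), "equals")
})

test_that("single-path mutations under the uniform catalog score exactly 1/96", {
  # GGT (G) -> GTT (V) is one change; construct a gene containing GGT
  g <- gene_sequence("ATGGGTAAA", "C", "C")
  mp <- mutation_probability(g, 2, "V", uw, uniform)
  one_change <- mp$paths[mp$paths$n_changes == 1, ]
  expect_equal(nrow(one_change), 1)   # GGT->GTT is the only 1-change V codon
  expect_equal(one_change$probability, 1 / 96)
})

test_that("double paths sum both substitution orders (2 x (1/96)^2 uniform)", {
  g <- gene_sequence("ATGGGTAAA", "C", "C")
  mp <- mutation_probability(g, 1, "W", uw, uniform)   # ATG -> TGG, 2 changes
  expect_false(mp$excluded_triple)
  expect_equal(mp$relative_probability, 2 * (1 / 96)^2, tolerance = 1e-15)
})

test_that("double-path scoring is order-symmetric with a non-uniform catalog", {
  catal <- make_random_catalog(1, seed = 9)
  w <- c(SIG1 = 1)
  g <- gene_sequence("ATGGGTAAA", "C", "C")
  mp <- mutation_probability(g, 1, "W", w, catal)
  # independent oracle: enumerate both orders by hand on the padded sequence
  padded <- paste0("C", "ATGGGTAAA", "C")
  step <- function(chars, gpos, alt) {
    base_change_probability(chars[gpos], chars[gpos + 1], chars[gpos + 2],
                            alt, w, catal)
  }
  chars0 <- strsplit(padded, "")[[1]]
  # ATG -> TGG: A1->T at gene pos 1, T2? no: positions 1 (A->T) and 3 (G...)
  # changes: pos1 A->T, pos2 T->G
  p12 <- {
    c1 <- chars0
    a <- step(c1, 1, "T"); c1[2] <- "T"
    a * step(c1, 2, "G")
  }
  p21 <- {
    c2 <- chars0
    b <- step(c2, 2, "G"); c2[3] <- "G"
    b * step(c2, 1, "T")
  }
  expect_equal(mp$relative_probability, p12 + p21, tolerance = 1e-12)
})

test_that("triple-only targets are excluded, matching a Hamming oracle", {
  g <- make_toy_gene(8, seed = 4)
  gc <- Biostrings::GENETIC_CODE
  aas <- sort(unique(gc[gc != "*"]))
  codons <- substring(g$sequence, seq(1, nchar(g$sequence), 3),
                      seq(3, nchar(g$sequence), 3))
  for (pos in seq_len(g$n_codons)) {
    wt <- unname(gc[codons[pos]])
    from <- strsplit(codons[pos], "")[[1]]
    for (aa in setdiff(aas, wt)) {
      # oracle: minimum Hamming distance over the target codons
      dmin <- min(vapply(names(gc)[gc == aa], function(cdn) {
        sum(strsplit(cdn, "")[[1]] != from)
      }, integer(1)))
      mp <- mutation_probability(g, pos, aa, uw, uniform)
      expect_equal(mp$excluded_triple, dmin == 3)
      if (dmin == 3) {
        expect_true(is.na(mp$relative_probability))
      } else {
        expect_true(is.finite(mp$relative_probability))
        expect_gte(mp$relative_probability, 0)
      }
    }
  }
})

test_that("probability ranking matches a naive sort oracle", {
  g <- make_toy_gene(6, seed = 12)
  catal <- make_random_catalog(2, seed = 12)
  w <- c(SIG1 = 0.8, SIG2 = 0.2)
  mps <- list()
  gc <- Biostrings::GENETIC_CODE
  for (pos in seq_len(g$n_codons)) {
    codon <- substr(g$sequence, 3 * pos - 2, 3 * pos)
    for (aa in setdiff(c("A", "W", "R", "P"), unname(gc[codon]))) {
      mps[[length(mps) + 1]] <- mutation_probability(g, pos, aa, w, catal)
    }
  }
  ranked <- rank_probabilities(mps)
  # descending with all excluded entries at the tail
  excl <- ranked$excluded_triple
  expect_true(all(which(excl) > max(c(0, which(!excl)))))
  finite <- ranked$relative_probability[!excl]
  expect_true(!is.unsorted(rev(finite)))
  # naive oracle: full reorder from scratch
  d0 <- do.call(rbind, lapply(mps, function(m) {
    data.frame(protein_position = m$protein_position,
               target_aa = m$target_aa,
               p = ifelse(m$excluded_triple, -Inf, m$relative_probability))
  }))
  d0 <- d0[order(-d0$p, d0$protein_position, d0$target_aa), ]
  expect_equal(ranked$protein_position, d0$protein_position)
  expect_equal(ranked$target_aa, d0$target_aa)
})

test_that("gene sequences validate their alphabet, frame and flanks", {
  expect_error(gene_sequence("ATGX", "A", "A"), "A/C/G/T")
  expect_error(gene_sequence("ATGA", "A", "A"), "divisible")
  expect_error(gene_sequence("ATG", "AA", "A"), "single")
  g <- gene_sequence("ATGAAA", "G", "T")
  expect_equal(g$n_codons, 2)
  expect_error(mutation_probability(g, 3, "W", uw, uniform), "outside")
})
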