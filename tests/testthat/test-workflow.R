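test_that("job loading applies defaults and rejects bad input", {
  job <- load_job(minimal_job_yaml())
  expect_equal(job$epsilon, 0.03)
  expect_equal(job$shell_radius, 12)
  expect_equal(job$triage$cutoff, -3)
  expect_equal(job$interface_cutoff, 5)
  expect_equal(job$temperature, 298.15)
  expect_error(load_job(minimal_job_yaml("foo: 1\n")), "foo")
  expect_error(load_job("partner_a_chains: [A]\npartner_b_chains: [B]\n"),
               "structure_path")
  expect_error(load_job(minimal_job_yaml("epsilon: 1.5\n")), "epsilon")
  expect_error(load_job(minimal_job_yaml(
    "pair_mode: true\nmutable: [\"A:1\", \"A:2\", \"A:3\"]\n")), "pair_mode")
  expect_error(load_job(minimal_job_yaml("cancer_type: melanoma\n")),
               "gene_path")
})

test_that("a wildtype-only scan yields the reference row with zero delta", {
  toy <- toy_dimer()
  job <- load_job(minimal_job_yaml(
    "mutable: [\"A:2\"]\nallowed_mutations: [S]\n"))   # S is the wildtype
  scan <- run_scan(job, structure = toy$structure)
  expect_equal(nrow(scan$calls), 0)
  expect_equal(nrow(scan$wildtype), 1)
  expect_identical(scan$wildtype$self_delta, 0)
})

test_that("the calls table has one row per non-wildtype mutation", {
  toy <- toy_dimer()
  job <- load_job(minimal_job_yaml(
    paste0("mutable: [\"A:2\", \"A:3\"]\n",
           "allowed_mutations: {\"A:2\": [T, G, H], \"A:3\": [C]}\n")))
  scan <- run_scan(job, structure = toy$structure)
  expect_equal(nrow(scan$calls), 4)          # T, G, H (3 variants), C
  his <- scan$calls[scan$calls$target == "H", ]
  expect_equal(his$n_variants, 3)
  expect_true(all(is.finite(c(his$delta_1, his$delta_2, his$delta_3))))
  nonhis <- scan$calls[scan$calls$target != "H", ]
  expect_true(all(nonhis$n_variants == 1))
  expect_true(all(is.na(nonhis$delta_2)))
  expect_equal(nrow(scan$failures), 0)
})

test_that("auto-interface scanning picks up the facing residues", {
  toy <- toy_dimer()
  job <- load_job(minimal_job_yaml("allowed_mutations: [G]\n"))
  scan <- run_scan(job, structure = toy$structure)
  # 6 interface residues; one is GLY (wildtype target) so 5 scored rows
  expect_equal(nrow(scan$calls), 5)
  expect_equal(nrow(scan$wildtype), 6)
})

test_that("scans are deterministic: identical bytes on rerun", {
  toy <- toy_dimer()
  yaml_txt <- minimal_job_yaml(
    "mutable: [\"A:1\"]\nallowed_mutations: [S, T]\nseed: 7\n")
  d1 <- tempfile(); d2 <- tempfile()
  write_scan(run_scan(load_job(yaml_txt), structure = toy$structure), d1)
  write_scan(run_scan(load_job(yaml_txt), structure = toy$structure), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("engineered complex-energy offsets surface as disruptive calls", {
  toy <- toy_dimer()
  job <- load_job(minimal_job_yaml(
    "mutable: [\"A:1\"]\nallowed_mutations: [S, T]\n"))
  off <- data.frame(site = "A:1", target_aa = "S", offset = 8)
  scan <- run_scan(job, structure = toy$structure, complex_offsets = off)
  calls <- scan$calls
  expect_equal(calls$verdict[calls$target == "S"], "disruptive")
  expect_equal(calls$verdict[calls$target == "T"], "non_disruptive")
  # the offset shifts the score by offset / (RT ln 10)
  expected_shift <- 8 / (RT_TEST * log(10))
  base <- calls$delta_1[calls$target == "T"]
  expect_lt(abs(calls$delta_1[calls$target == "S"] + expected_shift), 1.0)
})

test_that("probability stage runs when a cancer type is configured", {
  toy <- toy_dimer()
  dir <- tempfile(); dir.create(dir)
  gene <- make_toy_gene(6, seed = 2)
  writeLines(c(">g", paste0(gene$flank5, gene$sequence, gene$flank3)),
             file.path(dir, "gene.fa"))
  catal <- make_random_catalog(2, seed = 2)
  write.table(data.frame(class = rownames(catal), catal,
                         check.names = FALSE),
              file.path(dir, "sigs.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(signature = colnames(catal), weight = c(0.7, 0.3)),
              file.path(dir, "weights.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  # pick targets that differ from both the structure's and the gene's
  # residue at position 2, so every probability is computable
  aa2 <- kstarscan:::gene_translate(gene)[2]
  targets <- setdiff(c("T", "C", "A"), c(aa2, "S"))[1:2]
  job <- load_job(minimal_job_yaml(paste0(
    "mutable: [\"A:2\"]\nallowed_mutations: [", paste(targets, collapse = ", "),
    "]\n",
    "cancer_type: melanoma\n",
    "gene_path: ", file.path(dir, "gene.fa"), "\n",
    "signatures_path: ", file.path(dir, "sigs.tsv"), "\n",
    "weights_path: ", file.path(dir, "weights.tsv"), "\n")))
  scan <- run_scan(job, structure = toy$structure)
  expect_false(is.null(scan$probabilities))
  expect_equal(nrow(scan$probabilities), 2)
  expect_true(all(c("relative_probability", "excluded_triple") %in%
                    names(scan$probabilities)))
  unlink(dir, recursive = TRUE)
})

test_that("pair mode scores target combinations at two sites", {
  toy <- toy_dimer()
  job <- load_job(minimal_job_yaml(paste0(
    "pair_mode: true\nmutable: [\"A:1\", \"B:1\"]\n",
    "allowed_mutations: [S, T]\n")))
  scan <- run_scan(job, structure = toy$structure)
  expect_equal(nrow(scan$calls), 4)    # {S,T} x {S,T}
  expect_true(all(grepl("\\+", scan$calls$label)))
  expect_identical(scan$wildtype$self_delta, 0)
})
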