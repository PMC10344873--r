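mk_mut <- function(resnum, wt = "A", target = "S",
                   site = paste0("A:", resnum)) {
  list(site = site, resnum = resnum, wildtype_aa = wt, target_aa = target,
       label = paste0(wt, resnum, target))
}

test_that("the default cutoff calls the documented verdicts", {
  cfg <- triage_config()
  expect_equal(cfg$cutoff, -3)
  expect_equal(classify_disruption(-4.46, mutation = mk_mut(248, "R", "Q"))$verdict,
               "disruptive")
  expect_equal(classify_disruption(-1.0)$verdict, "non_disruptive")
  # closed boundary: exactly -3 disrupts
  expect_equal(classify_disruption(-3)$verdict, "disruptive")
  # complete disruption (sentinel NA) always disrupts
  expect_equal(classify_disruption(NA_real_)$verdict, "disruptive")
})

test_that("histidine needs all three protonation variants to disrupt", {
  expect_equal(classify_disruption(c(-3.5, -2.9, -4.1))$verdict,
               "non_disruptive")
  expect_equal(classify_disruption(c(-3.5, -3.1, -4.1))$verdict,
               "disruptive")
  expect_equal(classify_disruption(c(-3.5, NA, -4.1))$verdict, "disruptive")
  # with the rule off, one disrupting variant suffices
  cfg_off <- triage_config(his_rule = FALSE)
  expect_equal(classify_disruption(c(-3.5, -2.9, -0.1), cfg = cfg_off)$verdict,
               "disruptive")
  expect_error(classify_disruption(numeric(0)), "empty")
  expect_error(classify_disruption(c(-4, -4)), "1 score difference")
})

test_that("triple-contiguous paths are excluded regardless of the scores", {
  cl <- classify_disruption(-50, path_class = "triple")
  expect_equal(cl$verdict, "excluded_triple")
  keep <- triage_config(exclude_triples = FALSE)
  expect_equal(classify_disruption(-50, path_class = "triple",
                                   cfg = keep)$verdict, "disruptive")
})

test_that("tightening the cutoff never creates new disruptive calls", {
  set.seed(99)
  vals <- round(runif(200, -8, 2), 2)
  for (cuts in list(c(-2, -3), c(-3, -5), c(-1.5, -6))) {
    loose <- vapply(vals, function(v)
      classify_disruption(v, cfg = triage_config(cutoff = cuts[1]))$verdict,
      character(1))
    tight <- vapply(vals, function(v)
      classify_disruption(v, cfg = triage_config(cutoff = cuts[2]))$verdict,
      character(1))
    expect_true(all(!(tight == "disruptive" & loose != "disruptive")))
  }
})

test_that("hotspot counts match a brute-force groupby oracle", {
  set.seed(17)
  calls <- list()
  positions <- c(84, 84, 84, 84, 23, 87, 10, 20, 10, 20)
  verdicts <- c("disruptive", "disruptive", "disruptive", "disruptive",
                "disruptive", "disruptive", "disruptive", "disruptive",
                "disruptive", "disruptive")
  targets <- c("G", "H", "N", "V", "S", "P", "A", "C", "D", "E")
  for (i in seq_along(positions)) {
    calls[[i]] <- classify_disruption(-5, mutation = mk_mut(positions[i],
                                                            "D", targets[i]))
  }
  # plus a non-disruptive call that must not count
  calls[[11]] <- classify_disruption(-1, mutation = mk_mut(84, "D", "Y"))
  hs <- hotspot_rank(calls, top_k = 1)
  expect_equal(hs$top, "A:84")
  expect_equal(hs$counts$count[hs$counts$site == "A:84"], 4)
  # brute-force oracle over the disruptive calls
  tab <- table(vapply(Filter(function(cl) cl$verdict == "disruptive", calls),
                      function(cl) cl$site, character(1)))
  for (k in names(tab)) {
    expect_equal(hs$counts$count[hs$counts$site == k], unname(tab[[k]]))
  }
  # tie at count 2 between residues 10 and 20: lower residue first
  ranked <- hotspot_rank(calls, top_k = 4)$counts
  expect_lt(which(ranked$site == "A:10"), which(ranked$site == "A:20"))
  # no disruptive calls: empty ranking
  expect_length(hotspot_rank(list(classify_disruption(-1)))$ranking, 0)
})

test_that("a full single-position scan populates 21 target cells plus wt", {
  calls <- list()
  wt <- "D"
  for (aa in setdiff(names(kstarscan:::AA3), wt)) {
    vals <- if (aa == "H") c(-4, -5, -6) else -4
    calls[[length(calls) + 1]] <-
      classify_disruption(vals, mutation = mk_mut(84, wt, aa))
  }
  h <- heatmap_matrix(calls)
  expect_equal(dim(h), c(22, 1))        # 19 non-His rows + H1-H3
  expect_equal(colnames(h), "D84")
  expect_equal(sum(!h %in% c("", "wt")), 21)   # 18 numeric + 3 His variants
  expect_equal(sum(h == "wt"), 1)
  expect_equal(h["D", 1], "wt")
  expect_setequal(h[c("H1", "H2", "H3"), 1], c("-4.00", "-5.00", "-6.00"))
  # triple-excluded and complete-disruption markers
  calls2 <- list(classify_disruption(-9, path_class = "triple",
                                     mutation = mk_mut(7, "G", "W")),
                 classify_disruption(NA_real_, mutation = mk_mut(7, "G", "S")))
  h2 <- heatmap_matrix(calls2)
  expect_equal(h2["W", "G7"], "triple")
  expect_equal(h2["S", "G7"], "X")
  expect_error(heatmap_matrix(c(calls2, calls2[2])), "duplicate")
})

test_that("prioritisation orders by probability, or by score drop without one", {
  calls <- list(classify_disruption(-4.14, mutation = mk_mut(249, "R", "S")),
                classify_disruption(-53.49, mutation = mk_mut(248, "R", "W")),
                classify_disruption(NA_real_, mutation = mk_mut(248, "R", "Q")))
  hs <- hotspot_rank(calls, top_k = 3)
  # no-probability mode: complete disruption first, then most negative
  pr <- prioritize(calls, hs)
  expect_equal(pr$label, c("R248Q", "R248W", "R249S"))
  # probability mode
  probs <- data.frame(protein_position = c(249, 248, 248),
                      target_aa = c("S", "W", "Q"),
                      relative_probability = c(0.02, 0.001, 0.005),
                      excluded_triple = FALSE)
  pr2 <- prioritize(calls, hs, probs)
  expect_equal(pr2$label, c("R249S", "R248Q", "R248W"))
  expect_error(prioritize(calls, hs, probs[1:2, ]), "missing")
  expect_equal(nrow(prioritize(list(), hs)), 0)
})
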