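# closed-form checks for degenerate spaces, oracle comparisons for the
# bounded estimator, and the score arithmetic

pf_from_energy <- function(e, temperature = 298.15) {
  partition_function_exhaustive(new_energy_matrix(e, list()),
                                temperature = temperature)
}

test_that("single-conformation partition functions follow the closed form", {
  pf0 <- pf_from_energy(0)
  expect_equal(pf0$log10_lower, 0)       # Z = exp(0) = 1
  expect_equal(pf0$log10_upper, 0)
  e <- 2.718
  pfe <- pf_from_energy(e)
  expect_equal(pfe$log10_lower, -e / RT_TEST / log(10), tolerance = 1e-12)
})

test_that("a 2x2 space matches the hand-summed four-term Boltzmann sum", {
  m <- new_energy_matrix(0.5, list(c(0, 1), c(0, 2)),
                         pairs = list(list(NULL, matrix(c(0, 0.3, -0.2, 3),
                                                        2, 2, byrow = TRUE)),
                                      NULL))
  energies <- c(0.5 + 0 + 0 + 0,      # (1,1): pair m[1,1] = 0
                0.5 + 0 + 2 + 0.3,    # (1,2): pair m[1,2] = 0.3
                0.5 + 1 + 0 - 0.2,    # (2,1): pair m[2,1] = -0.2
                0.5 + 1 + 2 + 3)      # (2,2): pair m[2,2] = 3
  z_hand <- sum(exp(-energies / RT_TEST))
  pf <- partition_function_exhaustive(m)
  expect_equal(pf$log10_lower, log10(z_hand), tolerance = 1e-12)
  pb <- partition_function_bounded(m, epsilon = 0.03)
  expect_lte(pb$log10_lower, log10(z_hand) + 1e-12)
  expect_gte(pb$log10_upper, log10(z_hand) - 1e-12)
})

test_that("bounded estimator brackets the exhaustive Z at the requested gap", {
  set.seed(101)
  for (rep in 1:30) {
    np <- sample(1:4, 1)
    nr <- sample(1:4, 1)
    m <- random_energy_matrix(np, nr)
    lz <- log10_Z_oracle(m)
    for (eps in c(0.03, 0.5, 0.99)) {
      pb <- partition_function_bounded(m, epsilon = eps)
      expect_lte(pb$log10_lower, lz + 1e-9)
      expect_gte(pb$log10_upper, lz - 1e-9)
      expect_lte(pf_relative_gap(pb), eps + 1e-12)
    }
  }
})

test_that("log-space accumulation survives extreme energies", {
  pf_low <- pf_from_energy(-100)
  pf_high <- pf_from_energy(1000)
  expect_true(is.finite(pf_low$log10_lower))
  expect_true(is.finite(pf_high$log10_lower))
  m <- new_energy_matrix(0, list(c(-100, 1000)))
  pb <- partition_function_bounded(m, epsilon = 0.03)
  expect_true(is.finite(pb$log10_lower))
  expect_gte(pb$log10_upper, pb$log10_lower)
})

test_that("the K* score combines the three ensembles conservatively", {
  score0 <- kstar_score(pf_from_energy(0), pf_from_energy(0),
                        pf_from_energy(0))
  expect_equal(score0$score, 0)
  expect_equal(score0$status, "OK")

  # log10 Z values of -5, 2, 3 give a score of -10
  e_of <- function(lz) -lz * RT_TEST * log(10)
  sc <- kstar_score(pf_from_energy(e_of(-5)), pf_from_energy(e_of(2)),
                    pf_from_energy(e_of(3)))
  expect_equal(sc$score, -10, tolerance = 1e-9)
})

test_that("a massless complex ensemble is flagged as complete disruption", {
  dead <- pf_from_energy(1e6)   # log10 Z ~ -7e5, far below the floor
  ok <- pf_from_energy(0)
  sc <- kstar_score(dead, ok, ok)
  expect_equal(sc$status, "COMPLETE_DISRUPTION")
  expect_true(is.na(sc$score))
  d <- delta_kstar(sc, kstar_score(ok, ok, ok))
  expect_true(d$complete_disruption)
  expect_equal(format(d), "X")
  # a massless unbound partner is outside the model
  expect_error(kstar_score(ok, dead, ok), "unbound")
  expect_error(delta_kstar(sc, sc), "wildtype")
})

test_that("score differences are plain subtraction; wildtype self-delta is 0", {
  e_of <- function(lz) -lz * RT_TEST * log(10)
  wt <- kstar_score(pf_from_energy(e_of(-2.54)), pf_from_energy(0),
                    pf_from_energy(0))
  mut <- kstar_score(pf_from_energy(e_of(-7.00)), pf_from_energy(0),
                     pf_from_energy(0))
  expect_equal(delta_kstar(mut, wt)$value, -4.46, tolerance = 1e-9)
  expect_equal(delta_kstar(wt, wt)$value, 0)
})

test_that("raising complex pair energies strictly lowers the K* score", {
  set.seed(11)
  m <- random_energy_matrix(3, 3)
  pa <- new_energy_matrix(0, list(rnorm(2)))
  pb <- new_energy_matrix(0, list(rnorm(2)))
  score_with <- function(delta) {
    mc <- m
    for (i in 1:2) {
      for (j in (i + 1):3) mc$pairs[[i]][[j]] <- mc$pairs[[i]][[j]] + delta
    }
    kstar_score(partition_function_bounded(mc, epsilon = 0.03),
                partition_function_bounded(pa, epsilon = 0.03),
                partition_function_bounded(pb, epsilon = 0.03))$score
  }
  base <- score_with(0)
  expect_lt(score_with(0.5), base)
  expect_lt(score_with(2), score_with(0.5))
})

test_that("epsilon outside (0,1) and oversized spaces are rejected", {
  m <- new_energy_matrix(0, list(c(0, 1)))
  expect_error(partition_function_bounded(m, epsilon = 0), "epsilon")
  expect_error(partition_function_bounded(m, epsilon = 1), "epsilon")
  big <- new_energy_matrix(0, rep(list(rep(0, 100)), 4))
  expect_error(partition_function_exhaustive(big, conf_cap = 1e6), "cap")
})
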