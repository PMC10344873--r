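# Partition functions over rotamer ensembles and the Log10 K* binding
# score. Boltzmann masses are carried in natural-log space throughout, so
# per-conformation energies anywhere in [-100, +1000] kcal/mol neither
# overflow nor underflow.

GAS_CONSTANT <- 0.0019872   # kcal / (mol K)
DEFAULT_TEMPERATURE <- 298.15
ZERO_MASS_LOG10 <- -300     # below this, an ensemble carries no usable mass

logaddexp <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

new_pf_result <- function(log_lower, log_upper, epsilon, n_enumerated,
                          n_total, temperature) {
  structure(list(log10_lower = log_lower / log(10),
                 log10_upper = log_upper / log(10),
                 epsilon_requested = epsilon,
                 n_enumerated = n_enumerated,
                 n_total = n_total,
                 temperature = temperature),
            class = "partition_function")
}

#' @export
print.partition_function <- function(x, ...) {
  cat(sprintf(paste0("partition function: log10 Z in [%.6g, %.6g], ",
                     "epsilon %.3g, %d/%s conformations enumerated, ",
                     "T = %.2f K\n"),
              x$log10_lower, x$log10_upper, x$epsilon_requested,
              x$n_enumerated, format(x$n_total), x$temperature))
  invisible(x)
}

#' Relative gap of a bounded partition function
#'
#' `(upper - lower) / upper`, computed stably in log space; 0 for an exact
#' result.
#' @param pf a `partition_function`.
#' @export
pf_relative_gap <- function(pf) {
  if (pf$log10_upper == -Inf) return(0)
  -expm1((pf$log10_lower - pf$log10_upper) * log(10))
}

#' Exhaustive partition function over a conformation space
#'
#' Brute-force Boltzmann sum `Z = sum exp(-E/RT)` over every full rotamer
#' assignment, accumulated in log space. Serves as the exact reference for
#' the epsilon-bounded estimator.
#'
#' @param m an `energy_matrix`.
#' @param temperature Kelvin (default 298.15).
#' @param conf_cap refuse spaces larger than this many conformations.
#' @return a `partition_function` with equal lower and upper bounds.
#' @export
partition_function_exhaustive <- function(m, temperature = DEFAULT_TEMPERATURE,
                                          conf_cap = 1e6) {
  stopifnot(inherits(m, "energy_matrix"))
  rt <- GAS_CONSTANT * temperature
  nc <- vapply(m$singles, length, integer(1))
  total <- prod(nc)
  if (total > conf_cap) {
    stop("conformation space has ", format(total), " conformations ",
         "(cap ", format(conf_cap), "); use partition_function_bounded()")
  }
  if (m$n_positions == 0L) {
    ll <- -m$template / rt
    return(new_pf_result(ll, ll, 0, 1L, 1L, temperature))
  }
  grid <- as.matrix(expand.grid(lapply(nc, seq_len)))
  energies <- apply(grid, 1L, function(idx) assignment_energy(m, idx))
  ll <- logsumexp(-energies / rt)
  new_pf_result(ll, ll, 0, nrow(grid), total, temperature)
}

# admissible heuristic: lower bound on the remaining singles+pairs energy
# given choices `assigned` at positions 1..k
bound_heuristic <- function(m, assigned) {
  np <- m$n_positions
  k <- length(assigned)
  if (k == np) return(0)
  h <- 0
  for (i in (k + 1L):np) {
    cost <- m$singles[[i]]
    if (k > 0L) {
      for (j in seq_len(k)) {
        cost <- cost + m$pairs[[j]][[i]][assigned[j], ]
      }
    }
    if (i < np) {
      for (j in (i + 1L):np) {
        cost <- cost + apply(m$pairs[[i]][[j]], 1L, min)
      }
    }
    h <- h + min(cost)
  }
  h
}

#' Epsilon-bounded partition function
#'
#' Best-first (A*-ordered) enumeration of full rotamer assignments using an
#' admissible lower bound on the energy of every completion. The Boltzmann
#' mass of the enumerated conformations is a lower bound on Z; the upper
#' bound adds (remaining conformation count) x exp(-f_min/RT), where f_min
#' is the smallest admissible bound on any non-enumerated conformation.
#' Enumeration stops as soon as `(upper - lower) <= epsilon * upper`, so the
#' exact Z is bracketed with relative gap at most `epsilon`. Ties in the
#' best-first order are broken by insertion (lexicographic choice-index)
#' order, making the enumeration deterministic.
#'
#' @param m an `energy_matrix`.
#' @param temperature Kelvin.
#' @param epsilon requested relative gap, in (0, 1); 0.03 matches the
#'   protocol default.
#' @return a `partition_function` with `lower <= Z_exact <= upper` and
#'   relative gap at termination at most `epsilon`.
#' @export
partition_function_bounded <- function(m, temperature = DEFAULT_TEMPERATURE,
                                       epsilon = 0.03) {
  stopifnot(inherits(m, "energy_matrix"))
  if (!(epsilon > 0 && epsilon < 1)) {
    stop("epsilon must lie strictly between 0 and 1")
  }
  rt <- GAS_CONSTANT * temperature
  np <- m$n_positions
  nc <- vapply(m$singles, length, integer(1))
  total <- prod(nc)
  if (np == 0L) {
    ll <- -m$template / rt
    return(new_pf_result(ll, ll, epsilon, 1L, 1L, temperature))
  }
  # leaves below a node at level k: prod of choice counts beyond k
  leaves_below <- rev(cumprod(rev(c(nc[-1], 1))))

  node_f <- m$template + bound_heuristic(m, integer(0))
  nodes <- list(list(assigned = integer(0), g = m$template))
  fs <- node_f
  order_id <- 1L
  ids <- 1L
  log_lower <- -Inf
  n_leaves <- 0L
  log_eps <- log(epsilon)

  repeat {
    if (length(fs) == 0L) {
      return(new_pf_result(log_lower, log_lower, epsilon, n_leaves, total,
                           temperature))
    }
    best <- which.min(fs)
    cand <- which(fs == fs[best])
    if (length(cand) > 1L) best <- cand[which.min(ids[cand])]
    node <- nodes[[best]]
    f_best <- fs[best]
    nodes[[best]] <- NULL
    fs <- fs[-best]
    ids <- ids[-best]

    k <- length(node$assigned)
    if (k == np) {
      n_leaves <- n_leaves + 1L
      log_lower <- logaddexp(log_lower, -f_best / rt)
    } else {
      i <- k + 1L
      for (ci in seq_len(nc[i])) {
        g <- node$g + m$singles[[i]][ci]
        if (k > 0L) {
          for (j in seq_len(k)) {
            g <- g + m$pairs[[j]][[i]][node$assigned[j], ci]
          }
        }
        assigned <- c(node$assigned, ci)
        f <- g + bound_heuristic(m, assigned)
        nodes[[length(nodes) + 1L]] <- list(assigned = assigned, g = g)
        fs <- c(fs, f)
        order_id <- order_id + 1L
        ids <- c(ids, order_id)
      }
    }

    n_rem <- total - n_leaves
    if (n_rem == 0L || length(fs) == 0L) {
      return(new_pf_result(log_lower, log_lower, epsilon, n_leaves, total,
                           temperature))
    }
    f_min <- min(fs)
    log_rem <- log(n_rem) - f_min / rt
    log_upper <- logaddexp(log_lower, log_rem)
    if (log_upper > -Inf && log_rem <= log_eps + log_upper) {
      return(new_pf_result(log_lower, log_upper, epsilon, n_leaves, total,
                           temperature))
    }
  }
}

#' Combine partition functions into a Log10 K* binding score
#'
#' `K* = Z_complex / (Z_A * Z_B)` reported on the log10 scale. The
#' conservative bound combination is used: the complex contributes its
#' lower bound, the unbound partners their upper bounds, so disruption
#' calls err toward caution. When the complex ensemble carries no Boltzmann
#' mass (all conformations clash-capped; log10 mass below -300) the status
#' is `COMPLETE_DISRUPTION` and no finite score exists.
#'
#' @param pf_complex,pf_A,pf_B `partition_function` results computed at the
#'   same temperature.
#' @return object of class `kstar_score`.
#' @export
kstar_score <- function(pf_complex, pf_A, pf_B) {
  for (pf in list(pf_complex, pf_A, pf_B)) {
    stopifnot(inherits(pf, "partition_function"))
  }
  temps <- c(pf_complex$temperature, pf_A$temperature, pf_B$temperature)
  if (max(temps) - min(temps) > 1e-9) {
    stop("partition functions computed at different temperatures")
  }
  if (pf_A$log10_lower < ZERO_MASS_LOG10 ||
      pf_B$log10_lower < ZERO_MASS_LOG10) {
    stop("an unbound partner has no Boltzmann mass; the unfolded state is ",
         "outside the model's scope")
  }
  disrupted <- pf_complex$log10_lower < ZERO_MASS_LOG10
  score <- if (disrupted) NA_real_ else {
    pf_complex$log10_lower - pf_A$log10_upper - pf_B$log10_upper
  }
  structure(list(log10_Z_complex = pf_complex$log10_lower,
                 log10_Z_A = pf_A$log10_upper,
                 log10_Z_B = pf_B$log10_upper,
                 score = score,
                 status = if (disrupted) "COMPLETE_DISRUPTION" else "OK",
                 temperature = pf_complex$temperature),
            class = "kstar_score")
}

#' @export
print.kstar_score <- function(x, ...) {
  if (x$status == "COMPLETE_DISRUPTION") {
    cat("K* score: X (complete disruption; complex ensemble has no mass)\n")
  } else {
    cat(sprintf("Log10 K* score: %.4f  (log10 Zc %.4g, Za %.4g, Zb %.4g)\n",
                x$score, x$log10_Z_complex, x$log10_Z_A, x$log10_Z_B))
  }
  invisible(x)
}

#' Mutant-vs-wildtype score difference
#'
#' The difference of the mutant Log10 K* score and the wildtype score from
#' the same scan run. A mutant with status `COMPLETE_DISRUPTION` yields the
#' sentinel value (printed `"X"`) instead of a number.
#'
#' @param mut,wt `kstar_score` objects; `wt` must have status `OK`.
#' @param mutation optional `mutation_spec` carried along for labelling.
#' @return object of class `delta_kstar` with elements `value` (`NA` when
#'   the sentinel applies), `complete_disruption`, `wildtype_score`.
#' @export
delta_kstar <- function(mut, wt, mutation = NULL) {
  stopifnot(inherits(mut, "kstar_score"), inherits(wt, "kstar_score"))
  if (wt$status == "COMPLETE_DISRUPTION") {
    stop("wildtype reference has no complex ensemble mass; ",
         "cannot compute score differences")
  }
  disrupted <- mut$status == "COMPLETE_DISRUPTION"
  structure(list(value = if (disrupted) NA_real_ else mut$score - wt$score,
                 complete_disruption = disrupted,
                 wildtype_score = wt$score,
                 mutation = mutation),
            class = "delta_kstar")
}

#' @export
print.delta_kstar <- function(x, ...) {
  lab <- if (!is.null(x$mutation)) paste0(x$mutation$label, ": ") else ""
  if (x$complete_disruption) {
    cat(lab, "delta K* = X (complete disruption)\n", sep = "")
  } else {
    cat(sprintf("%sdelta K* = %.4f (wildtype %.4f)\n", lab, x$value,
                x$wildtype_score))
  }
  invisible(x)
}

#' @export
format.delta_kstar <- function(x, digits = 2, ...) {
  if (x$complete_disruption) "X" else formatC(x$value, digits = digits,
                                              format = "f")
}
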