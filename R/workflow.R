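# Scan orchestration: YAML job specification, per-mutation conformation
# spaces -> energy matrices -> bounded partition functions -> K* -> score
# differences -> triage -> probabilities, with deterministic outputs.

JOB_KEYS <- c("structure_path", "partner_a_chains", "partner_b_chains",
              "mutable", "allowed_mutations", "pair_mode", "epsilon",
              "temperature", "triage", "interface_cutoff", "shell_radius",
              "cancer_type", "gene_path", "signatures_path", "weights_path",
              "seed")

#' Load and validate a YAML job specification
#'
#' @param yaml_text YAML text or path to a YAML file. Recognised keys:
#'   `structure_path`, `partner_a_chains`, `partner_b_chains`, `mutable`
#'   (list of `"CHAIN:RESNUM[:ICODE]"` or `"auto-interface"`),
#'   `allowed_mutations` (1-letter codes, `"ALL"`, or a per-site map),
#'   `pair_mode`, `epsilon` (default 0.03), `temperature` (default 298.15),
#'   `triage` (map with `cutoff`, `his_rule`, `exclude_triples`),
#'   `interface_cutoff` (default 5), `shell_radius` (default 12),
#'   `cancer_type`, `gene_path`, `signatures_path`, `weights_path`, `seed`.
#'   Unknown keys are rejected.
#' @return object of class `job_spec`.
#' @export
load_job <- function(yaml_text) {
  y <- if (length(yaml_text) == 1L && !grepl("\n", yaml_text) &&
           file.exists(yaml_text)) {
    yaml::read_yaml(yaml_text)
  } else {
    yaml::yaml.load(paste(yaml_text, collapse = "\n"))
  }
  if (!is.list(y)) stop("job YAML must be a mapping")
  unknown <- setdiff(names(y), JOB_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown job key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(y$structure_path)) stop("job is missing 'structure_path'")
  if (is.null(y$partner_a_chains) || is.null(y$partner_b_chains)) {
    stop("job must name partner_a_chains and partner_b_chains")
  }
  epsilon <- y$epsilon %||% 0.03
  if (!(epsilon > 0 && epsilon < 1)) {
    stop("epsilon must lie strictly in (0, 1), got ", epsilon)
  }
  shell_radius <- y$shell_radius %||% 12
  if (!(shell_radius > 0)) stop("shell_radius must be positive")
  tri <- y$triage %||% list()
  cfg <- triage_config(cutoff = tri$cutoff %||% -3,
                       his_rule = tri$his_rule %||% TRUE,
                       exclude_triples = tri$exclude_triples %||% TRUE)
  mutable <- y$mutable %||% "auto-interface"
  pair_mode <- isTRUE(y$pair_mode)
  if (pair_mode && !identical(mutable, "auto-interface") &&
      length(unlist(mutable)) != 2L) {
    stop("pair_mode requires exactly 2 mutable sites")
  }
  cancer_type <- y$cancer_type
  if (!is.null(cancer_type) &&
      (is.null(y$gene_path) || is.null(y$signatures_path) ||
         is.null(y$weights_path))) {
    stop("cancer_type is set: gene_path, signatures_path and weights_path ",
         "are required")
  }
  structure(list(structure_path = y$structure_path,
                 partner_a_chains = as.character(unlist(y$partner_a_chains)),
                 partner_b_chains = as.character(unlist(y$partner_b_chains)),
                 mutable = mutable,
                 allowed_mutations = y$allowed_mutations %||% "ALL",
                 pair_mode = pair_mode,
                 epsilon = epsilon,
                 temperature = y$temperature %||% DEFAULT_TEMPERATURE,
                 triage = cfg,
                 interface_cutoff = y$interface_cutoff %||% 5,
                 shell_radius = shell_radius,
                 cancer_type = cancer_type,
                 gene_path = y$gene_path,
                 signatures_path = y$signatures_path,
                 weights_path = y$weights_path,
                 seed = y$seed %||% 1L),
            class = "job_spec")
}

#' @export
print.job_spec <- function(x, ...) {
  cat("job_spec:", x$structure_path, "\n")
  cat("  partners:", paste(x$partner_a_chains, collapse = ","), "vs",
      paste(x$partner_b_chains, collapse = ","), "\n")
  cat("  epsilon:", x$epsilon, " T:", x$temperature, "K  cutoff:",
      x$triage$cutoff, "\n")
  invisible(x)
}

# 32-bit FNV-1a hash of a string, for provenance stamping.
# Kept in two 16-bit halves so the arithmetic stays inside R's integers.
fnv1a <- function(txt) {
  hi <- 33052; lo <- 40389   # 2166136261 = 33052 * 65536 + 40389
  for (b in utf8ToInt(txt)) {
    lo <- bitwXor(lo, b)
    # multiply (hi,lo) by the FNV prime 16777619 = 256 * 65536 + 403
    new_lo <- lo * 403
    new_hi <- (hi * 403 + lo * 256 + new_lo %/% 65536) %% 65536
    hi <- new_hi
    lo <- new_lo %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

allowed_for_site <- function(job, key) {
  al <- job$allowed_mutations
  if (is.character(al) && length(al) >= 1L && !is.list(al)) return(al)
  if (is.list(al)) {
    if (!is.null(al[[key]])) return(unlist(al[[key]]))
    stop("no allowed mutations listed for site ", key)
  }
  stop("allowed_mutations must be codes, 'ALL', or a per-site map")
}

# score one sequence (types per position) on precomputed matrices
score_sequence <- function(mats, types_by_site, epsilon, temperature) {
  pick <- function(m) {
    if (m$n_positions == 0L) return(m)
    restrict_energy_matrix(m, lapply(m$sites, function(sk)
      types_by_site[[sk]]))
  }
  kstar_score(
    partition_function_bounded(pick(mats$complex), temperature, epsilon),
    partition_function_bounded(pick(mats$partner_A), temperature, epsilon),
    partition_function_bounded(pick(mats$partner_B), temperature, epsilon))
}

offset_complex <- function(mats, offset) {
  if (is.null(offset) || offset == 0) return(mats)
  mats$complex$template <- mats$complex$template + offset
  mats
}

#' Run a full interface mutation scan
#'
#' The end-to-end protocol: read the complex, detect the binding interface,
#' trim to the retention shell, and for every allowed mutation at every
#' mutable site build the three conformation spaces, compute energy
#' matrices, evaluate epsilon-bounded partition functions, form the Log10
#' K* score and its difference to the same-run wildtype score, apply the
#' triage rules, and (when a cancer type is set) attach signature-derived
#' relative probabilities and a prioritised hotspot table. Per-mutation
#' failures are recorded and skipped; a wildtype failure is fatal.
#'
#' @param job a `job_spec` from [load_job()], or a path/YAML text accepted
#'   by it.
#' @param structure optionally, an already-read `kstar_structure` (the
#'   job's `structure_path` is then ignored).
#' @param complex_offsets optional data frame (`site`, `target_aa`,
#'   `offset`) adding a known energy offset to the mutant complex template
#'   — the hook used by synthetic fixtures with engineered disruptions.
#' @return object of class `kstar_scan`: `calls` (data frame), `hotspots`,
#'   `heatmap`, `priorities`, `probabilities`, `wildtype` (per-site scores),
#'   `failures`, `job`, `provenance`.
#' @export
run_scan <- function(job, structure = NULL, complex_offsets = NULL) {
  if (!inherits(job, "job_spec")) job <- load_job(job)
  set.seed(job$seed)
  s <- structure %||% read_structure(job$structure_path,
                                     job$partner_a_chains,
                                     job$partner_b_chains)
  iface <- find_interface_residues(s, job$interface_cutoff)
  if (identical(job$mutable, "auto-interface")) {
    mutable <- Filter(function(k) {
      is_protein_restype(s$sites$restype[s$sites$site == k])
    }, iface)
  } else {
    mutable <- as.character(unlist(job$mutable))
    bad <- setdiff(mutable, s$sites$site)
    if (length(bad) > 0L) {
      stop("mutable site(s) not found: ", paste(bad, collapse = ", "))
    }
  }
  if (length(mutable) == 0L) stop("no mutable sites (empty interface?)")
  if (length(iface) > 0L) s <- trim_to_shell(s, iface, job$shell_radius)
  mutable <- mutable[mutable %in% s$sites$site]

  gene <- if (!is.null(job$gene_path)) read_gene_fasta(job$gene_path)
  catalog <- if (!is.null(job$signatures_path)) {
    read_signature_catalog(job$signatures_path)
  }
  weights <- if (!is.null(job$weights_path)) {
    read_cancer_weights(job$weights_path)
  }

  if (job$pair_mode) {
    if (length(mutable) != 2L) {
      stop("pair_mode requires exactly 2 mutable sites, got ",
           length(mutable))
    }
    return(run_pair_scan(job, s, mutable, gene, catalog, weights))
  }

  calls <- list()
  probs <- list()
  wt_rows <- list()
  failures <- data.frame(label = character(), error = character(),
                         stringsAsFactors = FALSE)

  for (key in mutable) {
    srow <- s$sites[s$sites$site == key, ]
    muts <- enumerate_mutations(srow, allowed_for_site(job, key))
    wt_spec <- muts[[1]]
    targets <- Filter(function(m) !m$is_reference, muts)
    # group histidine protonation variants under one mutation
    groups <- split(targets, vapply(targets, function(m) m$target_aa,
                                    character(1)))
    groups <- groups[order(match(names(groups),
                                 vapply(targets, function(m) m$target_aa,
                                        character(1))))]

    wt_score <- tryCatch({
      spaces <- build_conf_spaces(s, key, mutation = NULL)
      mats <- lapply(spaces, compute_energy_matrix)
      types <- stats::setNames(list(toupper(srow$restype)), key)
      score_sequence(mats, types, job$epsilon, job$temperature)
    }, error = function(e) {
      stop("wildtype scoring failed at site ", key, ": ",
           conditionMessage(e))
    })
    wt_delta <- delta_kstar(wt_score, wt_score, wt_spec)
    wt_rows[[length(wt_rows) + 1L]] <-
      data.frame(site = key, resnum = srow$resnum,
                 wildtype = wt_spec$wildtype_aa, score = wt_score$score,
                 self_delta = wt_delta$value, stringsAsFactors = FALSE)

    for (grp in groups) {
      m0 <- grp[[1]]
      res <- tryCatch({
        deltas <- lapply(grp, function(m) {
          spaces <- build_conf_spaces(s, key, mutation = m)
          mats <- lapply(spaces, compute_energy_matrix)
          off <- NULL
          if (!is.null(complex_offsets)) {
            hit <- complex_offsets$site == key &
              complex_offsets$target_aa == m$target_aa
            if (any(hit)) off <- sum(complex_offsets$offset[hit])
          }
          tr <- target_restype(m$target_aa, m$protonation_variant)
          # the engineered offset applies to the mutant complex only
          mut_score <- score_sequence(
            offset_complex(mats, off), stats::setNames(list(tr), key),
            job$epsilon, job$temperature)
          # wildtype reference from the same run / same conformation space
          wt_here <- score_sequence(
            mats, stats::setNames(list(toupper(srow$restype)), key),
            job$epsilon, job$temperature)
          delta_kstar(mut_score, wt_here, m)
        })
        path_class <- NA_character_
        if (!is.null(gene) && srow$resnum >= 1 &&
            srow$resnum <= gene$n_codons) {
          path_class <- tryCatch({
            cp <- codon_paths(substr(gene$sequence,
                                     3 * (srow$resnum - 1) + 1,
                                     3 * (srow$resnum - 1) + 3),
                              m0$target_aa)
            nmin <- min(vapply(cp, function(p) p$n_changes, integer(1)))
            c("single", "double", "triple")[nmin]
          }, error = function(e) NA_character_)
        }
        meta <- m0
        meta$label <- sub("\\.H[123]$", "", m0$label)
        classify_disruption(deltas, path_class, job$triage,
                            mutation = meta)
      }, error = function(e) e)
      # the probability stage must not void a scoring result
      if (!inherits(res, "error") && !is.null(job$cancer_type) &&
          !is.null(gene) && srow$resnum >= 1 &&
          srow$resnum <= gene$n_codons) {
        pres <- tryCatch(
          mutation_probability(gene, srow$resnum, m0$target_aa, weights,
                               catalog),
          error = function(e) e)
        if (inherits(pres, "error")) {
          failures <- rbind(failures, data.frame(
            label = paste0(m0$label, " (probability)"),
            error = conditionMessage(pres), stringsAsFactors = FALSE))
        } else {
          probs[[length(probs) + 1L]] <- pres
        }
      }
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(label = m0$label,
                                     error = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      } else {
        calls[[length(calls) + 1L]] <- res
      }
    }
  }

  finish_scan(job, calls, probs, wt_rows, failures, pair_mode = FALSE)
}

finish_scan <- function(job, calls, probs, wt_rows, failures, pair_mode) {
  hotspots <- hotspot_rank(calls, top_k = 3)
  heat <- if (!pair_mode && length(calls) > 0L) heatmap_matrix(calls)
  prob_table <- if (length(probs) > 0L) rank_probabilities(probs)
  priorities <- if (length(calls) > 0L) {
    if (!is.null(job$cancer_type) && !is.null(prob_table)) {
      # fall back to score ordering if a probability is missing
      tryCatch(prioritize(calls, hotspots, prob_table),
               error = function(e) prioritize(calls, hotspots))
    } else {
      prioritize(calls, hotspots)
    }
  }
  cfg_yaml <- yaml::as.yaml(unclass(job)[!vapply(unclass(job), is.null,
                                                 logical(1))])
  structure(list(calls = calls_table(calls),
                 call_objects = calls,
                 hotspots = hotspots,
                 heatmap = heat,
                 priorities = priorities,
                 probabilities = prob_table,
                 wildtype = do.call(rbind, wt_rows),
                 failures = failures,
                 job = job,
                 provenance = list(seed = job$seed, epsilon = job$epsilon,
                                   temperature = job$temperature,
                                   package_version =
                                     as.character(utils::packageVersion("kstarscan")),
                                   config_hash = fnv1a(cfg_yaml),
                                   config_yaml = cfg_yaml)),
            class = "kstar_scan")
}

calls_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(site = character(), resnum = integer(),
                      wildtype = character(), target = character(),
                      label = character(), n_variants = integer(),
                      delta_1 = numeric(), delta_2 = numeric(),
                      delta_3 = numeric(), x_1 = logical(), x_2 = logical(),
                      x_3 = logical(), path_class = character(),
                      verdict = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(cl) {
    v <- cl$values
    x <- is.na(v)
    v3 <- c(v, rep(NA_real_, 3 - length(v)))
    x3 <- c(x, rep(NA, 3 - length(x)))
    data.frame(site = cl$site, resnum = as.integer(cl$resnum),
               wildtype = cl$wildtype_aa, target = cl$target_aa,
               label = cl$label, n_variants = length(v),
               delta_1 = v3[1], delta_2 = v3[2], delta_3 = v3[3],
               x_1 = x3[1], x_2 = x3[2], x_3 = x3[3],
               path_class = cl$path_class, verdict = cl$verdict,
               reason = cl$reason, stringsAsFactors = FALSE)
  }))
}

# two-site simultaneous scan: every combination of allowed targets at the
# two sites scored as a double mutant against the same-run wildtype
run_pair_scan <- function(job, s, mutable, gene, catalog, weights) {
  rows <- lapply(mutable, function(k) s$sites[s$sites$site == k, ])
  muts <- lapply(seq_along(mutable), function(i) {
    enumerate_mutations(rows[[i]], allowed_for_site(job, mutable[i]))
  })
  wt_types <- stats::setNames(lapply(rows, function(r) toupper(r$restype)),
                              mutable)
  spaces <- build_conf_spaces(s, mutable, mutation = NULL)
  mats <- lapply(spaces, compute_energy_matrix)
  wt_score <- score_sequence(mats, wt_types, job$epsilon, job$temperature)
  wt_rows <- list(data.frame(site = paste(mutable, collapse = "+"),
                             resnum = NA_integer_,
                             wildtype = paste(vapply(muts, function(m)
                               m[[1]]$wildtype_aa, character(1)),
                               collapse = "+"),
                             score = wt_score$score,
                             self_delta =
                               delta_kstar(wt_score, wt_score)$value,
                             stringsAsFactors = FALSE))
  calls <- list()
  failures <- data.frame(label = character(), error = character(),
                         stringsAsFactors = FALSE)
  t1 <- Filter(function(m) !m$is_reference, muts[[1]])
  t2 <- Filter(function(m) !m$is_reference, muts[[2]])
  for (m1 in t1) {
    for (m2 in t2) {
      label <- paste(m1$label, m2$label, sep = "+")
      res <- tryCatch({
        sp <- build_conf_spaces(s, mutable, mutation = list(m1, m2))
        mm <- lapply(sp, compute_energy_matrix)
        types <- stats::setNames(
          list(target_restype(m1$target_aa, m1$protonation_variant),
               target_restype(m2$target_aa, m2$protonation_variant)),
          c(m1$site, m2$site))
        mut_score <- score_sequence(mm, types, job$epsilon, job$temperature)
        wt_here <- score_sequence(mm, wt_types, job$epsilon,
                                  job$temperature)
        d <- delta_kstar(mut_score, wt_here)
        meta <- list(site = paste(m1$site, m2$site, sep = "+"),
                     resnum = m1$resnum, wildtype_aa =
                       paste(m1$wildtype_aa, m2$wildtype_aa, sep = "+"),
                     target_aa = paste(m1$target_aa, m2$target_aa,
                                       sep = "+"),
                     label = label)
        classify_disruption(list(d), NA_character_, job$triage,
                            mutation = meta)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures, data.frame(
          label = label, error = conditionMessage(res),
          stringsAsFactors = FALSE))
      } else {
        calls[[length(calls) + 1L]] <- res
      }
    }
  }
  finish_scan(job, calls, list(), wt_rows, failures, pair_mode = TRUE)
}

#' Write scan outputs as CSV tables
#'
#' Writes the calls table, hotspot report, heatmap matrix, priority table
#' and probability table (when present) under `dir`, each with a provenance
#' header comment carrying the config hash and seed so the same-run pairing
#' of scores is reproducible.
#'
#' @param x a `kstar_scan`.
#' @param dir output directory.
#' @export
write_scan <- function(x, dir) {
  stopifnot(inherits(x, "kstar_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# kstarscan %s  seed=%s  epsilon=%s  config=%s",
                 x$provenance$package_version, x$provenance$seed,
                 x$provenance$epsilon, x$provenance$config_hash)
  emit <- function(d, file, row_names = FALSE) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(d, con, row.names = row_names)
    close(con)
  }
  emit(x$calls, "calls.csv")
  emit(x$hotspots$counts, "hotspots.csv")
  if (!is.null(x$heatmap)) emit(as.data.frame(x$heatmap), "heatmap.csv",
                                row_names = TRUE)
  if (!is.null(x$priorities)) emit(x$priorities, "priorities.csv")
  if (!is.null(x$probabilities)) emit(x$probabilities, "probabilities.csv")
  if (nrow(x$failures) > 0) emit(x$failures, "failures.csv")
  invisible(dir)
}

#' @export
print.kstar_scan <- function(x, ...) {
  n <- nrow(x$calls)
  cat("kstar_scan:", n, "mutation(s) scored,",
      sum(x$calls$verdict == "disruptive"), "disruptive,",
      sum(x$calls$verdict == "excluded_triple"), "excluded (triple),",
      nrow(x$failures), "failed\n")
  if (length(x$hotspots$top) > 0) {
    cat("top hotspot position(s):", paste(x$hotspots$top, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.kstar_scan <- function(object, ...) {
  cat("Interface mutation scan (epsilon ", object$provenance$epsilon,
      ", T ", object$provenance$temperature, " K, seed ",
      object$provenance$seed, ")\n\n", sep = "")
  print(object)
  cat("\nWildtype Log10 K* per scanned site:\n")
  print(object$wildtype, row.names = FALSE)
  if (!is.null(object$priorities) && nrow(object$priorities) > 0) {
    cat("\nPrioritised hotspot mutations:\n")
    print(object$priorities, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.kstar_scan <- function(x, ...) x$calls

#' Heatmap of score differences across the scanned interface
#'
#' Base-graphics rendering of the scan's heatmap matrix: rows are target
#' residues (H1-H3 the histidine protonation variants), columns scanned
#' positions; wildtype cells are marked black, triple-excluded cells grey.
#'
#' @param x a `kstar_scan`.
#' @param ... ignored.
#' @export
plot.kstar_scan <- function(x, ...) {
  if (is.null(x$heatmap)) stop("scan has no heatmap (pair mode?)")
  h <- x$heatmap
  num <- suppressWarnings(matrix(as.numeric(h), nrow(h), ncol(h)))
  z <- num
  rng <- range(num, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(-1, 0)
  z[h == "X"] <- rng[1]
  pal <- grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE)
  graphics::image(seq_len(ncol(h)), seq_len(nrow(h)), t(z),
                  col = pal, axes = FALSE, xlab = "scanned position",
                  ylab = "target residue", ...)
  wt <- which(h == "wt", arr.ind = TRUE)
  if (nrow(wt)) graphics::points(wt[, 2], wt[, 1], pch = 15, col = "black")
  tri <- which(h == "triple", arr.ind = TRUE)
  if (nrow(tri)) graphics::points(tri[, 2], tri[, 1], pch = 15,
                                  col = "grey")
  graphics::axis(1, seq_len(ncol(h)), colnames(h), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(h)), rownames(h), las = 1, cex.axis = 0.6)
  invisible(x)
}
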