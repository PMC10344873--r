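# Turning score differences into disruption verdicts, hotspot counts and
# ranked outputs.

#' Triage configuration
#'
#' @param cutoff disruption cutoff on the Log10 K* difference (default -3):
#'   a mutation disrupts binding when its score drops by at least 3 log10
#'   units relative to wildtype, i.e. `delta <= cutoff` (closed boundary).
#'   Adaptable at the user's discretion.
#' @param his_rule when `TRUE` (default) a histidine mutation counts as
#'   disruptive only if all three protonation variants disrupt; when
#'   `FALSE` a single disrupting variant suffices.
#' @param exclude_triples when `TRUE` (default) mutations reachable only by
#'   substituting all three codon bases are discarded.
#' @export
triage_config <- function(cutoff = -3, his_rule = TRUE,
                          exclude_triples = TRUE) {
  if (!(cutoff < 0)) stop("cutoff must be negative (a score decrease)")
  structure(list(cutoff = cutoff, his_rule = isTRUE(his_rule),
                 exclude_triples = isTRUE(exclude_triples)),
            class = "triage_config")
}

# normalise deltas to a numeric vector where NA encodes the complete-
# disruption sentinel
delta_values <- function(deltas) {
  if (inherits(deltas, "delta_kstar")) deltas <- list(deltas)
  if (is.list(deltas)) {
    vapply(deltas, function(d) {
      if (inherits(d, "delta_kstar")) {
        if (d$complete_disruption) NA_real_ else d$value
      } else {
        as.numeric(d)
      }
    }, numeric(1))
  } else {
    as.numeric(deltas)
  }
}

#' Classify a mutation as binding-disrupting or not
#'
#' A variant disrupts when its score difference is at or below the cutoff,
#' or when the mutant complex ensemble carried no Boltzmann mass at all
#' (complete disruption, encoded `NA`). The mutation-level verdict is
#' `disruptive` only when every variant disrupts (histidine all-three
#' rule); mutations whose DNA paths all require a triple contiguous codon
#' substitution are `excluded_triple` regardless of score.
#'
#' @param deltas numeric vector of score differences (NA = complete
#'   disruption), or a list of `delta_kstar` objects; length 1, or 3 for
#'   histidine protonation variants.
#' @param path_class `"single"`, `"double"` or `"triple"` (minimum codon
#'   path class); `NA` when no gene information is available.
#' @param cfg a [triage_config()].
#' @param mutation optional `mutation_spec`-like metadata (needs `site`,
#'   `resnum`, `wildtype_aa`, `target_aa`, `label`).
#' @return object of class `disruption_call`.
#' @export
classify_disruption <- function(deltas, path_class = NA_character_,
                                cfg = triage_config(), mutation = NULL) {
  stopifnot(inherits(cfg, "triage_config"))
  v <- delta_values(deltas)
  if (length(v) == 0L) stop("empty score-difference list")
  if (!length(v) %in% c(1L, 3L)) {
    stop("expected 1 score difference, or 3 for histidine variants; got ",
         length(v))
  }
  disrupts <- is.na(v) | v <= cfg$cutoff
  if (!is.na(path_class) && path_class == "triple" && cfg$exclude_triples) {
    verdict <- "excluded_triple"
    reason <- "all codon paths require a triple contiguous substitution"
  } else if (length(v) == 3L && cfg$his_rule) {
    verdict <- if (all(disrupts)) "disruptive" else "non_disruptive"
    reason <- if (all(disrupts)) {
      "all three protonation variants at or below cutoff"
    } else {
      paste0(sum(!disrupts), " protonation variant(s) above cutoff")
    }
  } else {
    hit <- if (length(v) == 3L) any(disrupts) else all(disrupts)
    verdict <- if (hit) "disruptive" else "non_disruptive"
    reason <- if (any(is.na(v))) {
      "complete disruption of the complex ensemble"
    } else if (hit) {
      sprintf("score difference %.4g at or below cutoff %.3g", min(v),
              cfg$cutoff)
    } else {
      sprintf("score difference %.4g above cutoff %.3g", min(v), cfg$cutoff)
    }
  }
  structure(list(mutation = mutation,
                 site = mutation$site %||% NA_character_,
                 resnum = mutation$resnum %||% NA_integer_,
                 wildtype_aa = mutation$wildtype_aa %||% NA_character_,
                 target_aa = mutation$target_aa %||% NA_character_,
                 label = mutation$label %||% NA_character_,
                 values = v, path_class = path_class,
                 verdict = verdict, reason = reason),
            class = "disruption_call")
}

#' @export
print.disruption_call <- function(x, ...) {
  vals <- ifelse(is.na(x$values), "X", formatC(x$values, format = "f",
                                               digits = 2))
  cat(if (!is.na(x$label)) paste0(x$label, ": ") else "",
      x$verdict, " [", paste(vals, collapse = ", "), "] — ", x$reason,
      "\n", sep = "")
  invisible(x)
}

#' Rank residue positions into mutational hotspots
#'
#' Counts disruptive mutations per residue position; positions with the
#' highest counts are the mutational hotspots. Ranking is descending by
#' count with ties broken by ascending residue number.
#'
#' @param calls list of `disruption_call` objects.
#' @param top_k how many top positions to report (default 3).
#' @return object of class `hotspot_report` with `counts` (data frame),
#'   `ranking` (site keys) and `top` (the first `top_k`).
#' @export
hotspot_rank <- function(calls, top_k = 3) {
  dis <- Filter(function(cl) cl$verdict == "disruptive", calls)
  if (length(dis) == 0L) {
    counts <- data.frame(site = character(), resnum = integer(),
                         count = integer(), stringsAsFactors = FALSE)
  } else {
    d <- data.frame(site = vapply(dis, function(cl) cl$site, character(1)),
                    resnum = vapply(dis, function(cl) as.integer(cl$resnum),
                                    integer(1)),
                    stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = d$site), by = list(site = d$site),
                            FUN = length)
    agg$resnum <- d$resnum[match(agg$site, d$site)]
    counts <- agg[order(-agg$count, agg$resnum), c("site", "resnum", "count")]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, ranking = counts$site,
                 top = utils::head(counts$site, top_k), top_k = top_k),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("mutational hotspots (", nrow(x$counts), " positions with disruptive ",
      "mutations; top ", x$top_k, "):\n", sep = "")
  if (nrow(x$counts) > 0) {
    print(utils::head(x$counts, max(x$top_k, 5)), row.names = FALSE)
  }
  invisible(x)
}

heatmap_rows <- function() {
  rows <- character(0)
  for (aa in sort(names(AA3))) {
    if (aa == "H") rows <- c(rows, "H1", "H2", "H3") else rows <- c(rows, aa)
  }
  rows
}

#' Heatmap-ready matrix of score differences
#'
#' Rows are target residues (histidine expanded into the H1-H3 protonation
#' variants), columns the scanned positions. Cells carry the formatted
#' score difference, `"X"` for complete disruption, `"wt"` marking the
#' wildtype reference, `"triple"` for excluded triple-contiguous mutations,
#' and `""` where nothing was scanned.
#'
#' @param calls list of `disruption_call` objects from one scan.
#' @return character matrix (21 rows x scanned positions).
#' @export
heatmap_matrix <- function(calls) {
  rows <- heatmap_rows()
  sites <- unique(vapply(calls, function(cl) cl$site, character(1)))
  resnum <- vapply(calls, function(cl) as.integer(cl$resnum), integer(1))
  ord <- order(resnum[match(sites, vapply(calls, function(cl) cl$site,
                                          character(1)))])
  sites <- sites[ord]
  labels <- vapply(sites, function(sk) {
    cl <- calls[[which(vapply(calls, function(c2) c2$site, character(1)) ==
                         sk)[1]]]
    paste0(cl$wildtype_aa, cl$resnum)
  }, character(1))
  m <- matrix("", nrow = length(rows), ncol = length(sites),
              dimnames = list(rows, unname(labels)))
  seen <- character(0)
  for (cl in calls) {
    col <- which(sites == cl$site)
    rr <- if (cl$target_aa == "H") c("H1", "H2", "H3") else cl$target_aa
    key <- paste(cl$site, cl$target_aa)
    if (key %in% seen) {
      stop("duplicate call for target ", cl$target_aa, " at ", cl$site)
    }
    seen <- c(seen, key)
    if (cl$verdict == "excluded_triple") {
      m[rr, col] <- "triple"
    } else {
      m[rr, col] <- ifelse(is.na(cl$values), "X",
                           formatC(cl$values, format = "f", digits = 2))
    }
    # wildtype reference cell(s), marked without a number
    wr <- if (cl$wildtype_aa == "H") c("H1", "H2", "H3") else cl$wildtype_aa
    m[wr, col] <- "wt"
  }
  m
}

#' Prioritised table of disruptive hotspot mutations
#'
#' Disruptive mutations at the top hotspot positions, ordered by relative
#' probability of formation (descending) when probabilities are available,
#' or by score difference (ascending, complete disruption first) when no
#' cancer type applies.
#'
#' @param calls list of `disruption_call` objects.
#' @param hotspots a `hotspot_report`.
#' @param probs optional data frame from [rank_probabilities()] (or a list
#'   of `mutation_probability`), required to cover every disruptive
#'   mutation at the top hotspot positions.
#' @return data frame, one row per prioritised mutation.
#' @export
prioritize <- function(calls, hotspots, probs = NULL) {
  stopifnot(inherits(hotspots, "hotspot_report"))
  keep <- Filter(function(cl) cl$verdict == "disruptive" &&
                   cl$site %in% hotspots$top, calls)
  if (length(keep) == 0L) {
    return(data.frame(site = character(), label = character(),
                      resnum = integer(), target_aa = character(),
                      delta = numeric(), complete_disruption = logical(),
                      relative_probability = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(probs) && is.list(probs) && !is.data.frame(probs)) {
    probs <- rank_probabilities(probs)
  }
  d <- do.call(rbind, lapply(keep, function(cl) {
    data.frame(site = cl$site, label = cl$label,
               resnum = as.integer(cl$resnum), target_aa = cl$target_aa,
               delta = suppressWarnings(min(cl$values, na.rm = !all(
                 is.na(cl$values)))),
               complete_disruption = any(is.na(cl$values)),
               stringsAsFactors = FALSE)
  }))
  d$delta[d$complete_disruption] <- NA_real_
  if (!is.null(probs)) {
    idx <- match(paste(d$resnum, d$target_aa),
                 paste(probs$protein_position, probs$target_aa))
    if (anyNA(idx)) {
      stop("missing relative probability for mutation(s): ",
           paste(d$label[is.na(idx)], collapse = ", "))
    }
    d$relative_probability <- probs$relative_probability[idx]
    ord <- order(-ifelse(is.na(d$relative_probability), -Inf,
                         d$relative_probability), d$resnum, d$target_aa)
  } else {
    d$relative_probability <- NA_real_
    key <- ifelse(d$complete_disruption, -Inf, d$delta)
    ord <- order(key, d$resnum, d$target_aa)
  }
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}
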