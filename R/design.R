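#' Score a candidate substitution
#'
#' Combines flexibility and conservation evidence into a single ranking
#' value: `w1 * min(b_norm / b_cap, 1) + w2 * consensus_freq`. The score is
#' a deterministic tie-ordering aid for reports, never a filter.
#'
#' @param b_norm normalized B-factor at the position.
#' @param consensus_freq plurality frequency of the proposed residue.
#' @param weights length-2 non-negative weights summing to 1
#'   (default `c(0.5, 0.5)`).
#' @param b_cap cap applied to `b_norm` before weighting (default 3.0, i.e.
#'   flexibility saturates three standard deviations above the mean).
#' @return numeric score.
#' @export
#' @examples
#' score_candidate(3.0, 1.0)  # 1, the maximum attainable
score_candidate <- function(b_norm, consensus_freq, weights = c(0.5, 0.5),
                            b_cap = 3.0) {
  if (any(weights < 0)) stop("invalid weights: must be non-negative",
                             call. = FALSE)
  if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-8)
    stop("invalid weights: must be two values summing to 1", call. = FALSE)
  weights[1L] * pmin(b_norm / b_cap, 1) + weights[2L] * consensus_freq
}

#' Propose stabilizing substitutions from flexibility and consensus
#'
#' Intersects detected flexible regions with alignment consensus: every
#' flexible position whose mapped alignment column has a plurality residue
#' different from the query residue, and which passes the conservation and
#' gap filters, yields one candidate substitution toward the consensus
#' residue. Positions where the consensus equals the wild type yield
#' nothing. Flexible positions not covered by the query (alignment gaps)
#' are skipped with a warning. Proposed cysteines are flagged (possible
#' unpaired-disulfide risk) but not suppressed.
#'
#' @param profile a `bfactor_profile` for the structure chain.
#' @param regions flexible regions from [detect_flexible_regions()].
#' @param alignment an `aa_alignment` containing the query row.
#' @param qmap a `query_column_map` from [map_query_to_columns()].
#' @param min_consensus_freq minimum plurality frequency (default 0.5).
#' @param max_gap_frac maximum column gap fraction (default 0.5).
#' @param weights,b_cap passed to [score_candidate()].
#' @return a `data.frame` of class `mutation_candidates`, sorted by score
#'   (descending; ties by position ascending), with columns `label` (e.g.
#'   `"K64N"`), `position`, `wt_aa`, `proposed_aa`, `b_norm`,
#'   `consensus_freq`, `gap_frac`, `score`, `cys_flag`.
#' @export
propose_mutations <- function(profile, regions, alignment, qmap,
                              min_consensus_freq = 0.5, max_gap_frac = 0.5,
                              weights = c(0.5, 0.5), b_cap = 3.0) {
  stopifnot(inherits(profile, "bfactor_profile"),
            inherits(alignment, "aa_alignment"),
            inherits(qmap, "query_column_map"))
  cols <- column_profiles(alignment)
  positions <- sort(unique(unlist(regions$members)))
  bnorm_by_pos <- stats::setNames(profile$b_norm, profile$residues$res_seq)

  rows <- lapply(positions, function(p) {
    m <- qmap$pairs[qmap$pairs$res_seq == p, , drop = FALSE]
    if (nrow(m) == 0L) {
      warning("flexible position ", p,
              " is not covered by the query row; skipped", call. = FALSE)
      return(NULL)
    }
    cp <- cols[cols$col == m$col[1L], ]
    wt <- m$aa[1L]
    if (cp$degenerate || cp$gap_frac > max_gap_frac ||
        cp$consensus_freq < min_consensus_freq ||
        cp$consensus_aa == wt) return(NULL)
    bn <- unname(bnorm_by_pos[as.character(p)])
    data.frame(label = paste0(wt, p, cp$consensus_aa),
               position = p, wt_aa = wt, proposed_aa = cp$consensus_aa,
               b_norm = bn, consensus_freq = cp$consensus_freq,
               gap_frac = cp$gap_frac,
               score = score_candidate(bn, cp$consensus_freq, weights, b_cap),
               cys_flag = cp$consensus_aa == "C",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), position = integer(),
                      wt_aa = character(), proposed_aa = character(),
                      b_norm = numeric(), consensus_freq = numeric(),
                      gap_frac = numeric(), score = numeric(),
                      cys_flag = logical(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$score, out$position), , drop = FALSE]
    if (any(out$cys_flag))
      warning("candidate(s) introduce cysteine (flagged, not removed): ",
              paste(out$label[out$cys_flag], collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("mutation_candidates", "data.frame")
  out
}

#' Assemble a design report
#'
#' Bundles candidates with the provenance needed to reproduce them
#' (thresholds, sd convention, alignment statistics). An empty candidate
#' list is a valid report.
#'
#' @param candidates a `mutation_candidates` data frame.
#' @param metadata named list of provenance values (thresholds, alignment
#'   size, sd convention, ...).
#' @return an object of class `design_report`.
#' @export
design_report <- function(candidates, metadata = list()) {
  structure(list(candidates = candidates, metadata = metadata,
                 created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Mutation design report (", nrow(x$candidates), " candidate",
      if (nrow(x$candidates) != 1L) "s", ")\n", sep = "")
  for (k in names(x$metadata))
    cat("  ", k, ": ", paste(format(x$metadata[[k]]), collapse = " "),
        "\n", sep = "")
  if (nrow(x$candidates) > 0L) {
    cat("\n")
    print.data.frame(x$candidates, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write a design report as CSV plus a text summary
#'
#' @param report a `design_report`.
#' @param csv_file path for the candidate table CSV.
#' @param txt_file optional path for a human-readable summary with the
#'   provenance header.
#' @return `csv_file`, invisibly.
#' @export
write_design_report <- function(report, csv_file, txt_file = NULL) {
  stopifnot(inherits(report, "design_report"))
  utils::write.csv(as.data.frame(report$candidates), csv_file,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(txt_file)) {
    con <- file(txt_file, "w")
    on.exit(close(con))
    writeLines("Mutation design report", con)
    for (k in names(report$metadata))
      writeLines(paste0("  ", k, ": ",
                        paste(format(report$metadata[[k]]), collapse = " ")),
                 con)
    writeLines(paste0("  candidates: ",
                      paste(report$candidates$label, collapse = ", ")), con)
  }
  invisible(csv_file)
}
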