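#' Read a multiple sequence alignment
#'
#' Reads an aligned-FASTA or Clustal file into a simple alignment object.
#' Sequences are upper-cased and `.` gap characters are converted to `-`.
#'
#' @param source path to the alignment file.
#' @param format `"fasta"` (aligned FASTA, default) or `"clustal"`.
#' @return an object of class `aa_alignment`: list with `ids`, `seqs`
#'   (character vector of aligned sequences, one per entry, file order),
#'   `n_seq` and `n_cols`.
#' @export
read_alignment <- function(source, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readAAStringSet(source),
                    error = function(e) stop("no sequences: ",
                                             conditionMessage(e), call. = FALSE))
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    aln <- tryCatch(Biostrings::readAAMultipleAlignment(source, format = "clustal"),
                    error = function(e) stop("not an alignment: ",
                                             conditionMessage(e), call. = FALSE))
    seqs <- as.character(aln)
    ids <- names(seqs)
  }
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  ## FASTA ids: text up to first whitespace
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("not an alignment: ragged sequence lengths", call. = FALSE)
  structure(list(ids = unname(ids), seqs = unname(seqs),
                 n_seq = length(seqs), n_cols = unname(widths[1L])),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Alignment:", x$n_seq, "sequences x", x$n_cols, "columns\n")
  invisible(x)
}

as_alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Per-column consensus and conservation of an alignment
#'
#' Counts residue occurrences in every alignment column and reports the
#' plurality (most frequent non-gap) residue, its frequency among non-gap
#' characters, the gap fraction, and a Shannon-entropy conservation score.
#' Plurality ties are broken deterministically by one-letter alphabet order
#' (A < C < D < ... < Y). Characters outside the 20-residue alphabet are
#' counted as `X`. A column consisting only of gaps is flagged degenerate
#' and reported with `consensus_aa = "X"`, `consensus_freq = 0`.
#'
#' @param alignment an `aa_alignment` from [read_alignment()].
#' @return a `data.frame` with one row per column: `col`, `consensus_aa`,
#'   `consensus_freq`, `gap_frac`, `entropy` (nats, over non-gap residue
#'   frequencies; 0 = fully conserved) and `degenerate`. The full count
#'   matrix (residues + gap x columns) is attached as attribute `"counts"`.
#' @export
column_profiles <- function(alignment) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (alignment$n_seq == 0L) stop("no sequences", call. = FALSE)
  m <- as_alignment_matrix(alignment)
  m[!(m %in% c(AA_ALPHABET, "-"))] <- "X"
  levels <- c(AA_ALPHABET, "X", "-")
  counts <- apply(m, 2L, function(col) table(factor(col, levels = levels)))
  ## counts: levels x n_cols
  nongap <- counts[seq_len(21L), , drop = FALSE]
  nongap_tot <- colSums(nongap)
  top_idx <- apply(nongap, 2L, which.max)  # first max = alphabet-order tie-break
  top_cnt <- nongap[cbind(top_idx, seq_len(ncol(nongap)))]
  degenerate <- nongap_tot == 0L
  consensus_aa <- rownames(nongap)[top_idx]
  consensus_freq <- ifelse(degenerate, 0, top_cnt / pmax(nongap_tot, 1L))
  consensus_aa[degenerate] <- "X"
  entropy <- vapply(seq_len(ncol(nongap)), function(j) {
    p <- nongap[, j] / max(nongap_tot[j], 1L)
    p <- p[p > 0]
    if (length(p) == 0L) return(NA_real_)
    -sum(p * log(p))
  }, numeric(1))
  if (any(degenerate))
    warning(sum(degenerate), " all-gap column(s) flagged degenerate",
            call. = FALSE)
  out <- data.frame(col = seq_len(alignment$n_cols),
                    consensus_aa = consensus_aa,
                    consensus_freq = as.numeric(consensus_freq),
                    gap_frac = as.numeric(counts["-", ] / alignment$n_seq),
                    entropy = entropy,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  rownames(out) <- NULL
  out
}

#' Map query residue positions to alignment columns
#'
#' The k-th non-gap character of the query row maps to the column where it
#' sits; the corresponding structure residue number is `k + offset`. This is
#' the plumbing that connects structure numbering (flexible regions) to
#' alignment columns (consensus).
#'
#' @param alignment an `aa_alignment`.
#' @param query_id id of the structure's own sequence within the alignment.
#' @param offset integer added to 1-based query positions to obtain
#'   structure residue numbers (default 0).
#' @return an object of class `query_column_map`: list with `query_id`,
#'   `offset` and `pairs`, a `data.frame` of `query_pos`, `col`, `res_seq`
#'   and `aa` (the query character).
#' @export
map_query_to_columns <- function(alignment, query_id, offset = 0L) {
  stopifnot(inherits(alignment, "aa_alignment"))
  i <- match(query_id, alignment$ids)
  if (is.na(i)) stop("query not in alignment: '", query_id, "'", call. = FALSE)
  chars <- strsplit(alignment$seqs[i], "", fixed = TRUE)[[1L]]
  cols <- which(chars != "-")
  pairs <- data.frame(query_pos = seq_along(cols),
                      col = cols,
                      res_seq = seq_along(cols) + offset,
                      aa = chars[cols],
                      stringsAsFactors = FALSE)
  structure(list(query_id = query_id, offset = offset, pairs = pairs),
            class = "query_column_map")
}

#' Write a consensus table as CSV
#'
#' @param profiles output of [column_profiles()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_consensus_csv <- function(profiles, file) {
  utils::write.csv(
    profiles[, c("col", "consensus_aa", "consensus_freq", "gap_frac",
                 "entropy")],
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
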