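#' Extract per-residue C-alpha B-factors from a PDB structure
#'
#' Reads a PDB file and returns one record per residue carrying the C-alpha
#' temperature factor. Only `ATOM` records are considered, so HETATM entries
#' and waters are excluded. When a C-alpha has alternate locations, the
#' highest-occupancy altloc is kept (ties broken by the alphabetically first
#' altloc identifier). Residues that have atoms but no C-alpha are skipped
#' with a warning. Author (auth) residue numbering is used throughout, and
#' insertion codes are preserved in file order.
#'
#' @param pdb_source path to a PDB file (wwPDB v3.3 columns).
#' @param chain one-character chain identifier. `NULL` (default) selects the
#'   first chain occurring in the file.
#' @return a `data.frame` with columns `chain_id`, `res_seq`, `icode`
#'   (`""` when absent), `aa3`, `aa1` (nonstandard residues map to `"X"`
#'   with a warning), `b_raw` (Angstrom^2) and `occupancy`.
#' @seealso [normalize_bfactors()], [detect_flexible_regions()]
#' @export
#' @examples
#' gen <- gen_pdb(seed = 1, n_res = 80, bump_start = 40, bump_end = 44)
#' head(read_pdb_calpha(gen$file))
read_pdb_calpha <- function(pdb_source, chain = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(pdb_source, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("empty structure: ", conditionMessage(e),
                             call. = FALSE)
  )
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L) stop("empty structure: no ATOM records", call. = FALSE)

  if (is.null(chain)) chain <- atom$chain[1L]
  if (!chain %in% atom$chain) stop("unknown chain: '", chain, "'", call. = FALSE)
  atom <- atom[atom$chain == chain, , drop = FALSE]

  icode <- ifelse(is.na(atom$insert), "", atom$insert)
  res_key <- paste(atom$resno, icode, sep = "|")
  keys <- unique(res_key)  # file order

  rows <- lapply(keys, function(k) {
    sub <- atom[res_key == k, , drop = FALSE]
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      warning("residue ", sub$resno[1L], icode[res_key == k][1L],
              " has no CA atom; skipped", call. = FALSE)
      return(NULL)
    }
    if (nrow(ca) > 1L) {
      ## altloc: highest occupancy wins, ties to first altloc alphabetically
      alt <- ifelse(is.na(ca$alt), "", ca$alt)
      ca <- ca[order(-ca$o, alt), , drop = FALSE]
    }
    ca <- ca[1L, ]
    data.frame(chain_id = ca$chain,
               res_seq = ca$resno,
               icode = ifelse(is.na(ca$insert), "", ca$insert),
               aa3 = ca$resid,
               b_raw = ca$b,
               occupancy = ca$o,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("empty structure: no CA atoms in chain '", chain, "'", call. = FALSE)
  out$aa1 <- aa_three_to_one(out$aa3)
  rownames(out) <- NULL
  out[, c("chain_id", "res_seq", "icode", "aa3", "aa1", "b_raw", "occupancy")]
}

#' Normalize C-alpha B-factors to zero mean and unit variance
#'
#' Converts raw temperature factors to z-scores,
#' \eqn{B' = (B - \langle B \rangle) / \sigma(B)}, over the residues of one
#' chain. High positive \eqn{B'} marks residues more mobile than the chain
#' average. The population standard deviation (divide by N) is the default
#' convention; the sample convention (divide by N-1) is available and the
#' choice is recorded in the returned object.
#'
#' @param records per-residue records from [read_pdb_calpha()] (or any
#'   `data.frame` with at least `res_seq` and `b_raw` columns).
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return an object of class `bfactor_profile`: a list with `residues`
#'   (the input records), `b_norm`, `mean_b`, `sd_b`, and `sd_convention`.
#' @export
#' @examples
#' rec <- data.frame(chain_id = "A", res_seq = 1:3, icode = "",
#'                   aa3 = "ALA", aa1 = "A", b_raw = c(10, 20, 30),
#'                   occupancy = 1)
#' normalize_bfactors(rec)$b_norm   # -1.2247, 0, +1.2247
normalize_bfactors <- function(records,
                               sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  b <- records$b_raw
  n <- length(b)
  if (n < 2L) stop("degenerate profile: need at least 2 residues", call. = FALSE)
  mean_b <- mean(b)
  sd_b <- if (sd_convention == "population") {
    sqrt(sum((b - mean_b)^2) / n)
  } else {
    stats::sd(b)
  }
  if (sd_b == 0) stop("constant B-factors: zero variance", call. = FALSE)
  structure(
    list(residues = records,
         b_norm = (b - mean_b) / sd_b,
         mean_b = mean_b,
         sd_b = sd_b,
         sd_convention = sd_convention),
    class = "bfactor_profile")
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat("B-factor profile:", nrow(x$residues), "residues, chain",
      unique(x$residues$chain_id), "\n")
  cat(sprintf("  <B> = %.3f A^2, sigma(B) = %.3f A^2 (%s sd)\n",
              x$mean_b, x$sd_b, x$sd_convention))
  cat(sprintf("  B' range: [%.3f, %.3f]\n", min(x$b_norm), max(x$b_norm)))
  invisible(x)
}

#' Detect contiguous high-flexibility regions
#'
#' Finds maximal runs of at least `min_run` consecutive residues whose
#' normalized B-factor is at or above `threshold`. Residues are consecutive
#' when they are adjacent in the profile, lie in the same chain, and their
#' author numbers differ by at most one (insertion-coded residues therefore
#' extend a run). Regions are non-overlapping and sorted by start position.
#'
#' @param profile a `bfactor_profile` from [normalize_bfactors()].
#' @param threshold minimum `b_norm` for a residue to count as flexible
#'   (default 1.0, i.e. one standard deviation above the chain mean).
#' @param min_run minimum region length in residues (default 3).
#' @return a `data.frame` with columns `chain_id`, `start`, `end`
#'   (inclusive author numbering), `n_residues` and `peak_bnorm`, plus a
#'   list column `members` holding the member residue numbers.
#' @export
detect_flexible_regions <- function(profile, threshold = 1.0, min_run = 3L) {
  stopifnot(inherits(profile, "bfactor_profile"), is.finite(threshold),
            min_run >= 1L)
  res <- profile$residues
  bn <- profile$b_norm
  n <- nrow(res)
  hot <- bn >= threshold

  regions <- list()
  i <- 1L
  while (i <= n) {
    if (!hot[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && hot[j + 1L] &&
           res$chain_id[j + 1L] == res$chain_id[j] &&
           (res$res_seq[j + 1L] - res$res_seq[j]) <= 1L) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_run) {
      idx <- i:j
      regions[[length(regions) + 1L]] <- data.frame(
        chain_id = res$chain_id[i],
        start = res$res_seq[i],
        end = res$res_seq[j],
        n_residues = length(idx),
        peak_bnorm = max(bn[idx]),
        stringsAsFactors = FALSE)
      regions[[length(regions)]]$members <- I(list(res$res_seq[idx]))
    }
    i <- j + 1L
  }
  if (length(regions) == 0L) {
    out <- data.frame(chain_id = character(), start = integer(),
                      end = integer(), n_residues = integer(),
                      peak_bnorm = numeric(), stringsAsFactors = FALSE)
    out$members <- I(list())
    return(out)
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a per-residue B-factor profile as CSV
#'
#' The CSV uses a fixed 4-decimal convention for `b_raw` and `b_norm`, so a
#' written profile re-read with [read_bfactor_csv()] reproduces the values
#' exactly as formatted. The header line records the normalization
#' convention and chain statistics as a comment.
#'
#' @param profile a `bfactor_profile`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bfactor_csv <- function(profile, file) {
  res <- profile$residues
  hdr <- sprintf("# sd_convention=%s mean_b=%.4f sd_b=%.4f",
                 profile$sd_convention, profile$mean_b, profile$sd_b)
  df <- data.frame(chain = res$chain_id, res_seq = res$res_seq,
                   icode = res$icode, aa1 = res$aa1,
                   b_raw = sprintf("%.4f", res$b_raw),
                   b_norm = sprintf("%.4f", profile$b_norm),
                   stringsAsFactors = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_bfactor_csv
#' @export
read_bfactor_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#",
                        colClasses = c(icode = "character"),
                        stringsAsFactors = FALSE)
  df$icode[is.na(df$icode)] <- ""
  df
}
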