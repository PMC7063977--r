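# Independent oracles and tiny fixture builders used across the suite.
# Oracles deliberately re-derive each quantity from its definition rather
# than calling the implementation under test.

# brute-force enumeration of all (start, end) index pairs: a region is any
# maximal stretch of >= min_run positions that are all hot (b_norm >=
# threshold) and pairwise contiguous (same chain, res_seq step <= 1)
oracle_flexible_regions <- function(res_seq, chain, b_norm, threshold,
                                    min_run) {
  n <- length(res_seq)
  hot <- b_norm >= threshold
  linked <- function(i, j) {          # indices i..j form one contiguous run
    all(hot[i:j]) &&
      (i == j || all(chain[(i + 1):j] == chain[i:(j - 1)] &
                     (res_seq[(i + 1):j] - res_seq[i:(j - 1)]) <= 1L))
  }
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!linked(i, j)) next
    if (j - i + 1L < min_run) next
    left_ext <- i > 1L && linked(i - 1L, j)
    right_ext <- j < n && linked(i, j + 1L)
    if (!left_ext && !right_ext)
      out[[length(out) + 1L]] <- data.frame(start = res_seq[i],
                                            end = res_seq[j])
  }
  do.call(rbind, out)
}

# fabricate a normalized profile object directly from b_norm values
fake_profile <- function(res_seq, b_norm, chain = "A") {
  res <- data.frame(chain_id = chain, res_seq = res_seq, icode = "",
                    aa3 = "ALA", aa1 = "A", b_raw = b_norm, occupancy = 1,
                    stringsAsFactors = FALSE)
  structure(list(residues = res, b_norm = b_norm, mean_b = 0, sd_b = 1,
                 sd_convention = "population"),
            class = "bfactor_profile")
}

# minimal hand-written PDB text (wwPDB v3.3 fixed columns)
pdb_atom_line <- function(serial, name, altloc, resname, chain, resno, x, y,
                          z, occ, b) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", name), altloc, resname, chain, resno, x, y, z,
          occ, b)
}

write_fixture_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# dense grid search over decay constants: for first-order decay the model
# is ln(residual) = a - k t; profile out the intercept analytically and
# scan k on a fine grid
oracle_halflife_grid <- function(time_min, residual_pct,
                                 k_grid = seq(1e-4, 0.2, by = 1e-5)) {
  keep <- residual_pct > 0
  lr <- log(residual_pct[keep])
  tt <- time_min[keep]
  sse <- vapply(k_grid, function(k) {
    a <- mean(lr + k * tt)
    sum((lr - (a - k * tt))^2)
  }, numeric(1))
  log(2) / k_grid[which.min(sse)]
}

# worked-example inputs: flexible stretch 63-68 of the query with the
# thermophile consensus differing at four positions
worked_example_query <- function() {
  paste0(strrep("A", 62), "TKWDCK", strrep("G", 20))
}

worked_example_patch <- function() {
  c("64" = "N", "65" = "I", "66" = "T", "68" = "T")
}

worked_example_resnames <- function() {
  c("63" = "THR", "64" = "LYS", "65" = "TRP", "66" = "ASP", "67" = "CYS",
    "68" = "LYS")
}
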