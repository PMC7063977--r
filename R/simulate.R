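#' Generate a synthetic single-chain PDB with a planted flexibility bump
#'
#' Writes a straight-line C-alpha trace (synthetic geometry — not a fold;
#' only the B-factor column matters downstream) whose temperature factors
#' are a flat baseline with small clamped noise plus an elevated "bump"
#' over a chosen residue range. The baseline noise alternates in sign
#' along the chain, so after z-normalization only the bump can form a
#' contiguous stretch above `B' = 1`: the planted region is an exact
#' detection truth, not a probabilistic one.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical files.
#' @param n_res chain length (default 300).
#' @param chain chain identifier (default `"A"`).
#' @param bump_start,bump_end inclusive residue range of the planted bump
#'   (defaults 63-68).
#' @param bump_height B-factor elevation of the bump (Angstrom^2, default
#'   10; 0 plants nothing).
#' @param baseline_b,baseline_sd,baseline_clamp baseline B-factor mean,
#'   noise sd, and absolute clamp of the noise (defaults 20, 0.5, 1).
#' @param residue_names optional named character vector of three-letter
#'   residue names keyed by residue number (e.g. `c("63" = "THR")`);
#'   everything else is `ALA`.
#' @param file output PDB path (default a tempfile).
#' @return list with `file`, `b_raw`, and `truth` — the ground-truth
#'   manifest (planted region, heights, seed, parameters).
#' @export
gen_pdb <- function(seed, n_res = 300L, chain = "A",
                    bump_start = 63L, bump_end = 68L, bump_height = 10,
                    baseline_b = 20, baseline_sd = 0.5, baseline_clamp = 1,
                    residue_names = NULL,
                    file = tempfile(fileext = ".pdb")) {
  if (bump_start < 1L || bump_end > n_res || bump_start > bump_end)
    stop("invalid spec: bump outside chain", call. = FALSE)
  b <- with_seed(seed, {
    ## clamped magnitudes with alternating sign: consecutive baseline
    ## residues can never both sit above the chain mean, so runs above the
    ## detection threshold exist exactly where the bump is planted
    mag <- pmin(abs(stats::rnorm(n_res, 0, baseline_sd)), baseline_clamp)
    baseline_b + mag * rep_len(c(1, -1), n_res)
  })
  bump <- bump_start:bump_end
  b[bump] <- b[bump] + bump_height

  resid <- rep("ALA", n_res)
  if (!is.null(residue_names))
    resid[as.integer(names(residue_names))] <- toupper(residue_names)

  xyz <- as.numeric(t(cbind(3.8 * (seq_len(n_res) - 1L), 0, 0)))
  bio3d::write.pdb(file = file, xyz = xyz, resno = seq_len(n_res),
                   resid = resid, elety = rep("CA", n_res),
                   chain = rep(chain, n_res), o = rep(1, n_res),
                   b = round(b, 2))
  list(file = file, b_raw = round(b, 2),
       truth = list(kind = "pdb_profile", seed = seed, n_res = n_res,
                    chain = chain, bump_start = bump_start,
                    bump_end = bump_end, bump_height = bump_height,
                    baseline_b = baseline_b, baseline_sd = baseline_sd,
                    baseline_clamp = baseline_clamp))
}

#' Generate a synthetic homolog alignment with a planted consensus
#'
#' Emulates an alignment of homolog sequences around a gap-free query row.
#' The planted per-column consensus equals the query everywhere except at
#' the positions named in `consensus_patch`. In every non-query row, each
#' column is independently a gap (probability `gap_frac`), the planted
#' consensus residue (probability `consensus_freq`), or a uniform draw
#' from the other 19 residues.
#'
#' @param seed integer RNG seed.
#' @param query gap-free one-letter query sequence (character scalar).
#' @param consensus_patch named character vector of planted consensus
#'   residues keyed by structure residue number (e.g.
#'   `c("64" = "N", "65" = "I")`).
#' @param n_seq number of homolog sequences excluding the query
#'   (default 92, a realistic NCBI harvest for one enzyme family).
#' @param consensus_freq unconditional per-column probability of the
#'   planted residue (default 0.7); must exceed 1/20.
#' @param gap_frac per-column gap probability in non-query rows
#'   (default 0.05).
#' @param query_id id of the query row (default `"query"`).
#' @param offset added to 1-based query positions to obtain structure
#'   numbering (default 0); patch names are structure numbers.
#' @param file output aligned-FASTA path (default a tempfile).
#' @return list with `file`, `alignment` (an `aa_alignment`), and `truth`
#'   (planted consensus string in column space, parameters, seed).
#' @export
gen_msa <- function(seed, query, consensus_patch = NULL, n_seq = 92L,
                    consensus_freq = 0.7, gap_frac = 0.05,
                    query_id = "query", offset = 0L,
                    file = tempfile(fileext = ".fasta")) {
  if (consensus_freq <= 1 / 20)
    stop("invalid spec: consensus frequency must exceed 1/20", call. = FALSE)
  if (consensus_freq + gap_frac > 1)
    stop("invalid spec: frequency + gap rate > 1", call. = FALSE)
  qchars <- strsplit(toupper(query), "", fixed = TRUE)[[1L]]
  if (any(!qchars %in% AA_ALPHABET))
    stop("query must use the 20-residue alphabet", call. = FALSE)
  n_cols <- length(qchars)

  planted <- qchars
  if (!is.null(consensus_patch)) {
    pos <- as.integer(names(consensus_patch)) - offset
    if (any(pos < 1L | pos > n_cols))
      stop("invalid spec: patch outside query", call. = FALSE)
    planted[pos] <- toupper(consensus_patch)
  }

  rows <- with_seed(seed, {
    vapply(seq_len(n_seq), function(i) {
      u <- stats::runif(n_cols)
      others <- vapply(planted, function(aa)
        sample(setdiff(AA_ALPHABET, aa), 1L), character(1))
      chars <- ifelse(u < gap_frac, "-",
               ifelse(u < gap_frac + consensus_freq, planted, others))
      paste(chars, collapse = "")
    }, character(1))
  })

  ids <- c(query_id, sprintf("seq%03d", seq_len(n_seq)))
  seqs <- c(paste(qchars, collapse = ""), rows)
  writeLines(paste0(">", ids, "\n", seqs), file)
  alignment <- structure(list(ids = ids, seqs = seqs, n_seq = n_seq + 1L,
                              n_cols = n_cols), class = "aa_alignment")
  list(file = file, alignment = alignment,
       truth = list(kind = "msa", seed = seed, n_seq = n_seq + 1L,
                    n_cols = n_cols, query_id = query_id, offset = offset,
                    planted_consensus = paste(planted, collapse = ""),
                    consensus_freq = consensus_freq, gap_frac = gap_frac))
}

#' Generate synthetic Michaelis-Menten rate data
#'
#' Rates `v = Vmax*[S]/(Km+[S])`, optionally with multiplicative Gaussian
#' noise, on a doubling-dilution substrate grid (default 10 mM halved down
#' to 0.078125 mM — the usual assay design for this substrate range).
#'
#' @param seed integer RNG seed (unused when `noise_cv = 0`).
#' @param enzyme_id label (default `"enzyme"`).
#' @param vmax,km ground-truth parameters (U/mg, mM); defaults 714.29 and
#'   0.36.
#' @param substrate_mM substrate grid (default `10 / 2^(0:7)`).
#' @param noise_cv coefficient of variation of multiplicative noise
#'   (default 0 = noiseless).
#' @param file optional CSV output path.
#' @return list with `dataset` (a `kinetic_dataset`), optional `file`, and
#'   `truth`.
#' @export
gen_kinetics <- function(seed, enzyme_id = "enzyme", vmax = 714.29,
                         km = 0.36, substrate_mM = 10 / 2^(0:7),
                         noise_cv = 0, file = NULL) {
  if (noise_cv < 0) stop("invalid spec: negative noise CV", call. = FALSE)
  if (vmax <= 0 || km <= 0) stop("invalid spec: non-positive parameters",
                                 call. = FALSE)
  v <- vmax * substrate_mM / (km + substrate_mM)
  if (noise_cv > 0)
    v <- with_seed(seed,
                   v * (1 + stats::rnorm(length(v), 0, noise_cv)))
  dataset <- kinetic_dataset(enzyme_id, substrate_mM, v)
  if (!is.null(file))
    utils::write.csv(data.frame(enzyme_id = enzyme_id,
                                substrate_mM = substrate_mM,
                                rate_U_per_mg = v),
                     file, row.names = FALSE, quote = FALSE)
  list(dataset = dataset, file = file,
       truth = list(kind = "kinetics", seed = seed, vmax = vmax, km = km,
                    noise_cv = noise_cv))
}

## the assay time grids used for thermal-inactivation time courses
DECAY_GRID_50C <- c(5, 10, 15, 20, 30, 40, 50, 65, 80, 100, 120)
DECAY_GRID_60C <- c(1, 3, 6, 10, 15, 20, 25, 30, 35, 45, 60, 75, 90)

#' Generate a synthetic thermal-inactivation time course
#'
#' First-order decay `residual(t) = 100*exp(-k*t)`, optionally with
#' multiplicative Gaussian noise, on the standard assay time grid for the
#' chosen temperature (50 C: 5-120 min, 60 C: 1-90 min).
#'
#' @param seed integer RNG seed (unused when `noise_cv = 0`).
#' @param enzyme_id label.
#' @param temperature_C incubation temperature, used to pick the default
#'   grid (default 50).
#' @param k_per_min ground-truth decay constant (default `log(2)/65`, a
#'   65-minute half-life).
#' @param time_min sampling grid; default depends on `temperature_C`.
#' @param noise_cv multiplicative noise CV (default 0).
#' @param file optional CSV output path.
#' @return list with `series` (an `inactivation_series`), optional `file`,
#'   and `truth` (including the implied half-life).
#' @export
gen_decay <- function(seed, enzyme_id = "enzyme", temperature_C = 50,
                      k_per_min = log(2) / 65,
                      time_min = if (temperature_C >= 60) DECAY_GRID_60C
                                 else DECAY_GRID_50C,
                      noise_cv = 0, file = NULL) {
  if (noise_cv < 0) stop("invalid spec: negative noise CV", call. = FALSE)
  if (k_per_min <= 0) stop("invalid spec: non-positive decay constant",
                           call. = FALSE)
  r <- 100 * exp(-k_per_min * time_min)
  if (noise_cv > 0)
    r <- with_seed(seed, r * (1 + stats::rnorm(length(r), 0, noise_cv)))
  r <- pmin(pmax(r, 0), 110)
  series <- inactivation_series(enzyme_id, temperature_C, time_min, r)
  if (!is.null(file))
    utils::write.csv(data.frame(enzyme_id = enzyme_id,
                                temperature_C = temperature_C,
                                time_min = time_min, residual_pct = r),
                     file, row.names = FALSE, quote = FALSE)
  list(series = series, file = file,
       truth = list(kind = "decay", seed = seed, k_per_min = k_per_min,
                    t_half_min = log(2) / k_per_min, noise_cv = noise_cv))
}

#' Generate a synthetic conformational ensemble
#'
#' A helical C-alpha trace whose frames scatter about fixed base positions
#' with
#' per-residue isotropic Gaussian displacement (known RMSF truth
#' `sigma*sqrt(3)`), optionally pushed through a random rigid transform per
#' frame (to exercise superposition) and optionally carrying a planted
#' donor/acceptor contact schedule with exact occupancy.
#'
#' @param seed integer RNG seed.
#' @param n_res number of residues (one CA each, default 20).
#' @param n_frames number of frames (default 100).
#' @param sigma_nm per-coordinate displacement sd, scalar or one value per
#'   residue (default 0.05 nm).
#' @param rigid_transforms apply a random rotation + translation to every
#'   frame (default `FALSE`).
#' @param hbond optional list
#'   `list(donor_res =, acceptor_res =, occupancy_frac =)` with optional
#'   `on_dist` (default 0.28 nm) and `off_dist` (default 0.60 nm): the
#'   acceptor CA is placed at `on_dist` from the donor CA in exactly
#'   `round(occupancy_frac * n_frames)` randomly chosen frames and at
#'   `off_dist` otherwise; both atoms are exempt from displacement noise so
#'   the planted occupancy is exact.
#' @param file optional multi-MODEL PDB output path.
#' @return list with `ensemble`, optional `file`, and `truth` (per-residue
#'   sigma, expected RMSF, planted occupancy).
#' @export
gen_ensemble <- function(seed, n_res = 20L, n_frames = 100L,
                         sigma_nm = 0.05, rigid_transforms = FALSE,
                         hbond = NULL, file = NULL) {
  if (n_frames < 2L) stop("invalid spec: need >= 2 frames", call. = FALSE)
  if (any(sigma_nm < 0)) stop("invalid spec: negative sigma", call. = FALSE)
  sigma <- rep_len(sigma_nm, n_res)

  ## idealized helical CA trace (non-collinear, so superposition is
  ## well-posed); ~100 deg turn and 0.15 nm rise per residue
  ang <- (seq_len(n_res) - 1L) * 100 * pi / 180
  base <- cbind(0.23 * cos(ang), 0.23 * sin(ang),
                0.15 * (seq_len(n_res) - 1L))
  occupancy_truth <- NULL
  if (!is.null(hbond))
    occupancy_truth <- 100 * round(hbond$occupancy_frac * n_frames) / n_frames

  coords <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(n_frames, n_res, 3L))
    for (f in seq_len(n_frames))
      arr[f, , ] <- base + stats::rnorm(n_res * 3L) * sigma
    if (!is.null(hbond)) {
      on_dist <- if (is.null(hbond$on_dist)) 0.28 else hbond$on_dist
      off_dist <- if (is.null(hbond$off_dist)) 0.60 else hbond$off_dist
      n_on <- round(hbond$occupancy_frac * n_frames)
      on_frames <- sample(n_frames, n_on)
      arr[, hbond$donor_res, ] <-
        matrix(base[hbond$donor_res, ], n_frames, 3L, byrow = TRUE)
      for (f in seq_len(n_frames)) {
        d <- if (f %in% on_frames) on_dist else off_dist
        arr[f, hbond$acceptor_res, ] <- base[hbond$donor_res, ] + c(0, d, 0)
      }
    }
    if (rigid_transforms) {
      for (f in seq_len(n_frames)) {
        q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
        if (det(q) < 0) q[, 1L] <- -q[, 1L]
        shift <- stats::runif(3L, -1, 1)
        arr[f, , ] <- sweep(arr[f, , ] %*% q, 2L, shift, `+`)
      }
    }
    arr
  })

  atoms <- data.frame(chain = "A", res_seq = seq_len(n_res),
                      res_name = "ALA", atom_name = "CA", element = "C",
                      stringsAsFactors = FALSE)
  ensemble <- conformational_ensemble(atoms, coords, units = "nm")
  if (!is.null(file)) {
    xyz <- t(apply(coords * 10, 1L, function(m) as.numeric(t(m))))
    bio3d::write.pdb(file = file, xyz = xyz, resno = seq_len(n_res),
                     resid = rep("ALA", n_res), elety = rep("CA", n_res),
                     chain = rep("A", n_res), o = rep(1, n_res),
                     b = rep(0, n_res))
  }
  list(ensemble = ensemble, file = file,
       truth = list(kind = "ensemble", seed = seed, n_res = n_res,
                    n_frames = n_frames, sigma_nm = sigma,
                    expected_rmsf_nm = sigma * sqrt(3),
                    rigid_transforms = rigid_transforms,
                    planted_occupancy_pct = occupancy_truth))
}

#' Write a generator truth manifest as JSON
#'
#' Every generator returns a `truth` list; this helper serializes it next
#' to the generated data so downstream tests and tools can read ground
#' truth from the manifest alone.
#'
#' @param truth a generator `truth` list.
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_truth_manifest <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
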