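#' Construct a conformational ensemble
#'
#' Container for a set of structure snapshots sharing one atom table:
#' frames x atoms x 3 coordinates, in nanometers.
#'
#' @param atoms `data.frame` with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element` (one row per atom, fixed order across frames).
#' @param coords numeric array `F x A x 3` (nm) or a single `A x 3` matrix.
#' @param frame_labels optional per-frame labels (e.g. times).
#' @param units `"nm"` (default) or `"angstrom"`; angstrom input is
#'   converted to nm on construction.
#' @return an object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(atoms, coords, frame_labels = NULL,
                                    units = c("nm", "angstrom")) {
  units <- match.arg(units)
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L,
            dim(coords)[2L] == nrow(atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (units == "angstrom") coords <- coords / 10
  structure(list(atoms = atoms, coords = coords,
                 frame_labels = frame_labels,
                 n_frames = dim(coords)[1L], n_atoms = dim(coords)[2L],
                 superposed = FALSE),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat("Conformational ensemble:", x$n_frames, "frames x", x$n_atoms,
      "atoms (nm)", if (x$superposed) "[superposed]", "\n")
  invisible(x)
}

#' Read a multi-MODEL PDB file as a conformational ensemble
#'
#' Each `MODEL` block becomes one frame; all models must share the atom
#' table of the first. PDB coordinates are in angstrom and are converted to
#' nanometers.
#'
#' @param file path to a (multi-)MODEL PDB file.
#' @return a `conformational_ensemble`.
#' @export
read_ensemble_pdb <- function(file) {
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("empty structure: ",
                                           conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  if (nrow(atom) == 0L) stop("empty structure: no atoms", call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz)
  a <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(f, a, 3L))
  for (i in seq_len(f))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  atoms <- data.frame(chain = atom$chain, res_seq = atom$resno,
                      res_name = atom$resid, atom_name = atom$elety,
                      element = atom$elesy, stringsAsFactors = FALSE)
  conformational_ensemble(atoms, coords, units = "angstrom")
}

select_atom_indices <- function(ensemble, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  which(ensemble$atoms$atom_name %in% selection)
}

## optimal proper rotation (SVD with determinant guard) mapping centered P
## onto centered Q
kabsch_rotation <- function(p, q) {
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition of ensemble frames onto a reference
#'
#' Each frame is translated and rotated so that the selected atoms fit the
#' reference frame in the least-squares sense (closed-form SVD solution,
#' with a determinant guard so only proper rotations are produced). The
#' transform derived from the selection is applied to all atoms.
#'
#' @param ensemble a `conformational_ensemble`.
#' @param reference_frame index of the reference frame (default 1).
#' @param selection atom-name character vector (default `"CA"`) or integer
#'   atom indices; needs at least three non-collinear atoms.
#' @return the ensemble with transformed coordinates, `superposed = TRUE`,
#'   and a numeric `rmsd` field giving each frame's post-fit RMSD (nm) over
#'   the selection.
#' @export
superpose <- function(ensemble, reference_frame = 1L, selection = "CA") {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  sel <- select_atom_indices(ensemble, selection)
  if (length(sel) < 3L)
    stop("underdetermined superposition: need >= 3 selected atoms",
         call. = FALSE)
  ref <- ensemble$coords[reference_frame, sel, , drop = TRUE]
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2L, ref_c)
  sv <- svd(ref0)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1e-12))
    stop("underdetermined superposition: collinear selection", call. = FALSE)

  coords <- ensemble$coords
  rmsd <- numeric(ensemble$n_frames)
  for (i in seq_len(ensemble$n_frames)) {
    mob <- coords[i, sel, , drop = TRUE]
    mob_c <- colMeans(mob)
    r <- kabsch_rotation(sweep(mob, 2L, mob_c), ref0)
    all0 <- sweep(coords[i, , , drop = TRUE], 2L, mob_c)
    fitted <- all0 %*% r
    fitted <- sweep(fitted, 2L, ref_c, `+`)
    coords[i, , ] <- fitted
    d <- fitted[sel, , drop = FALSE] - ref
    rmsd[i] <- sqrt(mean(rowSums(d^2)))
  }
  ensemble$coords <- coords
  ensemble$superposed <- TRUE
  ensemble$rmsd <- rmsd
  ensemble
}

#' Per-residue root-mean-square fluctuation
#'
#' For each selected atom, `RMSF = sqrt(mean_t |r(t) - <r>|^2)`, the spread
#' of the atom about its ensemble-average position. The ensemble should be
#' superposed first (see [superpose()]); set `check_superposed = FALSE` to
#' opt out explicitly. When several selected atoms share a residue number,
#' their squared fluctuations are RMS-averaged per residue.
#'
#' @param ensemble a `conformational_ensemble` with at least 2 frames.
#' @param selection atom names (default `"CA"`) or integer indices.
#' @param check_superposed error if the ensemble has not been superposed
#'   (default `TRUE`).
#' @return a `data.frame` with columns `res_seq` and `rmsf_nm`.
#' @export
compute_rmsf <- function(ensemble, selection = "CA", check_superposed = TRUE) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  if (ensemble$n_frames < 2L) stop("insufficient frames", call. = FALSE)
  if (check_superposed && !isTRUE(ensemble$superposed))
    stop("ensemble not superposed; run superpose() or set check_superposed = FALSE",
         call. = FALSE)
  sel <- select_atom_indices(ensemble, selection)
  if (length(sel) == 0L) stop("empty selection", call. = FALSE)
  msf <- vapply(sel, function(a) {
    xyz <- ensemble$coords[, a, , drop = TRUE]
    mu <- colMeans(xyz)
    mean(rowSums(sweep(xyz, 2L, mu)^2))
  }, numeric(1))
  res <- ensemble$atoms$res_seq[sel]
  agg <- tapply(msf, res, mean)
  out <- data.frame(res_seq = as.integer(names(agg)),
                    rmsf_nm = sqrt(as.numeric(agg)))
  out[order(out$res_seq), , drop = FALSE]
}

resolve_atom_spec <- function(ensemble, spec) {
  if (is.numeric(spec)) {
    i <- as.integer(spec)
    if (i < 1L || i > ensemble$n_atoms)
      stop("atom not found: index ", spec, call. = FALSE)
    return(i)
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  at <- ensemble$atoms
  hit <- if (length(parts) == 3L) {
    which(at$chain == parts[1L] & at$res_seq == as.integer(parts[2L]) &
          at$atom_name == parts[3L])
  } else if (length(parts) == 2L) {
    which(at$res_seq == as.integer(parts[1L]) & at$atom_name == parts[2L])
  } else {
    stop("atom spec must be 'resno:name' or 'chain:resno:name'", call. = FALSE)
  }
  if (length(hit) == 0L) stop("atom not found: '", spec, "'", call. = FALSE)
  hit[1L]
}

#' Geometric hydrogen-bond occupancy over an ensemble
#'
#' Fraction of frames (in percent) in which a donor-acceptor pair satisfies
#' a geometric hydrogen-bond criterion: heavy-atom distance at or below
#' `dist_cutoff_nm` (default 0.35 nm, common MD practice) and, when a
#' hydrogen atom is supplied, a D-H...A angle of at least
#' `angle_cutoff_deg` (default 120 degrees).
#'
#' @param ensemble a `conformational_ensemble`.
#' @param donor,acceptor atom specifiers: `"resno:atom_name"`,
#'   `"chain:resno:atom_name"`, or an integer atom index.
#' @param dist_cutoff_nm heavy-atom donor-acceptor distance cutoff (nm).
#' @param hydrogen optional specifier of the donor hydrogen; enables the
#'   angle test.
#' @param angle_cutoff_deg minimum D-H...A angle (degrees), used only when
#'   `hydrogen` is given.
#' @return an object of class `hbond_occupancy`: the spec plus
#'   `occupancy_pct` and the per-frame logical vector `satisfied`.
#' @export
hbond_occupancy <- function(ensemble, donor, acceptor, dist_cutoff_nm = 0.35,
                            hydrogen = NULL, angle_cutoff_deg = 120) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            dist_cutoff_nm > 0)
  id <- resolve_atom_spec(ensemble, donor)
  ia <- resolve_atom_spec(ensemble, acceptor)
  dvec <- ensemble$coords[, id, , drop = TRUE] -
          ensemble$coords[, ia, , drop = TRUE]
  if (is.null(dim(dvec))) dvec <- matrix(dvec, nrow = 1L)
  ok <- sqrt(rowSums(dvec^2)) <= dist_cutoff_nm
  if (!is.null(hydrogen)) {
    ih <- resolve_atom_spec(ensemble, hydrogen)
    hd <- ensemble$coords[, id, , drop = TRUE] -
          ensemble$coords[, ih, , drop = TRUE]
    ha <- ensemble$coords[, ia, , drop = TRUE] -
          ensemble$coords[, ih, , drop = TRUE]
    if (is.null(dim(hd))) { hd <- matrix(hd, 1L); ha <- matrix(ha, 1L) }
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok <- ok & ang >= angle_cutoff_deg
  }
  structure(list(donor = donor, acceptor = acceptor,
                 dist_cutoff_nm = dist_cutoff_nm,
                 angle_cutoff_deg = if (is.null(hydrogen)) NA_real_
                                    else angle_cutoff_deg,
                 occupancy_pct = 100 * mean(ok), satisfied = ok),
            class = "hbond_occupancy")
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("H-bond %s ... %s: occupancy %.1f%% (d <= %.2f nm%s)\n",
              format(x$donor), format(x$acceptor), x$occupancy_pct,
              x$dist_cutoff_nm,
              if (is.na(x$angle_cutoff_deg)) ""
              else sprintf(", angle >= %g deg", x$angle_cutoff_deg)))
  invisible(x)
}

#' Write an RMSF profile as CSV
#'
#' @param rmsf output of [compute_rmsf()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rmsf_csv <- function(rmsf, file) {
  utils::write.csv(rmsf, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
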