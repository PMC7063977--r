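random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

two_frame_ensemble <- function(a, b) {
  n <- nrow(a)
  atoms <- data.frame(chain = "A", res_seq = seq_len(n), res_name = "ALA",
                      atom_name = "CA", element = "C")
  coords <- array(NA_real_, dim = c(2, n, 3))
  coords[1, , ] <- a; coords[2, , ] <- b
  conformational_ensemble(atoms, coords)
}

test_that("superposition of identical or translated frames gives zero RMSD", {
  base <- gen_ensemble(seed = 1, n_res = 10, n_frames = 2,
                       sigma_nm = 0)$ensemble$coords[1, , ]
  same <- superpose(two_frame_ensemble(base, base))
  expect_equal(same$rmsd, c(0, 0), tolerance = 1e-12)
  expect_equal(same$coords[2, , ], base, tolerance = 1e-12)

  shifted <- superpose(two_frame_ensemble(base, sweep(base, 2, c(1, -2, 3),
                                                      `+`)))
  expect_lt(shifted$rmsd[2], 1e-12)
})

test_that("a known rotation is undone to within 1e-8", {
  base <- gen_ensemble(seed = 2, n_res = 15, n_frames = 2,
                       sigma_nm = 0)$ensemble$coords[1, , ]
  for (seed in 1:10) {
    r <- with_seed(seed, random_rotation())
    shift <- with_seed(seed + 50, stats::runif(3, -2, 2))
    moved <- sweep(base %*% r, 2, shift, `+`)
    sup <- superpose(two_frame_ensemble(base, moved))
    expect_lt(sup$rmsd[2], 1e-8)
    expect_equal(sup$coords[2, , ], base, tolerance = 1e-8)
    # the fitted transform is the inverse of the applied rotation
    got_r <- flexistab:::kabsch_rotation(
      sweep(moved, 2, colMeans(moved)), sweep(base, 2, colMeans(base)))
    expect_equal(got_r, t(r), tolerance = 1e-8)
  }
})

test_that("underdetermined selections are rejected", {
  line <- cbind(0.38 * (0:9), 0, 0)
  expect_error(superpose(two_frame_ensemble(line, line)),
               "collinear")
  tiny <- cbind(c(0, 0.38), 0, 0)
  expect_error(superpose(two_frame_ensemble(tiny, tiny)),
               ">= 3 selected atoms")
})

test_that("superposition matches the bio3d reference implementation", {
  g <- gen_ensemble(seed = 3, n_res = 12, n_frames = 20, sigma_nm = 0.08,
                    rigid_transforms = TRUE)
  sup <- superpose(g$ensemble)
  # independent route: bio3d fit.xyz on the same coordinates
  f <- g$ensemble$n_frames
  xyz <- t(apply(g$ensemble$coords, 1, function(m) as.numeric(t(m))))
  fitted <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = 1:ncol(xyz),
                           mobile.inds = 1:ncol(xyz))
  ref_rmsd <- vapply(seq_len(f), function(i)
    sqrt(mean(colSums(matrix((fitted[i, ] - xyz[1, ])^2, nrow = 3)))),
    numeric(1))
  expect_equal(sup$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("superposition never increases selection RMSD", {
  for (seed in 4:8) {
    g <- gen_ensemble(seed = seed, n_res = 10, n_frames = 15,
                      sigma_nm = 0.1, rigid_transforms = (seed %% 2 == 0))
    raw <- g$ensemble
    sup <- superpose(raw)
    before <- vapply(seq_len(raw$n_frames), function(i)
      sqrt(mean(rowSums((raw$coords[i, , ] - raw$coords[1, , ])^2))),
      numeric(1))
    expect_true(all(sup$rmsd <= before + 1e-12))
  }
})

test_that("RMSF is zero for a frozen ensemble and exact for a hand case", {
  g <- gen_ensemble(seed = 5, n_res = 8, n_frames = 5, sigma_nm = 0)
  r <- compute_rmsf(g$ensemble, check_superposed = FALSE)
  expect_equal(r$rmsf_nm, rep(0, 8))

  # one atom at (0,0,0) and (0,0,0.2): fluctuation 0.1 nm about the mean
  a <- cbind(c(0, 0.38, 0, 0.38), c(0, 0, 0.38, 0.38), 0)
  b <- a; b[1, 3] <- 0.2
  e <- two_frame_ensemble(a, b)
  r2 <- compute_rmsf(e, check_superposed = FALSE)
  expect_equal(r2$rmsf_nm[1], 0.1, tolerance = 1e-12)

  one <- gen_ensemble(seed = 6, n_res = 4, n_frames = 2, sigma_nm = 0)
  one$ensemble$coords <- one$ensemble$coords[1, , , drop = FALSE]
  one$ensemble$n_frames <- 1L
  expect_error(compute_rmsf(one$ensemble, check_superposed = FALSE),
               "insufficient frames")
})

test_that("isotropic Gaussian displacement gives RMSF = sigma*sqrt(3)", {
  g <- gen_ensemble(seed = 7, n_res = 10, n_frames = 2000, sigma_nm = 0.1)
  r <- compute_rmsf(g$ensemble, check_superposed = FALSE)
  expect_equal(r$rmsf_nm, rep(0.1 * sqrt(3), 10), tolerance = 0.04)
})

test_that("RMSF is invariant under a global rigid transform", {
  g <- gen_ensemble(seed = 8, n_res = 10, n_frames = 50, sigma_nm = 0.06)
  sup <- superpose(g$ensemble)
  r1 <- compute_rmsf(sup)
  rot <- with_seed(9, random_rotation())
  moved <- g$ensemble
  for (i in seq_len(moved$n_frames))
    moved$coords[i, , ] <- sweep(moved$coords[i, , ] %*% rot, 2,
                                 c(5, -1, 2), `+`)
  r2 <- compute_rmsf(superpose(moved))
  expect_equal(r2$rmsf_nm, r1$rmsf_nm, tolerance = 1e-9)
})

test_that("hydrogen-bond occupancy counts frames satisfying the criterion", {
  g <- gen_ensemble(seed = 10, n_res = 15, n_frames = 40, sigma_nm = 0.02,
                    hbond = list(donor_res = 3, acceptor_res = 11,
                                 occupancy_frac = 1))
  expect_equal(hbond_occupancy(g$ensemble, "3:CA", "11:CA")$occupancy_pct,
               100)
  g0 <- gen_ensemble(seed = 11, n_res = 15, n_frames = 40, sigma_nm = 0.02,
                     hbond = list(donor_res = 3, acceptor_res = 11,
                                  occupancy_frac = 0))
  expect_equal(hbond_occupancy(g0$ensemble, "3:CA", "11:CA")$occupancy_pct, 0)
  g60 <- gen_ensemble(seed = 12, n_res = 15, n_frames = 40, sigma_nm = 0.02,
                      hbond = list(donor_res = 3, acceptor_res = 11,
                                   occupancy_frac = 0.6))
  expect_equal(hbond_occupancy(g60$ensemble, "3:CA", "11:CA")$occupancy_pct,
               60)
  expect_error(hbond_occupancy(g60$ensemble, "3:XX", "11:CA"),
               "atom not found")
})

test_that("occupancy is order-invariant and monotone in the cutoff", {
  g <- gen_ensemble(seed = 13, n_res = 12, n_frames = 30, sigma_nm = 0.05)
  cuts <- seq(0.1, 1.2, by = 0.1)
  occ <- vapply(cuts, function(d)
    hbond_occupancy(g$ensemble, "2:CA", "9:CA",
                    dist_cutoff_nm = d)$occupancy_pct, numeric(1))
  expect_true(all(diff(occ) >= 0))

  perm <- with_seed(14, sample(g$ensemble$n_frames))
  shuffled <- g$ensemble
  shuffled$coords <- shuffled$coords[perm, , , drop = FALSE]
  expect_equal(hbond_occupancy(shuffled, "2:CA", "9:CA", 0.5)$occupancy_pct,
               hbond_occupancy(g$ensemble, "2:CA", "9:CA", 0.5)$occupancy_pct)
})

test_that("the angle test activates only when a hydrogen is given", {
  atoms <- data.frame(chain = "A", res_seq = c(1, 1, 2),
                      res_name = c("SER", "SER", "LYS"),
                      atom_name = c("OG", "HG", "NZ"), element = c("O", "H", "N"))
  # frame 1: linear D-H...A (angle 180); frame 2: H off to the side (90)
  coords <- array(0, dim = c(2, 3, 3))
  coords[1, 1, ] <- c(0, 0, 0);    coords[1, 2, ] <- c(0.1, 0, 0)
  coords[1, 3, ] <- c(0.3, 0, 0)
  coords[2, 1, ] <- c(0, 0, 0);    coords[2, 2, ] <- c(0, 0.1, 0)
  coords[2, 3, ] <- c(0.3, 0, 0)
  e <- conformational_ensemble(atoms, coords)
  plain <- hbond_occupancy(e, "1:OG", "2:NZ")
  expect_equal(plain$occupancy_pct, 100)
  ang <- hbond_occupancy(e, "1:OG", "2:NZ", hydrogen = "1:HG",
                         angle_cutoff_deg = 120)
  expect_equal(ang$occupancy_pct, 50)
})

test_that("multi-MODEL PDB files round-trip through the ensemble reader", {
  f <- tempfile(fileext = ".pdb")
  g <- gen_ensemble(seed = 15, n_res = 9, n_frames = 6, sigma_nm = 0.05,
                    file = f)
  e <- read_ensemble_pdb(f)
  expect_equal(e$n_frames, 6L)
  expect_equal(e$n_atoms, 9L)
  # PDB stores 3 decimals in angstrom: 1e-4 nm resolution
  expect_equal(e$coords, g$ensemble$coords, tolerance = 1e-3)
  expect_equal(e$atoms$res_seq, 1:9)
})
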