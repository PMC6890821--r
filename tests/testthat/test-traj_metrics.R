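test_that("kabsch_superpose recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  sp0 <- kabsch_superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)

  mob <- sweep(ref %*% t(rotation_z(30)), 2, -c(1, 2, 3))
  sp <- kabsch_superpose(mob, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(mob, sp), ref, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch_superpose matches the quaternion oracle", {
  set.seed(99)
  for (i in 1:100) {
    a <- matrix(rnorm(30, sd = 4), 10, 3)
    b <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(kabsch_superpose(b, a)$rmsd, quaternion_rmsd(b, a),
                 tolerance = 1e-8)
  }
})

test_that("RMSD is invariant under a common rigid motion", {
  set.seed(5)
  a <- matrix(rnorm(24, sd = 3), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
  r0 <- kabsch_superpose(b, a)$rmsd
  rot <- rotation_z(77)
  a2 <- sweep(a %*% t(rot), 2, -c(3, -1, 9))
  b2 <- sweep(b %*% t(rot), 2, -c(3, -1, 9))
  expect_equal(kabsch_superpose(b2, a2)$rmsd, r0, tolerance = 1e-10)
})

test_that("rmsd_series is zero on copies and grows with hinge amplitude", {
  m <- make_test_model(20)
  tr <- make_test_trajectory(m, n_frames = 5, sigma = 0)
  rs <- rmsd_series(tr, m, fit = selection_spec("calpha"))
  expect_equal(rs$values, rep(0, 5), tolerance = 1e-9)
  expect_equal(rs$times, (1:5) * 0.1)

  st <- generate_toy_structure(toy_protein_spec(c(30L, 30L)), seed = 2)
  maxima <- vapply(c(1, 2, 4), function(a) {
    tr <- generate_trajectory(st, motion_spec(hinge_amplitude = a,
                                              twist_amplitude = 0,
                                              global_sigma = 0,
                                              n_frames = 40, seed = 3))
    max(rmsd_series(tr, st, fit = selection_spec("calpha"))$values)
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))
})

test_that("all-to-all RMSD matrix matches pairwise superposition", {
  m <- make_test_model(12)
  tr <- make_test_trajectory(m, n_frames = 3, sigma = 1,
                             frame_interval = 1)
  am <- all_to_all_rmsd(tr, fit = selection_spec("calpha"), stride = 1)
  expect_equal(dim(am$matrix), c(3, 3))
  expect_equal(diag(am$matrix), rep(0, 3))
  expect_equal(am$matrix, t(am$matrix), tolerance = 1e-6)
  expect_true(all(am$matrix >= 0))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(am$matrix[i, j],
                 kabsch_superpose(frame_coords(tr, j), frame_coords(tr, i))$rmsd,
                 tolerance = 1e-9)
  }
  # constant trajectory -> zero matrix
  tr0 <- make_test_trajectory(m, n_frames = 4, sigma = 0, frame_interval = 1)
  expect_equal(max(all_to_all_rmsd(tr0, selection_spec("calpha"),
                                   stride = 1)$matrix), 0, tolerance = 1e-9)
  expect_error(all_to_all_rmsd(tr, selection_spec("calpha"), stride = 0.5),
               "stride")
})

test_that("two-state trajectories show block structure in the matrix", {
  m <- make_test_model(15)
  x0 <- coords(m)
  x1 <- sweep(x0, 2, c(0, 0, 0))
  x2 <- x0 %*% t(rotation_z(25))
  x2[1:5, ] <- x2[1:5, ] + 3  # internal change, not removable by fitting
  set.seed(8)
  frames <- c(lapply(1:4, function(i) x1 + rnorm(length(x1), sd = 0.05)),
              lapply(1:4, function(i) x2 + rnorm(length(x1), sd = 0.05)))
  tr <- trajectory(frames, frame_interval = 1, atom_meta = m)
  am <- all_to_all_rmsd(tr, selection_spec("calpha"), stride = 1)$matrix
  within <- c(am[1:4, 1:4][upper.tri(diag(4))],
              am[5:8, 5:8][upper.tri(diag(4))])
  between <- as.numeric(am[1:4, 5:8])
  expect_true(max(within) < min(between))
})

test_that("rmsf reproduces closed-form fluctuation and planted loops", {
  m <- make_test_model(10)
  tr0 <- make_test_trajectory(m, n_frames = 3, sigma = 0)
  prof0 <- rmsf(tr0, fit = selection_spec("calpha"), include_termini = TRUE)
  expect_equal(prof0$values, rep(0, 10), tolerance = 1e-9)
  expect_error(rmsf(make_test_trajectory(m, n_frames = 1),
                    fit = selection_spec("calpha")), "2 frames")

  # one atom oscillating +/- d about its mean with a large rigid scaffold:
  # fit on the immobile scaffold only so the oscillation is not absorbed
  d <- 0.7
  x0 <- coords(m)
  fr1 <- x0; fr2 <- x0
  fr1[5, 1] <- fr1[5, 1] + d
  fr2[5, 1] <- fr2[5, 1] - d
  tr <- trajectory(list(fr1, fr2, fr1, fr2), atom_meta = m)
  prof <- rmsf(tr,
               fit = selection_spec("names",
                                    atom_names = "CA",
                                    residue_range = c(7, 10)),
               measure = selection_spec("calpha"),
               include_termini = TRUE)
  expect_equal(prof$values[prof$residue_numbers == 5], d, tolerance = 1e-9)
  expect_equal(max(prof$values[prof$residue_numbers != 5]), 0,
               tolerance = 1e-9)

  # planted flexible loops exceed the scaffold mean
  st <- generate_toy_structure(seed = 4)
  trl <- generate_trajectory(st, motion_spec(hinge_amplitude = 0,
                                             twist_amplitude = 0,
                                             loop_sigma = 1.2,
                                             global_sigma = 0.1,
                                             n_frames = 60, seed = 5))
  prof <- rmsf(trl, fit = selection_spec("calpha"), include_termini = TRUE)
  loop_mask <- rep(FALSE, length(prof$residue_numbers))
  for (r in default_flexible_regions())
    loop_mask <- loop_mask | (prof$residue_numbers >= r[1] &
                              prof$residue_numbers <= r[2])
  expect_gt(mean(prof$values[loop_mask]), mean(prof$values[!loop_mask]))
})

test_that("rmsf of a self-concatenated trajectory equals the original", {
  m <- make_test_model(8)
  tr <- make_test_trajectory(m, n_frames = 6, sigma = 0.5)
  tr2 <- trajectory(array(tr$coords[rep(1:6, 2), , ],
                          c(12, dim(tr$coords)[2], 3)),
                    atom_meta = m)
  p1 <- rmsf(tr, fit = selection_spec("calpha"), include_termini = TRUE)
  p2 <- rmsf(tr2, fit = selection_spec("calpha"), include_termini = TRUE)
  expect_equal(p1$values, p2$values, tolerance = 1e-9)
})

test_that("terminal residues are excluded from RMSF reports by default", {
  st <- generate_toy_structure(seed = 4)
  tr <- generate_trajectory(st, motion_spec(n_frames = 5, seed = 1))
  prof <- rmsf(tr, fit = selection_spec("calpha"),
               measure = selection_spec("calpha"))
  expect_false(any(prof$residue_numbers %in% c(4:13, 345:354)))
  prof_all <- rmsf(tr, fit = selection_spec("calpha"),
                   measure = selection_spec("calpha"),
                   include_termini = TRUE)
  expect_true(all(4:13 %in% prof_all$residue_numbers))
})

test_that("density_estimate integrates to 1 and matches the normal pdf", {
  set.seed(123)
  x <- rnorm(10000)
  d <- density_estimate(x)
  area <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  at0 <- d$density[which.min(abs(d$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.1)

  u <- runif(5000)
  du <- density_estimate(u, method = "histogram")
  mid <- du$density[du$grid > 0.2 & du$grid < 0.8]
  expect_true(all(abs(mid - 1) < 0.2))
  expect_equal(mean(du$density), 1, tolerance = 0.02)

  expect_warning(dd <- density_estimate(rep(1, 10)), "degenerate")
  expect_equal(dd$method, "histogram")
  expect_error(density_estimate(1), "2 finite")
})

test_that("region flexibility flags exactly the elevated regions", {
  flat <- structure(list(residue_numbers = 14:344,
                         values = rep(1, 331)), class = "rmsf_profile")
  rep0 <- region_flexibility(flat)
  expect_false(any(rep0$flags))

  vals <- rep(1, 331)
  vals[flat$residue_numbers >= 30 & flat$residue_numbers <= 38] <- 5
  prof <- structure(list(residue_numbers = 14:344, values = vals),
                    class = "rmsf_profile")
  rep1 <- region_flexibility(prof)
  expect_equal(unname(rep1$flags), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))

  expect_error(region_flexibility(flat, list(bad = c(1, 5))), "outside")
})

test_that("all six planted flexible regions are flagged on the toy kinase", {
  st <- generate_toy_structure(seed = 6)
  tr <- generate_trajectory(st, motion_spec(hinge_amplitude = 0,
                                            twist_amplitude = 0,
                                            loop_sigma = 1.5,
                                            global_sigma = 0.1,
                                            n_frames = 80, seed = 6))
  prof <- rmsf(tr, fit = selection_spec("calpha"), include_termini = TRUE)
  rep <- region_flexibility(prof)
  expect_true(all(rep$flags))
})
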