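test_that("probe-cluster files parse by block and round-trip", {
  cl <- list(probe_cluster(matrix(rnorm(9), 3, 3), 1, "ethanol"),
             probe_cluster(matrix(rnorm(6) + 10, 2, 3), 2, "benzene"),
             probe_cluster(matrix(rnorm(3) - 10, 1, 3), 3, "urea"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_probe_clusters(cl, path)
  back <- load_probe_clusters(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$coords, unname(cl[[i]]$coords),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back[[i]]$probe_type, cl[[i]]$probe_type)
  }

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_length(load_probe_clusters(empty), 0)

  headerless <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "HETATM    1  C   PRB A   1       1.000   2.000   3.000  1.00  0.00           C",
    headerless)
  expect_warning(one <- load_probe_clusters(headerless), "one cluster")
  expect_length(one, 1)

  expect_warning(probe_cluster(matrix(0, 1, 3), probe_type = "xenon"),
                 "vocabulary")
})

test_that("bounding spheres follow the centroid + max-distance rule", {
  s1 <- bounding_sphere(matrix(c(1, 2, 3), 1, 3))
  expect_equal(s1$center, c(1, 2, 3))
  expect_equal(s1$radius, 0.5)  # singleton floor

  s2 <- bounding_sphere(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(s2$center, c(2, 0, 0))
  expect_equal(s2$radius, 2)

  side <- 2.5
  cube <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  s3 <- bounding_sphere(cube)
  expect_equal(s3$radius, sqrt(3) / 2 * side, tolerance = 1e-9)
  expect_equal(s3$center, rep(side / 2, 3))

  s4 <- bounding_sphere(cube, method = "minimal")
  expect_gte(s4$radius, sqrt(3) / 2 * side - 1e-9)
})

test_that("intersection volume hits all three analytic branches", {
  expect_equal(intersect_volume(sphere(c(0, 0, 0), 1),
                                sphere(c(2, 0, 0), 1 / 0.75)), 0)
  expect_equal(intersect_volume(sphere(c(0, 0, 0), 3),
                                sphere(c(0.5, 0, 0), 1 / 0.75)),
               4 / 3 * pi, tolerance = 1e-12)
  expect_equal(intersect_volume(sphere(c(0, 0, 0), 1),
                                sphere(c(1, 0, 0), 1 / 0.75)),
               5 * pi / 12, tolerance = 1e-12)
  expect_error(sphere(c(0, 0, 0), -1), "radius")
})

test_that("intersection volume is continuous, bounded, and monotone in d", {
  set.seed(61)
  for (i in 1:20) {
    r1 <- runif(1, 0.5, 4); r2 <- runif(1, 0.5, 4)
    eps <- 1e-9
    for (d0 in c(abs(r1 - r2), r1 + r2)) {
      if (d0 == 0) next
      v_lo <- intersect_volume(sphere(c(0, 0, 0), r1),
                               sphere(c(d0 - eps, 0, 0), r2), scale_r2 = 1)
      v_hi <- intersect_volume(sphere(c(0, 0, 0), r1),
                               sphere(c(d0 + eps, 0, 0), r2), scale_r2 = 1)
      expect_lt(abs(v_lo - v_hi), 1e-6)
    }
    ds <- seq(0, r1 + r2 + 1, length.out = 40)
    vs <- vapply(ds, function(d)
      intersect_volume(sphere(c(0, 0, 0), r1), sphere(c(d, 0, 0), r2),
                       scale_r2 = 1), numeric(1))
    expect_true(all(diff(vs) <= 1e-9))
    expect_true(all(vs <= 4 / 3 * pi * min(r1, r2)^3 + 1e-9))
    # symmetry in the unscaled arguments
    expect_equal(intersect_volume(sphere(c(0, 0, 0), r1),
                                  sphere(c(1.7, 0, 0), r2), scale_r2 = 1),
                 intersect_volume(sphere(c(1.7, 0, 0), r2),
                                  sphere(c(0, 0, 0), r1), scale_r2 = 1),
                 tolerance = 1e-12)
  }
})

test_that("intersection volume matches the Monte-Carlo oracle", {
  # spot check here (the full 50-pair sweep runs in the acceptance suite)
  set.seed(71)
  for (i in 1:5) {
    r1 <- runif(1, 1, 3); r2 <- runif(1, 1, 3)
    d <- runif(1, 0.2, 0.9 * (r1 + r2))
    v <- intersect_volume(sphere(c(0, 0, 0), r1), sphere(c(d, 0, 0), r2),
                          scale_r2 = 1)
    v_mc <- mc_intersect_volume(c(0, 0, 0), r1, c(d, 0, 0), r2, n = 2e5)
    if (v > 0.5) expect_equal(as.numeric(v_mc), v, tolerance = 0.02)
  }
})

test_that("pocket spheres compose bounding_sphere over lining heavy atoms", {
  at <- data.frame(serial = 1:3, name = c("CA", "CA", "H"),
                   residue_name = "ALA", chain = "A",
                   residue_number = c(1, 2, 2),
                   x = c(0, 6, 50), y = 0, z = 0,
                   element = c("C", "C", "H"), het = FALSE)
  m <- structure_model(at)
  p <- pocket_definition("toy", c(1, 2))
  s <- pocket_sphere(m, p)  # hydrogen excluded
  expect_equal(s$center, c(3, 0, 0))
  expect_equal(s$radius, 3)
  expect_error(pocket_sphere(m, pocket_definition("bad", c(1, 9))),
               "absent")
  single <- pocket_sphere(m, pocket_definition("one", 1))
  expect_equal(single$center, c(0, 0, 0))
  expect_equal(single$radius, 0.5)
})

test_that("clusters are assigned to the max-overlap pocket, or unassigned", {
  st <- generate_toy_structure(seed = 8)
  reg <- toy_pocket_registry(st, n_pockets = 3)
  sites <- attr(reg, "sites")
  near <- probe_cluster(sweep(matrix(rnorm(15, sd = 0.5), 5, 3), 2,
                              -sites[[2]]), 1, "phenol")
  far <- probe_cluster(matrix(rnorm(15, sd = 0.5) + 500, 5, 3), 2, "urea")
  asg <- classify_clusters(list(near, far), st, reg)
  expect_equal(asg$pocket, c("site2", NA))
  expect_true(asg$volume[1] > 0)
  # conservation: every cluster appears exactly once
  expect_equal(nrow(asg), 2)
  expect_error(classify_clusters(list(near), st, list()), "empty")
})

test_that("planted clusters are recovered with full accuracy", {
  st <- generate_toy_structure(seed = 8)
  reg <- toy_pocket_registry(st, n_pockets = 4)
  clusters <- plant_probe_clusters(st, attr(reg, "sites"),
                                   n_clusters = 20, spread = 1,
                                   outlier_fraction = 0.1, seed = 13)
  truth <- attr(clusters, "truth_labels")
  asg <- classify_clusters(clusters, st, reg)
  got <- ifelse(is.na(asg$pocket), "outlier", asg$pocket)
  expect_equal(got, truth)
})

test_that("ATP-site pockets merge under the ATP label", {
  at <- data.frame(serial = 1:2, name = "CA", residue_name = "ALA",
                   chain = "A", residue_number = 1:2,
                   x = c(0, 3), y = 0, z = 0, element = "C", het = FALSE)
  m <- structure_model(at)
  reg <- structure(list(pocket_definition("ATP", 1, atp_site = TRUE),
                        pocket_definition("ATP-sub", 2, atp_site = TRUE)),
                   class = "pocket_registry")
  cl <- probe_cluster(matrix(c(3, 0, 0), 1, 3), 1, "ethanol")
  asg <- classify_clusters(list(cl), m, reg)
  expect_equal(asg$pocket, "ATP")
})

test_that("reports aggregate consensus strength and call druggability", {
  mk_asg <- function(pockets) data.frame(
    cluster_id = seq_along(pockets), pocket = pockets,
    volume = 1, d = 1, r1 = 1, r2 = 1)
  reg <- load_pocket_registry()
  one <- mk_asg(rep("ATP", 3))
  rep1 <- aggregate_report(list(one), reg)
  expect_equal(unname(rep1$occurrences["ATP"]), 3)
  expect_true(all(is.na(rep1$occurrences[names(rep1$occurrences) != "ATP"])))
  expect_false(rep1$druggable["ATP"])  # 3 < 16

  many <- mk_asg(rep("MKI", 16))
  rep2 <- aggregate_report(list(one, many), reg)
  expect_true(rep2$druggable["MKI"])
  expect_equal(unname(rep2$occurrences["MKI"]), 16)

  none <- mk_asg(c(NA_character_, NA_character_))
  rep3 <- aggregate_report(list(none), reg)
  expect_true(all(is.na(rep3$occurrences)))
  expect_equal(rep3$unassigned, 2)

  # pooled mode: 10 + 10 across snapshots crosses the threshold
  rep4 <- aggregate_report(list(mk_asg(rep("L12", 10)),
                                mk_asg(rep("L12", 10))), reg)
  expect_false(rep4$druggable["L12"])
  rep5 <- aggregate_report(list(mk_asg(rep("L12", 10)),
                                mk_asg(rep("L12", 10))), reg, pooled = TRUE)
  expect_true(rep5$druggable["L12"])

  path <- withr::local_tempfile(fileext = ".csv")
  write_pocket_report(rep1, path)
  back <- utils::read.csv(path)
  expect_equal(back$occurrences[back$pocket == "ATP"], "3")
  expect_true(all(back$occurrences[back$pocket != "ATP"] == "N/A"))
})

test_that("the packaged registry has 19 pockets, 17 of them novel", {
  reg <- load_pocket_registry()
  expect_length(reg, 19)
  nm <- vapply(reg, `[[`, "", "name")
  expect_length(setdiff(nm, c("ATP", "MKI")), 17)
  expect_true(all(vapply(reg, function(p) length(p$lining_residues) >= 3,
                         logical(1))))
})
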