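#' Toy two-domain protein specification
#'
#' The stand-in for a two-lobe kinase: two spatially separated pseudo-
#' residue clusters (one Calpha-like atom per residue by default) with a
#' hinge pivot between them, continuously numbered so the packaged
#' residue-range registries (flexible regions, charged residues up to
#' residue 354) resolve directly.
#'
#' @param n_residues integer(2): residues per domain (default
#'   `c(180, 174)`, a 354-residue construct).
#' @param inter_domain_distance centroid separation, Angstrom.
#' @param loop_regions named list of inclusive residue ranges flagged
#'   flexible (default: the six kinase loop regions).
#' @param atoms_per_residue 1 (Calpha only) or 4 (backbone quad N, CA, C,
#'   O).
#' @return A `toy_protein_spec`.
#' @export
toy_protein_spec <- function(n_residues = c(180L, 174L),
                             inter_domain_distance = 30,
                             loop_regions = default_flexible_regions(),
                             atoms_per_residue = 1L) {
  stopifnot(length(n_residues) == 2, all(n_residues >= 4),
            inter_domain_distance > 0, atoms_per_residue %in% c(1L, 4L))
  structure(list(n_residues = as.integer(n_residues),
                 inter_domain_distance = inter_domain_distance,
                 loop_regions = loop_regions,
                 atoms_per_residue = as.integer(atoms_per_residue)),
            class = "toy_protein_spec")
}

.domain_blob <- function(n, spacing = 3.8) {
  # compact deterministic-shape lattice + seeded jitter (caller sets seed)
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  pts <- as.matrix(g[seq_len(n), ]) * spacing
  pts + matrix(stats::rnorm(n * 3, sd = 0.4), n, 3)
}

#' Generate a toy two-domain structure
#'
#' Deterministic given `seed`. Domain 1 is centred at the origin, domain 2
#' at `inter_domain_distance` along +x (centroids exact); the hinge pivot
#' sits midway between them.
#'
#' @param spec a `toy_protein_spec`.
#' @param seed integer RNG seed.
#' @return A `structure_model` with attributes `domain2_residues`,
#'   `pivot`, `hinge_axis` (z), `twist_axis` (x, the inter-domain axis).
#' @export
generate_toy_structure <- function(spec = toy_protein_spec(), seed = 1) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n1 <- spec$n_residues[1]; n2 <- spec$n_residues[2]
  d1 <- .domain_blob(n1); d2 <- .domain_blob(n2)
  d1 <- sweep(d1, 2, colMeans(d1))
  d2 <- sweep(d2, 2, colMeans(d2))
  d2[, 1] <- d2[, 1] + spec$inter_domain_distance
  xyz <- rbind(d1, d2)
  apr <- spec$atoms_per_residue
  n_res <- n1 + n2
  if (apr == 1L) {
    at <- data.frame(serial = seq_len(n_res), name = "CA",
                     residue_name = "ALA", chain = "A",
                     residue_number = seq_len(n_res),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     element = "C", het = FALSE)
  } else {
    # backbone quad: small fixed offsets around the Calpha position
    off <- rbind(N = c(-1.2, 0.5, 0), CA = c(0, 0, 0),
                 C = c(1.2, 0.5, 0), O = c(1.8, 1.6, 0))
    at <- do.call(rbind, lapply(seq_len(n_res), function(i)
      data.frame(serial = (i - 1L) * 4L + 1:4, name = rownames(off),
                 residue_name = "ALA", chain = "A", residue_number = i,
                 x = xyz[i, 1] + off[, 1], y = xyz[i, 2] + off[, 2],
                 z = xyz[i, 3] + off[, 3], element = c("N", "C", "C", "O"),
                 het = FALSE)))
    rownames(at) <- NULL
  }
  m <- structure_model(at, model_id = 1L)
  attr(m, "domain2_residues") <- (n1 + 1L):n_res
  attr(m, "pivot") <- c(spec$inter_domain_distance / 2, 0, 0)
  attr(m, "hinge_axis") <- c(0, 0, 1)
  attr(m, "twist_axis") <- c(1, 0, 0)
  attr(m, "spec") <- spec
  m
}

# save/restore global RNG state so generators are pure in (spec, seed)
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Motion specification for the toy trajectory generator
#'
#' @param hinge_amplitude hinge ("butterfly") rotation amplitude, degrees.
#' @param twist_amplitude inter-domain twist amplitude, degrees.
#' @param loop_sigma extra Gaussian displacement sd for loop-region atoms,
#'   Angstrom.
#' @param global_sigma isotropic thermal noise sd per coordinate, Angstrom.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param frame_interval ns per frame (default 0.1).
#' @param global_motion add a random rigid motion per frame (removed by
#'   alignment; used to test alignment invariance).
#' @return A `motion_spec`.
#' @export
motion_spec <- function(hinge_amplitude = 5, twist_amplitude = 2,
                        loop_sigma = 0, global_sigma = 0.2,
                        n_frames = 500, seed = 1, frame_interval = 0.1,
                        global_motion = FALSE) {
  stopifnot(hinge_amplitude >= 0, twist_amplitude >= 0, loop_sigma >= 0,
            global_sigma >= 0, n_frames >= 2)
  structure(list(hinge_amplitude = hinge_amplitude,
                 twist_amplitude = twist_amplitude,
                 loop_sigma = loop_sigma, global_sigma = global_sigma,
                 n_frames = as.integer(n_frames), seed = seed,
                 frame_interval = frame_interval,
                 global_motion = global_motion), class = "motion_spec")
}

.rotation_about <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle_rad); s1 <- sin(angle_rad)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(a)
}

.rigid_motion_basis <- function(xyz) {
  # orthonormal basis of the 6 infinitesimal rigid motions of a point set
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  cols <- list()
  for (k in 1:3) {
    v <- matrix(0, n, 3); v[, k] <- 1
    cols[[k]] <- as.numeric(t(v))
  }
  axes <- diag(3)
  for (k in 1:3)
    cols[[3 + k]] <- as.numeric(t(t(apply(rel, 1, function(ri)
      .cross3(axes[k, ], ri)))))
  b <- qr.Q(qr(do.call(cbind, cols)))
  b
}

.mode_jacobian <- function(structure) {
  # Linearized displacement field per radian of hinge / twist rotation of
  # domain 2, projected out of the whole-structure rigid-motion subspace:
  # per-frame superposition absorbs the best-fit rigid component, so the
  # mode that survives alignment (and that PCA can see) is the projected
  # one. Norms are post-projection.
  xyz <- coords(structure)
  d2res <- attr(structure, "domain2_residues")
  mask <- structure$atoms$residue_number %in% d2res
  pivot <- attr(structure, "pivot")
  jac <- function(axis) {
    v <- matrix(0, nrow(xyz), 3)
    r <- sweep(xyz[mask, , drop = FALSE], 2, pivot)
    v[mask, ] <- t(apply(r, 1, function(ri) .cross3(axis, ri)))
    as.numeric(t(v))
  }
  rb <- .rigid_motion_basis(xyz)
  proj <- function(v) v - rb %*% crossprod(rb, v)
  h <- as.numeric(proj(jac(attr(structure, "hinge_axis"))))
  t_ <- as.numeric(proj(jac(attr(structure, "twist_axis"))))
  list(hinge = h, twist = t_,
       hinge_norm = sqrt(sum(h^2)), twist_norm = sqrt(sum(t_^2)))
}

#' Calibrate motion amplitudes to target collective-mode variances
#'
#' Rotation amplitude (degrees) does not map one-to-one onto the variance
#' of the collective coordinate: lever arms set the Jacobian norm of each
#' mode. Given target hinge/twist displacement variances (Angstrom^2 along
#' the normalized mode), solves `A_rad = sqrt(2 var) / |J|` for each.
#'
#' @param structure output of [generate_toy_structure()].
#' @param hinge_var,twist_var target variances, Angstrom^2.
#' @param ... other [motion_spec()] arguments.
#' @return A `motion_spec` with calibrated amplitudes.
#' @export
calibrate_motion <- function(structure, hinge_var = 9, twist_var = 1, ...) {
  j <- .mode_jacobian(structure)
  motion_spec(
    hinge_amplitude = sqrt(2 * hinge_var) / j$hinge_norm * 180 / pi,
    twist_amplitude = sqrt(2 * twist_var) / j$twist_norm * 180 / pi,
    ...)
}

#' Generate a toy two-domain trajectory with planted modes
#'
#' Frame t applies to domain 2 a hinge rotation `A_h sin(2 pi t / T)`
#' (one full cycle over the trajectory) and a twist rotation
#' `A_t sin(4 pi t / T)` (two cycles, so the two angle series are
#' uncorrelated), then adds per-loop Gaussian displacement and global
#' thermal noise. Ground truth (unit mode vectors, per-frame angles,
#' planted mode variances, analytic top-2 variance fraction) is attached
#' as attribute `truth`.
#'
#' @param structure output of [generate_toy_structure()].
#' @param motion a `motion_spec`.
#' @return A `trajectory` with attribute `truth`.
#' @export
generate_trajectory <- function(structure, motion = motion_spec()) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(motion, "motion_spec"))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(motion$seed)
  xyz0 <- coords(structure)
  nat <- nrow(xyz0)
  nf <- motion$n_frames
  d2res <- attr(structure, "domain2_residues")
  mask <- structure$atoms$residue_number %in% d2res
  pivot <- attr(structure, "pivot")
  haxis <- attr(structure, "hinge_axis")
  taxis <- attr(structure, "twist_axis")
  spec <- attr(structure, "spec")
  loop_mask <- rep(FALSE, nat)
  if (!is.null(spec)) for (r in spec$loop_regions)
    loop_mask <- loop_mask |
      (structure$atoms$residue_number >= r[1] &
       structure$atoms$residue_number <= r[2])
  t_seq <- seq_len(nf)
  h_ang <- motion$hinge_amplitude * sin(2 * pi * t_seq / nf)
  t_ang <- motion$twist_amplitude * sin(4 * pi * t_seq / nf)
  co <- array(NA_real_, c(nf, nat, 3))
  for (i in t_seq) {
    fr <- xyz0
    r2 <- sweep(fr[mask, , drop = FALSE], 2, pivot)
    rot <- .rotation_about(haxis, h_ang[i] * pi / 180) %*%
           .rotation_about(taxis, t_ang[i] * pi / 180)
    fr[mask, ] <- sweep(r2 %*% t(rot), 2, -pivot)
    if (motion$loop_sigma > 0 && any(loop_mask))
      fr[loop_mask, ] <- fr[loop_mask, ] +
        matrix(stats::rnorm(sum(loop_mask) * 3, sd = motion$loop_sigma),
               sum(loop_mask), 3)
    if (motion$global_sigma > 0)
      fr <- fr + matrix(stats::rnorm(nat * 3, sd = motion$global_sigma),
                        nat, 3)
    if (motion$global_motion) {
      ax <- stats::rnorm(3); ang <- stats::runif(1, 0, 2 * pi)
      fr <- fr %*% t(.rotation_about(ax, ang))
      fr <- sweep(fr, 2, -stats::rnorm(3, sd = 5))
    }
    co[i, , ] <- fr
  }
  tr <- trajectory(co, frame_interval = motion$frame_interval,
                   atom_meta = structure)
  j <- .mode_jacobian(structure)
  amp_rad <- c(motion$hinge_amplitude, motion$twist_amplitude) * pi / 180
  hv <- amp_rad[1]^2 / 2 * j$hinge_norm^2
  tv <- amp_rad[2]^2 / 2 * j$twist_norm^2
  noise_tr <- 3 * nat * motion$global_sigma^2 +
    3 * sum(loop_mask) * motion$loop_sigma^2
  attr(tr, "truth") <- list(
    hinge_mode = j$hinge / j$hinge_norm,
    twist_mode = j$twist / j$twist_norm,
    hinge_angles = h_ang, twist_angles = t_ang,
    hinge_var = hv, twist_var = tv,
    noise_variance_total = noise_tr,
    top2_fraction = (hv + tv) / (hv + tv + noise_tr))
  tr
}

#' Plant probe clusters around named pocket sites
#'
#' Non-outlier clusters are assigned round-robin to the sites and their
#' member atoms drawn from an isotropic Gaussian of sd `spread` around the
#' site center; outlier clusters are placed on a shell far beyond every
#' site, so their intersection volume with every pocket sphere is zero.
#'
#' @param structure the toy `structure_model` (sets the far-shell scale).
#' @param sites named list of length-3 site centers (e.g. pocket-sphere
#'   centers from [pocket_sphere()]).
#' @param n_clusters total clusters (default 20).
#' @param spread Gaussian sd around the site, Angstrom (default 1).
#' @param outlier_fraction fraction placed beyond all sites (default 0.1).
#' @param atoms_per_cluster member atoms per cluster.
#' @param seed RNG seed.
#' @return list of `probe_cluster` with attribute `truth_labels`
#'   (site name or `"outlier"`).
#' @export
plant_probe_clusters <- function(structure, sites, n_clusters = 20,
                                 spread = 1, outlier_fraction = 0.1,
                                 atoms_per_cluster = 8, seed = 1) {
  stopifnot(length(sites) >= 1, !is.null(names(sites)))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  xyz <- coords(structure)
  ctr <- colMeans(xyz)
  far <- max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) + 60
  n_out <- round(n_clusters * outlier_fraction)
  n_in <- n_clusters - n_out
  labels <- character(n_clusters)
  clusters <- vector("list", n_clusters)
  site_names <- rep(names(sites), length.out = max(n_in, 1))
  for (i in seq_len(n_in)) {
    s <- sites[[site_names[i]]]
    pts <- sweep(matrix(stats::rnorm(atoms_per_cluster * 3, sd = spread),
                        atoms_per_cluster, 3), 2, -as.numeric(s))
    clusters[[i]] <- probe_cluster(pts, cluster_id = i,
                                   probe_type = "ethanol")
    labels[i] <- site_names[i]
  }
  for (i in seq_len(n_out)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    c0 <- ctr + dir * far
    pts <- sweep(matrix(stats::rnorm(atoms_per_cluster * 3, sd = spread),
                        atoms_per_cluster, 3), 2, -c0)
    clusters[[n_in + i]] <- probe_cluster(pts, cluster_id = n_in + i,
                                          probe_type = "benzene")
    labels[n_in + i] <- "outlier"
  }
  attr(clusters, "truth_labels") <- labels
  clusters
}

#' Spatially compact toy pocket registry
#'
#' Picks `n_pockets` well-separated seed residues (greedy maximin over the
#' structure) and takes each seed's nearest neighbours as the lining set,
#' yielding compact, mutually distant pockets suited to end-to-end
#' classification tests.
#'
#' @param structure toy `structure_model`.
#' @param n_pockets number of pockets.
#' @param residues_per_pocket lining residues per pocket.
#' @return A `pocket_registry`; attribute `sites` holds the pocket-sphere
#'   centers.
#' @export
toy_pocket_registry <- function(structure, n_pockets = 4,
                                residues_per_pocket = 4) {
  xyz <- coords(structure)
  rn <- structure$atoms$residue_number
  ca <- structure$atoms$name == "CA"
  xyz <- xyz[ca, , drop = FALSE]; rn <- rn[ca]
  seeds <- integer(n_pockets)
  seeds[1] <- which.max(xyz[, 1])
  for (k in 2:n_pockets) {
    dmin <- apply(xyz, 1, function(p)
      min(sqrt(colSums((t(xyz[seeds[seq_len(k - 1)], , drop = FALSE]) - p)^2))))
    seeds[k] <- which.max(dmin)
  }
  defs <- lapply(seq_len(n_pockets), function(k) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[seeds[k], ])^2))
    lining <- rn[order(d)[seq_len(residues_per_pocket)]]
    pocket_definition(paste0("site", k), lining)
  })
  reg <- structure(defs, class = "pocket_registry")
  sph <- lapply(defs, function(p) pocket_sphere(structure, p))
  attr(reg, "sites") <- stats::setNames(lapply(sph, `[[`, "center"),
                                        vapply(defs, `[[`, "", "name"))
  reg
}

#' Generate paired simulated/experimental observable tables
#'
#' Simulated values are drawn from a wide Gaussian; experimental values
#' follow `exp = slope * sim + intercept + N(0, sigma)`, with
#' `n_outliers` keys displaced by `outlier_scale * sigma` (random sign).
#'
#' @param keys character or integer keys (e.g. residue numbers).
#' @param slope,intercept the true linear relation.
#' @param sigma noise sd.
#' @param n_outliers planted outlier count.
#' @param outlier_scale displacement in units of sigma (default 5).
#' @param sim_sd spread of the simulated values (default 10).
#' @param seed RNG seed.
#' @return list: `sim`, `exp` (named numeric), `outlier_keys`, `slope`,
#'   `intercept`.
#' @export
generate_observables <- function(keys = 1:50, slope = 1, intercept = 0,
                                 sigma = 1, n_outliers = 0,
                                 outlier_scale = 5, sim_sd = 10, seed = 1) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n <- length(keys)
  stopifnot(n >= 2, n_outliers <= n)
  sim <- stats::rnorm(n, sd = sim_sd)
  exp_ <- slope * sim + intercept + stats::rnorm(n, sd = sigma)
  out_idx <- if (n_outliers > 0) sample(n, n_outliers) else integer(0)
  if (length(out_idx))
    exp_[out_idx] <- exp_[out_idx] +
      sample(c(-1, 1), n_outliers, replace = TRUE) * outlier_scale * sigma
  names(sim) <- names(exp_) <- as.character(keys)
  list(sim = sim, exp = exp_, outlier_keys = as.character(keys)[out_idx],
       slope = slope, intercept = intercept)
}
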