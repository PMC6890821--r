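#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over `fit_indices`:
#' centroids are matched and the optimal proper rotation is obtained from
#' the SVD of the covariance between the centred fit sets, forcing
#' determinant +1 (no reflection). The reported RMSD is over the fit atoms
#' after the transform.
#'
#' Apply the result with [apply_superposition()]: `x %*% rotation` then
#' `+ translation` maps mobile coordinates into the reference frame.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom).
#' @param fit_indices row indices used for fitting (default all rows);
#'   applied to both matrices, so both must index valid rows.
#' @return A `superposition_result`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, over the fit set).
#' @export
kabsch_superpose <- function(mobile, reference,
                             fit_indices = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  m <- mobile[fit_indices, , drop = FALSE]
  r <- reference[fit_indices, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("fit sets differ in size")
  if (nrow(m) < 3) stop("need at least 3 fit atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  # degenerate (collinear) sets have rank-deficient covariance
  if (qr(mc)$rank < 2) stop("degenerate (collinear) fit set")
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps row-vectors: x %*% t(rot)
  rot <- t(rot)
  fitted <- mc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  trans <- cr - cm %*% rot
  structure(list(rotation = rot, translation = as.numeric(trans),
                 rmsd = rmsd), class = "superposition_result")
}

#' Apply a superposition to coordinates
#' @param x n x 3 matrix.
#' @param sp a `superposition_result`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(x, sp) {
  sweep(as.matrix(x) %*% sp$rotation, 2, -sp$translation)
}

#' RMSD between two coordinate sets over given indices (no fitting)
#' @keywords internal
.rmsd_raw <- function(a, b, idx = seq_len(nrow(a))) {
  sqrt(mean(rowSums((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2)))
}

#' Per-frame RMSD time series against a reference structure
#'
#' Each frame is Kabsch-fitted to the reference on the `fit` selection
#' (default: backbone of the non-terminal residues 14-344, the convention
#' for this kinase construct) and the RMSD is then measured over the
#' `measure` selection (default: same as fit).
#'
#' @param traj a `trajectory` with `atom_meta`.
#' @param reference a `structure_model` sharing the trajectory topology.
#' @param fit,measure `selection_spec`s.
#' @return An `rmsd_series`: `times` (ns), `values` (Angstrom), selections.
#' @export
rmsd_series <- function(traj, reference,
                        fit = selection_spec("backbone",
                                             residue_range = c(14, 344)),
                        measure = fit) {
  stopifnot(inherits(traj, "trajectory"))
  meta <- if (!is.null(traj$atom_meta)) traj$atom_meta else reference
  fit_idx <- select_atoms(meta, fit)
  mea_idx <- select_atoms(meta, measure)
  ref_fit_idx <- select_atoms(reference, fit)
  ref_mea_idx <- select_atoms(reference, measure)
  if (length(fit_idx) != length(ref_fit_idx) ||
      length(mea_idx) != length(ref_mea_idx))
    stop("selection resolves to different atom counts on trajectory and reference")
  ref <- coords(reference)
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    sp <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                           ref[ref_fit_idx, , drop = FALSE])
    fitted <- apply_superposition(fr, sp)
    vals[i] <- .rmsd_raw(fitted[mea_idx, , drop = FALSE],
                         ref[ref_mea_idx, , drop = FALSE])
  }
  structure(list(times = frame_times(traj), values = vals,
                 fit_selection = fit, measure_selection = measure),
            class = "rmsd_series")
}

#' All-to-all RMSD convergence matrix
#'
#' Entry (i, j) is the RMSD after pairwise Kabsch fitting of frame j onto
#' frame i over the `fit` selection. Frames are subsampled at `stride` ns
#' (default 1 ns). Low-RMSD off-diagonal stripes indicate revisited
#' conformations, the standard convergence diagnostic.
#'
#' @param traj a `trajectory` with `atom_meta`.
#' @param fit a `selection_spec`.
#' @param stride ns between sampled frames; must be a positive multiple of
#'   the trajectory frame interval.
#' @return An `rmsd_matrix`: symmetric matrix (Angstrom), `stride`, sampled
#'   frame times.
#' @export
all_to_all_rmsd <- function(traj,
                            fit = selection_spec("backbone",
                                                 residue_range = c(14, 344)),
                            stride = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (stride < traj$frame_interval)
    stop("stride must be >= frame_interval")
  step <- stride / traj$frame_interval
  if (abs(step - round(step)) > 1e-9)
    stop("stride must be a multiple of frame_interval")
  step <- as.integer(round(step))
  idx_frames <- seq(1L, n_frames(traj), by = step)
  meta <- traj$atom_meta
  if (is.null(meta)) stop("trajectory lacks atom_meta; cannot resolve selection")
  sel <- select_atoms(meta, fit)
  n <- length(idx_frames)
  sub <- lapply(idx_frames, function(i)
    frame_coords(traj, i)[sel, , drop = FALSE])
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- kabsch_superpose(sub[[j]], sub[[i]])$rmsd
  }
  structure(list(matrix = m, stride = stride,
                 times = idx_frames * traj$frame_interval),
            class = "rmsd_matrix")
}

#' Per-residue RMSF profile
#'
#' Frames are fitted to the reference (trajectory `atom_meta`, or an
#' explicit reference) on `fit`; the fluctuation of each residue's
#' `measure` atoms about their time-average positions is then aggregated
#' per residue as the root-mean-square over that residue's atoms and all
#' frames.
#'
#' By default the floppy terminal stretches (residues 4-13 and 345-354)
#' are excluded from the report; set `include_termini = TRUE` to keep them.
#'
#' @param traj a `trajectory` with `atom_meta`.
#' @param fit,measure `selection_spec`s (defaults: backbone fit over
#'   residues 14-344; measure = fit).
#' @param reference optional `structure_model` fit target; default is the
#'   first frame.
#' @param include_termini keep residues 4-13 / 345-354 in the profile.
#' @return An `rmsf_profile`: `residue_numbers`, `values` (Angstrom).
#' @export
rmsf <- function(traj,
                 fit = selection_spec("backbone", residue_range = c(14, 344)),
                 measure = fit, reference = NULL,
                 include_termini = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2) stop("RMSF requires at least 2 frames")
  meta <- traj$atom_meta
  if (is.null(meta)) stop("trajectory lacks atom_meta")
  fit_idx <- select_atoms(meta, fit)
  mea_idx <- select_atoms(meta, measure)
  ref <- if (is.null(reference)) frame_coords(traj, 1) else coords(reference)
  nf <- n_frames(traj)
  aligned <- array(NA_real_, c(nf, length(mea_idx), 3))
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    sp <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                           ref[fit_idx, , drop = FALSE])
    aligned[i, , ] <- apply_superposition(fr, sp)[mea_idx, , drop = FALSE]
  }
  mean_pos <- apply(aligned, c(2, 3), mean)
  # squared deviation from the time-average position, per atom per frame
  sq <- sapply(seq_along(mea_idx), function(a)
    mean(rowSums(sweep(aligned[, a, , drop = TRUE], 2, mean_pos[a, ])^2)))
  resn <- meta$atoms$residue_number[mea_idx]
  per_res <- tapply(sq, resn, mean)  # RMS over the residue's atoms & frames
  residue_numbers <- as.integer(names(per_res))
  values <- sqrt(as.numeric(per_res))
  if (!include_termini) {
    keep <- !(residue_numbers %in% c(4:13, 345:354))
    residue_numbers <- residue_numbers[keep]
    values <- values[keep]
  }
  ord <- order(residue_numbers)
  structure(list(residue_numbers = residue_numbers[ord], values = values[ord]),
            class = "rmsf_profile")
}

#' Probability density estimate of a 1-D sample
#'
#' Gaussian kernel with Scott's bandwidth by default; a histogram density
#' is used as fallback (and automatically when the kernel bandwidth is
#' degenerate, i.e. all samples identical). The returned density is
#' non-negative and integrates to 1 over the grid.
#'
#' @param samples numeric vector (>= 2 finite values).
#' @param method `"kernel"` or `"histogram"`.
#' @param n grid size.
#' @return A `density_estimate`: `grid`, `density`.
#' @export
density_estimate <- function(samples, method = c("kernel", "histogram"),
                             n = 512) {
  method <- match.arg(method)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) stop("need at least 2 finite samples")
  if (method == "kernel" && stats::sd(samples) == 0) {
    warning("degenerate kernel bandwidth (identical samples); using histogram")
    method <- "histogram"
  }
  if (method == "kernel") {
    d <- stats::density(samples, bw = "nrd", n = n)  # Scott's rule
    grid <- d$x; dens <- d$y
  } else {
    h <- graphics::hist(samples, breaks = "Sturges", plot = FALSE)
    grid <- h$mids; dens <- h$density
    if (length(grid) < 2) {  # all mass in one bin
      w <- diff(h$breaks)[1]
      grid <- c(h$mids - w, h$mids, h$mids + w)
      dens <- c(0, h$density, 0)
    }
  }
  # renormalize so the integral is 1 within 1e-3: trapezoid on the kernel
  # grid, exact rectangle rule on histogram bins
  area <- if (method == "kernel")
    sum(diff(grid) * (head(dens, -1) + tail(dens, -1)) / 2)
  else sum(h$density * diff(h$breaks))
  structure(list(grid = grid, density = dens / area, method = method),
            class = "density_estimate")
}

#' Default flexible-region registry of the kinase
#'
#' The six loop/helix regions where elevated backbone flexibility is
#' expected in this kinase family: glycine-rich loop, L6 loop, alphaD
#' helix, activation loop, MAP kinase insert, and L16 loop.
#'
#' @return Named list of inclusive residue ranges `c(lo, hi)`.
#' @export
default_flexible_regions <- function() {
  list("glycine-rich loop" = c(30L, 38L),
       "L6 loop"           = c(93L, 99L),
       "alphaD helix"      = c(113L, 119L),
       "activation loop"   = c(169L, 183L),
       "MAP kinase insert" = c(243L, 261L),
       "L16 loop"          = c(305L, 330L))
}

#' Flag regions of elevated flexibility in an RMSF profile
#'
#' A region is flagged when its mean RMSF exceeds the whole-profile mean.
#'
#' @param profile an `rmsf_profile`.
#' @param regions named list of inclusive residue ranges (default
#'   [default_flexible_regions()]).
#' @return A `region_flexibility_report`: per-region mean RMSF, the
#'   profile mean, and logical flags.
#' @export
region_flexibility <- function(profile, regions = default_flexible_regions()) {
  stopifnot(inherits(profile, "rmsf_profile"))
  rn <- profile$residue_numbers
  lo <- min(rn); hi <- max(rn)
  means <- vapply(regions, function(r) {
    if (r[1] < lo || r[2] > hi)
      stop(sprintf("region [%d,%d] outside profile domain [%d,%d]",
                   r[1], r[2], lo, hi))
    sel <- rn >= r[1] & rn <= r[2]
    mean(profile$values[sel])
  }, numeric(1))
  pm <- mean(profile$values)
  structure(list(regions = regions, mean_rmsf = means,
                 protein_mean_rmsf = pm, flags = means > pm),
            class = "region_flexibility_report")
}

#' @export
print.region_flexibility_report <- function(x, ...) {
  cat(sprintf("region flexibility (protein mean RMSF %.3f A):\n",
              x$protein_mean_rmsf))
  for (i in seq_along(x$regions))
    cat(sprintf("  %-18s %3d-%3d  %.3f A %s\n", names(x$regions)[i],
                x$regions[[i]][1], x$regions[[i]][2], x$mean_rmsf[i],
                if (x$flags[i]) "*" else ""))
  invisible(x)
}
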