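#' Build a combined, aligned Calpha ensemble matrix
#'
#' Every frame of every trajectory is Kabsch-fitted to the reference on
#' Calpha atoms, flattened to a 3n row vector, and stacked; per-frame run
#' labels are preserved so ensembles from different runs (apo/bound,
#' different force fields) can be pooled for a single PCA.
#'
#' @param trajs list of `trajectory` objects sharing Calpha topology with
#'   the reference.
#' @param reference a `structure_model`.
#' @param run_labels character vector, one per trajectory (defaults
#'   run1, run2, ...).
#' @return An `ensemble_matrix`: numeric frames x 3n matrix with
#'   attributes `labels` (per row) and `reference_coords`.
#' @export
build_combined_ensemble <- function(trajs, reference, run_labels = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (is.null(run_labels)) run_labels <- paste0("run", seq_along(trajs))
  stopifnot(length(run_labels) == length(trajs))
  ca_spec <- selection_spec("calpha")
  ref_idx <- select_atoms(reference, ca_spec)
  ref <- coords(reference)[ref_idx, , drop = FALSE]
  rows <- list(); labels <- character(0)
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    meta <- if (!is.null(tr$atom_meta)) tr$atom_meta else reference
    idx <- select_atoms(meta, ca_spec)
    if (length(idx) != nrow(ref))
      stop("Calpha topology mismatch between trajectory ", k,
           " and reference")
    for (i in seq_len(n_frames(tr))) {
      fr <- frame_coords(tr, i)[idx, , drop = FALSE]
      sp <- kabsch_superpose(fr, ref)
      rows[[length(rows) + 1L]] <- as.numeric(t(apply_superposition(fr, sp)))
    }
    labels <- c(labels, rep(run_labels[k], n_frames(tr)))
  }
  m <- do.call(rbind, rows)
  structure(m, labels = labels, reference_coords = ref,
            class = c("ensemble_matrix", class(m)))
}

#' Essential-dynamics PCA of an aligned ensemble
#'
#' Eigendecomposition of the 3n x 3n covariance of the flattened Calpha
#' coordinates about the ensemble mean (no mass weighting by default).
#' For 3n <= 3000 the symmetric eigensolver on the covariance is used;
#' above that, the SVD of the centred data matrix (identical spectra to
#' 1e-6). Eigenvector signs are fixed so each column's largest-magnitude
#' element is positive, making projections reproducible.
#'
#' @param ensemble an `ensemble_matrix` (or plain frames x 3n matrix).
#' @param mass_weight logical; kept as an explicit switch, default off
#'   (uniform weights — Calpha-only ensembles gain nothing from carbon
#'   masses).
#' @return A `pca_model`: `mean`, `eigenvectors` (columns, orthonormal),
#'   `eigenvalues` (Angstrom^2, descending), `n_frames`.
#' @export
fit_pca <- function(ensemble, mass_weight = FALSE) {
  x <- unclass(ensemble)
  attr(x, "labels") <- NULL; attr(x, "reference_coords") <- NULL
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires at least 2 frames")
  if (mass_weight)
    message("mass_weight requested: uniform Calpha masses, no effect")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  p <- ncol(x)
  if (p <= 3000) {
    cv <- crossprod(xc) / (nrow(x) - 1)
    e <- eigen(cv, symmetric = TRUE)
    vec <- e$vectors
    val <- pmax(e$values, 0)
  } else {
    s <- svd(xc, nu = 0)
    vec <- s$v
    val <- s$d^2 / (nrow(x) - 1)
  }
  # deterministic sign: largest-|element| of each mode made positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(mean = mu, eigenvectors = vec, eigenvalues = val,
                 n_frames = nrow(x)), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("pca_model: %d frames, %d coordinates\n",
              x$n_frames, length(x$mean)))
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("  top eigenvalues (A^2): %s\n",
              paste(signif(x$eigenvalues[1:k], 4), collapse = ", ")))
  cat(sprintf("  PC1+PC2 variance fraction: %.3f\n",
              sum(x$eigenvalues[1:min(2, k)]) / tot))
  invisible(x)
}

.flatten_frames <- function(coords_in, model) {
  # accepts: matrix frames x 3n, ensemble_matrix, trajectory, n x 3 matrix,
  # or structure_model; returns frames x 3n matrix
  p <- length(model$mean)
  if (inherits(coords_in, "trajectory")) {
    nf <- n_frames(coords_in)
    out <- matrix(NA_real_, nf, p)
    for (i in seq_len(nf)) out[i, ] <- as.numeric(t(frame_coords(coords_in, i)))
    return(out)
  }
  if (inherits(coords_in, "structure_model"))
    coords_in <- coords(coords_in)
  x <- as.matrix(unclass(coords_in))
  if (ncol(x) == 3 && nrow(x) * 3 == p) return(matrix(as.numeric(t(x)), 1, p))
  if (ncol(x) == p) return(x)
  stop("dimension mismatch: model expects ", p, " coordinates")
}

#' Project conformations onto principal components
#'
#' Projections are the eigenvector-basis coordinates of
#' (conformation - mean). External structures are first Calpha-aligned to
#' the model mean (set `align = FALSE` for frames already in the model
#' frame, e.g. rows of the fitting ensemble).
#'
#' @param model a `pca_model`.
#' @param x frames x 3n matrix, `trajectory`, n x 3 matrix, or
#'   `structure_model`.
#' @param k number of components to return (default all).
#' @param align Kabsch-align each conformation to the model mean before
#'   projecting (default TRUE for structures/trajectories, FALSE for a
#'   plain matrix that is assumed pre-aligned).
#' @return A `projection_series`: frames x k matrix of PC coordinates.
#' @export
project <- function(model, x, k = NULL,
                    align = inherits(x, c("trajectory", "structure_model"))) {
  stopifnot(inherits(model, "pca_model"))
  xm <- .flatten_frames(x, model)
  if (is.null(k)) k <- ncol(model$eigenvectors)
  if (k < 1 || k > ncol(model$eigenvectors)) stop("k out of range")
  if (align) {
    mu <- matrix(model$mean, ncol = 3, byrow = TRUE)
    for (i in seq_len(nrow(xm))) {
      fr <- matrix(xm[i, ], ncol = 3, byrow = TRUE)
      sp <- kabsch_superpose(fr, mu)
      xm[i, ] <- as.numeric(t(apply_superposition(fr, sp)))
    }
  }
  pc <- sweep(xm, 2, model$mean) %*% model$eigenvectors[, seq_len(k),
                                                        drop = FALSE]
  colnames(pc) <- paste0("PC", seq_len(k))
  structure(pc, class = c("projection_series", class(pc)))
}

#' Fraction of total variance captured by the top k modes
#' @param model a `pca_model`.
#' @param k number of leading modes.
#' @return numeric in [0, 1].
#' @export
variance_explained <- function(model, k) {
  stopifnot(inherits(model, "pca_model"))
  if (k < 1 || k > length(model$eigenvalues)) stop("k out of range")
  sum(model$eigenvalues[seq_len(k)]) / sum(model$eigenvalues)
}

#' Extreme structures along a principal component
#'
#' Returns the trajectory frames attaining the minimum and maximum
#' projection on the chosen PC (ties broken by earliest frame), as aligned
#' structures labelled `-axis` / `+axis` — the endpoints used to visualize
#' a mode (e.g. the hinge "butterfly" opening).
#'
#' @param model a `pca_model`.
#' @param series a `projection_series` computed from `traj`.
#' @param traj the `trajectory` the series came from.
#' @param pc component index.
#' @return list with `minus` and `plus` (`structure_model`s when
#'   `traj$atom_meta` is present, else coordinate matrices), and the frame
#'   indices.
#' @export
extreme_structures <- function(model, series, traj, pc = 1) {
  if (pc < 1 || pc > ncol(series)) stop("pc out of range")
  v <- series[, pc]
  i_min <- which.min(v)  # which.min/max take the earliest on ties
  i_max <- which.max(v)
  get_frame <- function(i) {
    fr <- frame_coords(traj, i)
    meta <- traj$atom_meta
    if (is.null(meta)) return(fr)
    at <- meta$atoms
    at$x <- fr[, 1]; at$y <- fr[, 2]; at$z <- fr[, 3]
    structure_model(at, model_id = i)
  }
  list(minus = get_frame(i_min), plus = get_frame(i_max),
       frame_minus = i_min, frame_plus = i_max)
}

#' Linear Cartesian morph between two conformations
#'
#' `b` is Calpha-aligned onto `a`, then coordinates are interpolated
#' linearly in `n_steps` frames with both endpoints reproduced exactly.
#'
#' @param a,b `structure_model`s with identical topology.
#' @param n_steps number of output frames (>= 2).
#' @return A `trajectory` of `n_steps` frames (atom_meta from `a`).
#' @export
morph <- function(a, b, n_steps = 10) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (nrow(a$atoms) != nrow(b$atoms)) stop("topology mismatch")
  ca <- select_atoms(a, selection_spec("calpha"))
  xa <- coords(a); xb <- coords(b)
  sp <- kabsch_superpose(xb, xa, fit_indices = ca)
  xb <- apply_superposition(xb, sp)
  frames <- lapply(seq_len(n_steps), function(i) {
    t <- (i - 1) / (n_steps - 1)
    (1 - t) * xa + t * xb
  })
  trajectory(frames, frame_interval = 1, atom_meta = a)
}

#' Mode-similarity matrix between two PCA models
#'
#' Entry (i, j) is the absolute inner product of eigenvector i of `a`
#' with eigenvector j of `b`, for the top k modes of each — 1 for
#' identical directions, ~0 for orthogonal ones. Used to quantify how
#' similar the essential subspaces of two force fields or runs are.
#'
#' @param a,b `pca_model`s over the same coordinate dimension.
#' @param k number of leading modes to compare.
#' @return k x k matrix with entries in [0, 1], class `mode_overlap_matrix`.
#' @export
mode_overlap <- function(a, b, k = 2) {
  stopifnot(inherits(a, "pca_model"), inherits(b, "pca_model"))
  if (length(a$mean) != length(b$mean)) stop("coordinate dimension mismatch")
  k <- min(k, ncol(a$eigenvectors), ncol(b$eigenvectors))
  m <- abs(crossprod(a$eigenvectors[, seq_len(k), drop = FALSE],
                     b$eigenvectors[, seq_len(k), drop = FALSE]))
  dimnames(m) <- list(paste0("a.PC", seq_len(k)), paste0("b.PC", seq_len(k)))
  structure(m, class = c("mode_overlap_matrix", class(m)))
}

#' Root-mean-square overlap of a model's top-k subspace with target modes
#'
#' For checking planted-mode recovery: the squared projections of each
#' target direction onto the span of the model's top-k eigenvectors,
#' averaged and square-rooted. 1 means the subspace contains the targets.
#'
#' @param model a `pca_model`.
#' @param targets matrix whose columns are unit target directions.
#' @param k subspace size (default = number of targets).
#' @return numeric in [0, 1].
#' @export
subspace_overlap <- function(model, targets, k = ncol(targets)) {
  v <- model$eigenvectors[, seq_len(k), drop = FALSE]
  pr <- crossprod(v, as.matrix(targets))   # k x m
  sqrt(mean(colSums(pr^2)))
}
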