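#' Trajectory container
#'
#' Ordered conformations of a fixed atom set: a frames x atoms x 3 array in
#' Angstrom plus the time spacing between saved frames (default 0.1 ns, the
#' save interval of the production simulations this package targets).
#'
#' @param coords numeric array `c(n_frames, n_atoms, 3)`, or a list of
#'   n_atoms x 3 matrices.
#' @param frame_interval time per saved frame, ns (> 0).
#' @param atom_meta optional reference `structure_model` whose atom order
#'   matches the second array dimension.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, frame_interval = 0.1, atom_meta = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    n <- length(coords)
    stopifnot(n >= 1)
    a <- array(NA_real_, c(n, nrow(coords[[1]]), 3))
    for (i in seq_len(n)) a[i, , ] <- as.matrix(coords[[i]])
    coords <- a
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (!is.null(atom_meta)) {
    stopifnot(inherits(atom_meta, "structure_model"))
    if (nrow(atom_meta$atoms) != dim(coords)[2])
      stop("atom_meta atom count does not match trajectory")
  }
  structure(list(coords = coords, frame_interval = frame_interval,
                 atom_meta = atom_meta), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frames x %d atoms (%.3g ns/frame, %.3g ns total)\n",
              d[1], d[2], x$frame_interval, d[1] * x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame times of a trajectory, ns
#' @param traj a `trajectory`.
#' @return numeric vector (first frame at one frame_interval).
#' @export
frame_times <- function(traj) seq_len(n_frames(traj)) * traj$frame_interval

#' Extract one frame as a coordinate matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Build a trajectory from multi-model structures
#' @param models list of `structure_model` with identical atom counts.
#' @param frame_interval ns per frame.
#' @return A `trajectory` whose `atom_meta` is the first model.
#' @export
trajectory_from_models <- function(models, frame_interval = 0.1) {
  stopifnot(length(models) >= 1)
  nat <- vapply(models, function(m) nrow(m$atoms), integer(1))
  if (length(unique(nat)) != 1L)
    stop("models differ in atom count; cannot form a trajectory")
  trajectory(lapply(models, coords), frame_interval, atom_meta = models[[1]])
}

# ---- DCD binary trajectory format (CHARMM/NAMD dialect) ----------------

.read_record <- function(con, what, size, endian) {
  len <- readBin(con, "integer", 1, 4, endian = endian)
  if (!length(len)) return(NULL)
  dat <- readBin(con, what, len / size, size, endian = endian)
  tail <- readBin(con, "integer", 1, 4, endian = endian)
  if (!length(tail) || tail != len) stop("corrupt DCD record framing")
  dat
}

#' Read a DCD binary trajectory
#'
#' Supports the common CHARMM/NAMD single-precision layout (with or without
#' per-frame unit-cell records); byte order is auto-detected. Coordinates
#' are taken as Angstrom.
#'
#' @param path DCD file.
#' @param atom_meta optional reference `structure_model`.
#' @param frame_interval ns per saved frame (DCD stores step counts, not
#'   wall-clock spacing; supply the save interval, default 0.1).
#' @return A `trajectory`.
#' @export
read_dcd <- function(path, atom_meta = NULL, frame_interval = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  marker <- readBin(con, "integer", 1, 4, endian = "little")
  endian <- if (identical(marker, 84L)) "little" else {
    m2 <- .swap_int(marker)
    if (identical(m2, 84L)) "big" else stop("not a DCD file: ", path)
  }
  hdr_raw <- readBin(con, "raw", 84)
  tail <- readBin(con, "integer", 1, 4, endian = endian)
  if (tail != 84L) stop("corrupt DCD header")
  magic <- rawToChar(hdr_raw[1:4])
  if (magic != "CORD") stop("not a coordinate DCD (magic '", magic, "')")
  icntrl <- readBin(hdr_raw[5:84], "integer", 20, 4, endian = endian)
  has_cell <- icntrl[11] == 1L
  .skip_record(con, endian)  # title block
  natom <- .read_record(con, "integer", 4, endian)
  frames <- list()
  repeat {
    if (has_cell) {
      cell <- .read_record(con, "double", 8, endian)
      if (is.null(cell)) break
    }
    x <- .read_record(con, "double", 4, endian)
    if (is.null(x)) break
    y <- .read_record(con, "double", 4, endian)
    z <- .read_record(con, "double", 4, endian)
    if (length(x) != natom) stop("frame atom count mismatch in ", path)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  if (!length(frames)) stop("DCD contains no frames: ", path)
  trajectory(frames, frame_interval = frame_interval, atom_meta = atom_meta)
}

.skip_record <- function(con, endian) {
  len <- readBin(con, "integer", 1, 4, endian = endian)
  invisible(readBin(con, "raw", len))
  tail <- readBin(con, "integer", 1, 4, endian = endian)
  if (tail != len) stop("corrupt DCD record framing")
}

.swap_int <- function(x) {
  r <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(r, "integer", 1, 4, endian = "big")
}

.write_record <- function(con, dat, what, size) {
  len <- length(dat) * size
  writeBin(as.integer(len), con, 4, endian = "little")
  if (what == "integer") writeBin(as.integer(dat), con, size, endian = "little")
  else writeBin(as.numeric(dat), con, size, endian = "little")
  writeBin(as.integer(len), con, 4, endian = "little")
}

#' Write a trajectory as DCD
#'
#' Emits the plain CHARMM-flavoured single-precision layout (no unit-cell
#' records). Round-trips through [read_dcd()] to float precision.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  nat <- dim(traj$coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp
  writeBin(84L, con, 4, endian = "little")
  writeBin(charToRaw("CORD"), con)
  writeBin(icntrl, con, 4, endian = "little")
  writeBin(84L, con, 4, endian = "little")
  title <- formatC("generated by dynpocket", width = 80, flag = "-")
  writeBin(84L, con, 4, endian = "little")  # title record: ntitle + 80 chars
  writeBin(1L, con, 4, endian = "little")
  writeBin(charToRaw(title), con)
  writeBin(84L, con, 4, endian = "little")
  .write_record(con, nat, "integer", 4)
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    .write_record(con, fr[, 1], "double", 4)
    .write_record(con, fr[, 2], "double", 4)
    .write_record(con, fr[, 3], "double", 4)
  }
  invisible(path)
}
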