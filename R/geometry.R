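#' Atom specification
#'
#' Identifies a single atom by residue number and atom name (optionally
#' chain and/or residue name, e.g. to address ligand HETATM records).
#'
#' @param residue_number author residue number.
#' @param atom_name PDB atom name (e.g. `"N"`, `"CA"`, `"NB1"`).
#' @param chain optional chain id.
#' @param residue_name optional 3-letter code filter.
#' @return An `atom_spec`.
#' @export
atom_spec <- function(residue_number, atom_name, chain = NULL,
                      residue_name = NULL) {
  structure(list(residue_number = as.integer(residue_number),
                 atom_name = atom_name, chain = chain,
                 residue_name = residue_name), class = "atom_spec")
}

.describe_spec <- function(spec) {
  paste0(if (!is.null(spec$residue_name)) paste0(spec$residue_name, " "),
         spec$residue_number, ":", spec$atom_name,
         if (!is.null(spec$chain)) paste0(" chain ", spec$chain))
}

#' Resolve an atom spec to a single atom index
#' @param model a `structure_model`.
#' @param spec an `atom_spec`.
#' @return integer row index into `model$atoms`.
#' @export
resolve_atom <- function(model, spec) {
  at <- model$atoms
  keep <- at$residue_number == spec$residue_number & at$name == spec$atom_name
  if (!is.null(spec$chain)) keep <- keep & at$chain == spec$chain
  if (!is.null(spec$residue_name))
    keep <- keep & at$residue_name == spec$residue_name
  idx <- which(keep)
  if (length(idx) == 0)
    stop("atom not found: ", .describe_spec(spec))
  if (length(idx) > 1)
    stop("ambiguous atom spec (", length(idx), " matches): ",
         .describe_spec(spec))
  idx
}

#' Interatomic distance time series
#'
#' Euclidean distance between two atoms in every frame. To follow a
#' backbone-amide hydrogen bond, address the amide nitrogen (`"N"`): donor
#' hydrogens are not reliably present in crystal-derived inputs.
#'
#' @param traj a `trajectory` with `atom_meta`.
#' @param a,b `atom_spec`s; must resolve to distinct atoms.
#' @return A `distance_series`: `times` (ns), `values` (Angstrom),
#'   endpoint descriptors.
#' @export
atom_distance_series <- function(traj, a, b) {
  meta <- traj$atom_meta
  if (is.null(meta)) stop("trajectory lacks atom_meta")
  ia <- resolve_atom(meta, a)
  ib <- resolve_atom(meta, b)
  if (ia == ib) stop("atom specs resolve to the same atom: ",
                     .describe_spec(a))
  d <- sqrt(rowSums((traj$coords[, ia, , drop = TRUE] -
                     traj$coords[, ib, , drop = TRUE])^2))
  if (n_frames(traj) == 1L)
    d <- sqrt(sum((traj$coords[1, ia, ] - traj$coords[1, ib, ])^2))
  structure(list(times = frame_times(traj), values = d,
                 endpoints = list(.describe_spec(a), .describe_spec(b))),
            class = "distance_series")
}

#' Ring specification for stacking-distance measurements
#'
#' @param residue_number anchor residue number (protein ring) or ligand
#'   residue number.
#' @param atom_names member atom names (typically the 6 ring atoms, >= 3).
#' @param residue_name optional 3-letter code filter.
#' @return A `ring_spec`.
#' @export
ring_spec <- function(residue_number, atom_names, residue_name = NULL) {
  if (length(atom_names) < 3) stop("a ring needs at least 3 atoms")
  structure(list(residue_number = as.integer(residue_number),
                 atom_names = atom_names, residue_name = residue_name),
            class = "ring_spec")
}

.resolve_ring <- function(model, rs) {
  vapply(rs$atom_names, function(nm)
    resolve_atom(model, atom_spec(rs$residue_number, nm,
                                  residue_name = rs$residue_name)),
    integer(1))
}

#' Ring-center distance time series
#'
#' Distance per frame between the centers of two rings. Centers are
#' unweighted geometric centroids by default (C/N heavy-atom rings differ
#' negligibly from mass-weighted centers and ligand masses are not
#' guaranteed in inputs); set `mass_weight = TRUE` to weight by element
#' mass.
#'
#' @param traj a `trajectory` with `atom_meta`.
#' @param ring_a,ring_b `ring_spec`s.
#' @param mass_weight weight the centers by element mass.
#' @return A `distance_series`.
#' @export
ring_com_distance_series <- function(traj, ring_a, ring_b,
                                     mass_weight = FALSE) {
  meta <- traj$atom_meta
  if (is.null(meta)) stop("trajectory lacks atom_meta")
  ia <- .resolve_ring(meta, ring_a)
  ib <- .resolve_ring(meta, ring_b)
  wts <- function(idx) {
    if (!mass_weight) return(rep(1, length(idx)))
    mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
    m <- mass[meta$atoms$element[idx]]
    m[is.na(m)] <- 12.011
    m
  }
  wa <- wts(ia); wb <- wts(ib)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    fr <- frame_coords(traj, i)
    ca <- colSums(fr[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(fr[ib, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  structure(list(times = frame_times(traj), values = vals,
                 endpoints = list("ring centroid", "ring centroid")),
            class = "distance_series")
}

#' Dihedral angle of four atoms
#'
#' IUPAC convention: cis = 0 degrees, sign positive for counterclockwise
#' rotation looking down the j -> k bond; range (-180, 180].
#'
#' @param model a `structure_model`, or an n x 3 matrix whose first four
#'   rows are the quadruple.
#' @param quad list/vector of four `atom_spec`s (for a model) or ignored
#'   for a 4 x 3 matrix.
#' @return angle in degrees.
#' @export
measure_dihedral <- function(model, quad = NULL) {
  if (inherits(model, "structure_model")) {
    stopifnot(length(quad) == 4)
    idx <- vapply(quad, function(s) resolve_atom(model, s), integer(1))
    if (anyDuplicated(idx)) stop("dihedral atoms must be distinct")
    p <- coords(model)[idx, , drop = FALSE]
  } else {
    p <- as.matrix(model)[1:4, , drop = FALSE]
  }
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: three collinear atoms")
  m1 <- .cross3(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Circular (vector) mean of angles in degrees
#'
#' `atan2` of the mean sine and mean cosine, in (-180, 180]. The mean is
#' undefined when the resultant vector is (numerically) zero, e.g. for
#' antipodal inputs.
#'
#' @param angles numeric vector, degrees.
#' @return mean angle, degrees in (-180, 180].
#' @export
circular_mean_angles <- function(angles) {
  if (!length(angles)) stop("empty angle list")
  rad <- angles * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-9)
    stop("circular mean undefined: resultant vector has zero length")
  ang <- atan2(s, c) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Derive a dihedral restraint from several source structures
#'
#' Measures the same atom quadruple in each structure (through an optional
#' atom-name alias map for ligands whose component names differ from the
#' parameterized names) and takes the circular mean as the equilibrium
#' angle.
#'
#' @param models list of `structure_model`s.
#' @param atom_names character(4): parameterized atom names a_i..a_l.
#' @param residue_number ligand residue number in the structures.
#' @param alias optional named character vector mapping parameterized
#'   names to structure atom names.
#' @param force_constant kJ/(mol rad), default 4184.
#' @param sources labels for the source structures.
#' @return A `dihedral_restraint`: atom names, `equilibrium_angle` (deg),
#'   `force_constant`, per-structure angles, sources.
#' @export
derive_dihedral_restraint <- function(models, atom_names, residue_number,
                                      alias = NULL, force_constant = 4184,
                                      sources = names(models)) {
  stopifnot(length(atom_names) == 4)
  resolved <- if (is.null(alias)) atom_names else {
    out <- ifelse(atom_names %in% names(alias), alias[atom_names], atom_names)
    unname(out)
  }
  angs <- vapply(models, function(m)
    measure_dihedral(m, lapply(resolved, function(nm)
      atom_spec(residue_number, nm))), numeric(1))
  structure(list(atom_names = atom_names,
                 equilibrium_angle = circular_mean_angles(angs),
                 force_constant = force_constant,
                 per_structure = angs, sources = sources),
            class = "dihedral_restraint")
}

#' Packaged dihedral-restraint table for the co-crystallized inhibitor
#'
#' Eight restrained dihedrals (parameterized atom-name quadruples,
#' equilibrium angles in degrees, force constant 4184 kJ/(mol rad)).
#'
#' @return data.frame with columns a_i..a_l, phi_deg, force_constant.
#' @export
dihedral_restraint_table <- function() {
  utils::read.delim(system.file("extdata", "dihedral_restraints.tsv",
                                package = "dynpocket", mustWork = TRUE))
}

#' Export dihedral restraints as TSV
#' @param restraints data.frame like [dihedral_restraint_table()] or a list
#'   of `dihedral_restraint` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  if (!is.data.frame(restraints)) {
    restraints <- do.call(rbind, lapply(restraints, function(r)
      data.frame(a_i = r$atom_names[1], a_j = r$atom_names[2],
                 a_k = r$atom_names[3], a_l = r$atom_names[4],
                 phi_deg = r$equilibrium_angle,
                 force_constant = r$force_constant)))
  }
  utils::write.table(restraints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' All-to-all distance matrix of charged residues
#'
#' One representative point per listed residue (Calpha by default; the
#' charged-group sidechain centroid behind `representative = "sidechain"`),
#' distances over the list's order. Two reports over the same residue list
#' are compared with [matrix_discrepancy()].
#'
#' @param model a `structure_model` containing every listed residue.
#' @param residues data.frame (`residue_number`, `residue_name`), e.g.
#'   [charged_residue_table()].
#' @param representative `"calpha"` or `"sidechain"`.
#' @return A `distance_matrix_report`: `residue_keys`, symmetric `matrix`
#'   (Angstrom).
#' @export
charged_distance_matrix <- function(model, residues,
                                    representative = c("calpha", "sidechain")) {
  representative <- match.arg(representative)
  at <- model$atoms
  pts <- matrix(NA_real_, nrow(residues), 3)
  missing <- character(0)
  charged_group <- list(ARG = c("NH1", "NH2", "CZ", "NE"),
                        LYS = "NZ", ASP = c("OD1", "OD2", "CG"),
                        GLU = c("OE1", "OE2", "CD"))
  for (i in seq_len(nrow(residues))) {
    rn <- residues$residue_number[i]
    sel <- which(at$residue_number == rn & !at$het)
    if (representative == "sidechain") {
      grp <- charged_group[[toupper(residues$residue_name[i])]]
      sub <- sel[at$name[sel] %in% grp]
      if (length(sub)) sel <- sub
      else sel <- sel[at$name[sel] == "CA"]
    } else sel <- sel[at$name[sel] == "CA"]
    if (!length(sel)) {
      missing <- c(missing, paste0(residues$residue_name[i], rn))
      next
    }
    pts[i, ] <- colMeans(at[sel, c("x", "y", "z"), drop = FALSE])
  }
  if (length(missing))
    stop("residues absent from model: ", paste(missing, collapse = ", "))
  m <- as.matrix(stats::dist(pts))
  keys <- paste0(residues$residue_name, residues$residue_number)
  dimnames(m) <- list(keys, keys)
  structure(list(residue_keys = keys, matrix = m,
                 representative = representative),
            class = "distance_matrix_report")
}

#' RMS element-wise discrepancy between two distance-matrix reports
#' @param a,b `distance_matrix_report`s over the same residue list.
#' @return numeric, Angstrom.
#' @export
matrix_discrepancy <- function(a, b) {
  stopifnot(inherits(a, "distance_matrix_report"),
            inherits(b, "distance_matrix_report"))
  if (!identical(dim(a$matrix), dim(b$matrix)))
    stop("reports differ in dimension")
  sqrt(mean((a$matrix - b$matrix)^2))
}
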