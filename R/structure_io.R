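# Residues stripped from PDB input unless keep_solvent = TRUE.
.solvent_residues <- c("HOH", "WAT", "DOD", "SOL", "NA", "CL", "K", "MG",
                       "ZN", "CA2", "SO4", "PO4")

#' Construct a structure model
#'
#' A structure model is the in-memory form of one PDB MODEL block: an
#' ordered atom table plus a model identifier. It is the reference topology
#' for trajectories and the substrate of atom selection.
#'
#' @param atoms data.frame with columns `serial`, `name`, `residue_name`,
#'   `chain`, `residue_number`, `x`, `y`, `z`, `element`, and logical `het`.
#'   Coordinates are in Angstrom; residue numbering is author (PDB)
#'   numbering, 1-based.
#' @param model_id integer model identifier.
#' @param caps optional character vector of terminal cap residue names
#'   (e.g. `c("ACE", "NME")`) present in the construct.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, caps = NULL) {
  required <- c("serial", "name", "residue_name", "chain", "residue_number",
                "x", "y", "z", "element", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a model")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  structure(list(atoms = atoms, model_id = as.integer(model_id), caps = caps),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  resn <- unique(x$atoms$residue_number)
  cat(sprintf("structure_model: %d atoms, %d residues (model %d)\n",
              nrow(x$atoms), length(resn), x$model_id))
  invisible(x)
}

#' Coordinates of a structure model as a matrix
#' @param model a `structure_model`.
#' @return numeric n x 3 matrix, Angstrom.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

.parse_pdb_num <- function(field, lineno, what) {
  v <- suppressWarnings(as.numeric(field))
  bad <- which(is.na(v) & nzchar(trimws(field)))
  if (length(bad))
    stop(sprintf("malformed %s field at line %d: '%s'",
                 what, lineno[bad[1]], field[bad[1]]))
  if (anyNA(v))
    stop(sprintf("empty %s field at line %d", what, lineno[which(is.na(v))[1]]))
  v
}

# Keep one altloc per (chain, residue, atom name): highest occupancy,
# ties by altloc letter order. Blank altloc always kept.
.resolve_altlocs <- function(at) {
  has_alt <- nzchar(at$altloc)
  if (!any(has_alt)) return(at)
  key <- paste(at$chain, at$residue_number, at$residue_name, at$name)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) == 1L) next
    ord <- order(-at$occupancy[idx], at$altloc[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  at[keep, , drop = FALSE]
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records with fixed-width columns. Alternate locations
#' are collapsed to the highest-occupancy conformer (ties by altloc letter);
#' water and common monoatomic ions are dropped unless `keep_solvent`.
#' Author residue numbering is preserved.
#'
#' @param path PDB file path.
#' @param model_index integer model number to return, or `"all"` for a list
#'   of every model in file order.
#' @param keep_solvent keep waters/ions (default FALSE).
#' @return A `structure_model`, or a list of them when `model_index = "all"`.
#' @export
read_structure <- function(path, model_index = 1L, keep_solvent = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_no <- cumsum(rec == "MODEL ")
  if (max(model_no) == 0L) model_no <- rep(1L, length(lines))
  models <- list()
  for (m in unique(model_no[is_atom])) {
    sel <- which(is_atom & model_no == m)
    ln <- lines[sel]
    pad <- function(s) formatC(s, width = 80, flag = "-")
    ln <- pad(ln)
    at <- data.frame(
      serial = as.integer(.parse_pdb_num(substr(ln, 7, 11), sel, "serial")),
      name = trimws(substr(ln, 13, 16)),
      altloc = trimws(substr(ln, 17, 17)),
      residue_name = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      residue_number = as.integer(
        .parse_pdb_num(substr(ln, 23, 26), sel, "residue number")),
      x = .parse_pdb_num(substr(ln, 31, 38), sel, "x-coordinate"),
      y = .parse_pdb_num(substr(ln, 39, 46), sel, "y-coordinate"),
      z = .parse_pdb_num(substr(ln, 47, 54), sel, "z-coordinate"),
      occupancy = {
        o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
        ifelse(is.na(o), 1, o)
      },
      element = trimws(substr(ln, 77, 78)),
      het = substr(ln, 1, 6) == "HETATM",
      stringsAsFactors = FALSE)
    # infer element from atom name when column 77-78 is blank
    blank <- !nzchar(at$element)
    at$element[blank] <- substr(gsub("[0-9']", "", at$name[blank]), 1, 1)
    if (!keep_solvent)
      at <- at[!(at$het & at$residue_name %in% .solvent_residues), ,
               drop = FALSE]
    at <- .resolve_altlocs(at)
    at$altloc <- NULL
    at$occupancy <- NULL
    rownames(at) <- NULL
    caps <- intersect(c("ACE", "NME"), unique(at$residue_name))
    models[[length(models) + 1L]] <-
      structure_model(at, model_id = m,
                      caps = if (length(caps)) caps else NULL)
  }
  if (!length(models)) stop("no ATOM/HETATM records in ", path)
  if (identical(model_index, "all")) return(models)
  model_index <- as.integer(model_index)
  if (model_index < 1L || model_index > length(models))
    stop(sprintf("model %d not found (%d models present)",
                 model_index, length(models)))
  models[[model_index]]
}

.format_pdb_atom <- function(at) {
  # atom names: element-justified convention (cols 13-16)
  nm <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
               paste0(" ", formatC(at$name, width = 3, flag = "-")))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(at$het, "HETATM", "ATOM"),
          at$serial %% 100000L, nm, " ", at$residue_name,
          ifelse(nzchar(at$chain), at$chain, "A"),
          at$residue_number %% 10000L, " ",
          at$x, at$y, at$z, 1, 0, at$element)
}

#' Write structure model(s) to a PDB file
#'
#' @param model a `structure_model` or a list of them (written as
#'   MODEL/ENDMDL blocks in order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  models <- if (inherits(model, "structure_model")) list(model) else model
  if (!length(models)) stop("nothing to write")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    m <- models[[i]]
    stopifnot(inherits(m, "structure_model"))
    if (!nrow(m$atoms)) stop("empty model")
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.format_pdb_atom(m$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selection specification
#'
#' @param mode one of `"backbone"` (N, CA, C, O), `"calpha"`, `"all"`, or
#'   `"names"` (explicit `atom_names`).
#' @param residue_range inclusive `c(lo, hi)` author-numbering range, or
#'   `NULL` for all residues.
#' @param atom_names character set, required for `mode = "names"`.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(mode = c("backbone", "calpha", "all", "names"),
                           residue_range = NULL, atom_names = NULL) {
  mode <- match.arg(mode)
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2L || residue_range[1] > residue_range[2])
      stop("residue_range must be c(lo, hi) with lo <= hi")
  }
  if (mode == "names" && !length(atom_names))
    stop("mode 'names' requires atom_names")
  structure(list(mode = mode, residue_range = residue_range,
                 atom_names = atom_names),
            class = "selection_spec")
}

#' Resolve an atom selection on a structure model
#'
#' Deterministic and order-preserving: returned indices follow the model's
#' atom order. An empty selection is an error, never a silent zero-length
#' result.
#'
#' @param model a `structure_model`.
#' @param spec a `selection_spec`.
#' @return integer vector of row indices into `model$atoms`.
#' @export
select_atoms <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"),
            inherits(spec, "selection_spec"))
  at <- model$atoms
  keep <- switch(spec$mode,
    backbone = at$name %in% c("N", "CA", "C", "O") & !at$het,
    calpha   = at$name == "CA" & !at$het,
    all      = rep(TRUE, nrow(at)),
    names    = at$name %in% spec$atom_names)
  if (!is.null(spec$residue_range))
    keep <- keep & at$residue_number >= spec$residue_range[1] &
                   at$residue_number <= spec$residue_range[2]
  idx <- which(keep)
  if (!length(idx)) stop("selection resolves to no atoms")
  idx
}

#' Formal-charge census and counterion count
#'
#' ARG/LYS carry +1, ASP/GLU carry -1, HIS and everything else 0 (neutral
#' tautomer convention); terminal caps contribute nothing. The construct is
#' neutralized with `|net|` monovalent counterions: sodium for a negative
#' net charge, chloride otherwise.
#'
#' @param residues data.frame with columns `residue_name`, `residue_number`.
#' @param caps_present logical; capped termini (ACE/NME) assumed, so no
#'   terminal charges are added either way.
#' @return A `charge_census`: per-residue charges, `net_charge`,
#'   `counterion_species`, `counterion_count`.
#' @export
charge_census <- function(residues, caps_present = TRUE) {
  stopifnot(all(c("residue_name", "residue_number") %in% names(residues)))
  rn <- toupper(residues$residue_name)
  known <- c("ARG", "LYS", "ASP", "GLU", "HIS", "ALA", "ASN", "CYS", "GLN",
             "GLY", "ILE", "LEU", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "ACE", "NME", "HID", "HIE", "HIP")
  unknown <- setdiff(unique(rn), known)
  if (length(unknown))
    warning("unknown residue code(s) treated as neutral: ",
            paste(unknown, collapse = ", "))
  charge <- ifelse(rn %in% c("ARG", "LYS"), 1L,
            ifelse(rn %in% c("ASP", "GLU"), -1L, 0L))
  net <- sum(charge)
  structure(list(
    per_residue_charge = data.frame(
      residue_name = residues$residue_name,
      residue_number = residues$residue_number,
      charge = charge),
    net_charge = as.integer(net),
    counterion_species = if (net < 0) "sodium" else "chloride",
    counterion_count = abs(as.integer(net)),
    caps_present = caps_present), class = "charge_census")
}

#' @export
print.charge_census <- function(x, ...) {
  cat(sprintf("charge_census: %d residues, net %+d -> %d %s counterion(s)\n",
              nrow(x$per_residue_charge), x$net_charge,
              x$counterion_count, x$counterion_species))
  invisible(x)
}

.residue_sequence <- function(model) {
  at <- model$atoms[!model$atoms$het, , drop = FALSE]
  first <- !duplicated(at$residue_number)
  stats::setNames(at$residue_name[first], at$residue_number[first])
}

#' Differences between two sequences over shared numbering
#'
#' Compares per-residue identities only at positions defined in both
#' models (author numbering); missing positions are ignored, not reported.
#'
#' @param a,b `structure_model` objects.
#' @return data.frame with columns `residue_number`, `code_a`, `code_b`,
#'   sorted by position; zero rows when identical.
#' @export
sequence_diff <- function(a, b) {
  sa <- .residue_sequence(a)
  sb <- .residue_sequence(b)
  shared <- intersect(names(sa), names(sb))
  shared <- shared[order(as.integer(shared))]
  diff <- shared[sa[shared] != sb[shared]]
  data.frame(residue_number = as.integer(diff),
             code_a = unname(sa[diff]), code_b = unname(sb[diff]))
}

#' Read a table of residues (number + 3-letter code) from TSV
#' @param path TSV with header columns `residue_number`, `residue_name`.
#' @return data.frame.
#' @export
read_residue_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue_number", "residue_name") %in% names(tab)))
  tab
}

#' Packaged charged-residue list (85 residues of the kinase construct)
#' @return data.frame with `residue_number`, `residue_name`.
#' @export
charged_residue_table <- function() {
  read_residue_table(system.file("extdata", "charged_residues.tsv",
                                 package = "dynpocket", mustWork = TRUE))
}
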