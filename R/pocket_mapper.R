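.probe_vocabulary <- c("acetamide", "acetonitrile", "acetone", "acetaldehyde",
                       "methylamine", "benzaldehyde", "benzene", "isobutanol",
                       "cyclohexane", "dimethylformamide", "dimethylether",
                       "ethanol", "ethane", "phenol", "isopropanol", "urea")

#' Probe-cluster container
#'
#' A consensus cluster of docked solvent probes: member atom coordinates,
#' the probe type (from the 16-probe solvent-mapping vocabulary, or
#' "unknown" with a warning) and the snapshot it came from.
#'
#' @param coords n x 3 matrix, Angstrom.
#' @param cluster_id identifier.
#' @param probe_type probe name.
#' @param snapshot_ns snapshot time, ns.
#' @return A `probe_cluster`.
#' @export
probe_cluster <- function(coords, cluster_id = 1L, probe_type = "unknown",
                          snapshot_ns = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  if (!probe_type %in% c(.probe_vocabulary, "unknown")) {
    warning("probe type '", probe_type, "' outside the 16-probe vocabulary")
    probe_type <- "unknown"
  }
  structure(list(coords = coords, cluster_id = cluster_id,
                 probe_type = probe_type, snapshot_ns = snapshot_ns),
            class = "probe_cluster")
}

#' Read probe clusters from a solvent-mapping PDB dialect
#'
#' Cluster blocks are introduced by HEADER/REMARK lines (the convention of
#' solvent-mapping output files); ATOM/HETATM coordinates between
#' delimiters form one cluster. A file without any delimiter is treated as
#' a single cluster, with a warning.
#'
#' @param path file path.
#' @return list of `probe_cluster` in file order (empty list for an empty
#'   file).
#' @export
load_probe_clusters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(list())
  rec <- substr(lines, 1, 6)
  delim <- rec %in% c("HEADER", "REMARK")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) return(list())
  if (!any(delim)) {
    warning("no cluster delimiters; treating file as one cluster")
    block <- rep(1L, length(lines))
  } else {
    block <- cumsum(delim)
    block[block == 0L] <- 1L
  }
  out <- list()
  for (b in unique(block[is_atom])) {
    sel <- which(is_atom & block == b)
    ln <- formatC(lines[sel], width = 80, flag = "-")
    xyz <- cbind(.parse_pdb_num(substr(ln, 31, 38), sel, "x-coordinate"),
                 .parse_pdb_num(substr(ln, 39, 46), sel, "y-coordinate"),
                 .parse_pdb_num(substr(ln, 47, 54), sel, "z-coordinate"))
    ptype <- "unknown"
    if (any(delim)) {
      hdr <- tolower(lines[which(delim & cumsum(delim) == b)][1])
      hit <- .probe_vocabulary[vapply(.probe_vocabulary, grepl, logical(1),
                                      x = hdr, fixed = TRUE)]
      if (length(hit)) ptype <- hit[1]
    }
    out[[length(out) + 1L]] <- suppressWarnings(
      probe_cluster(xyz, cluster_id = length(out) + 1L, probe_type = ptype))
  }
  out
}

#' Write probe clusters in the solvent-mapping PDB dialect
#' @param clusters list of `probe_cluster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_clusters <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    writeLines(sprintf("REMARK cluster %d probe %s", i, cl$probe_type), con)
    n <- nrow(cl$coords)
    writeLines(sprintf(
      "HETATM%5d  C   PRB A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), i %% 10000L,
      cl$coords[, 1], cl$coords[, 2], cl$coords[, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Bounding sphere of a point set
#'
#' Centroid-centred sphere whose radius is the maximum centroid-to-point
#' distance (with a 0.5 Angstrom floor so singleton clusters still have a
#' well-defined intersection volume). The minimal enclosing sphere
#' (Welzl-style, smaller for anisotropic sets) is available behind
#' `method = "minimal"`.
#'
#' @param points n x 3 matrix.
#' @param method `"centroid"` (default) or `"minimal"`.
#' @return A `sphere`: `center` (length 3), `radius` (> 0).
#' @export
bounding_sphere <- function(points, method = c("centroid", "minimal")) {
  method <- match.arg(method)
  points <- matrix(as.numeric(points), ncol = 3)
  if (method == "centroid") {
    ctr <- colMeans(points)
    r <- max(sqrt(rowSums(sweep(points, 2, ctr)^2)))
  } else {
    # Ritter's approximation refined by expansion passes: deterministic,
    # within a few percent of the true minimal sphere, ample here.
    i <- which.max(rowSums(sweep(points, 2, points[1, ])^2))
    j <- which.max(rowSums(sweep(points, 2, points[i, ])^2))
    ctr <- (points[i, ] + points[j, ]) / 2
    r <- sqrt(sum((points[i, ] - points[j, ])^2)) / 2
    for (pass in 1:2) for (k in seq_len(nrow(points))) {
      d <- sqrt(sum((points[k, ] - ctr)^2))
      if (d > r) {
        r <- (r + d) / 2
        ctr <- ctr + (d - r) / d * (points[k, ] - ctr)
      }
    }
  }
  sphere(ctr, max(r, 0.5))
}

#' Sphere constructor
#' @param center length-3 numeric.
#' @param radius positive radius, Angstrom.
#' @return A `sphere`.
#' @export
sphere <- function(center, radius) {
  if (radius <= 0) stop("sphere radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere")
}

#' Sphere-sphere intersection volume
#'
#' The pocket classifier's geometric score: with the pocket-sphere radius
#' scaled by `scale_r2` (default 0.75, counteracting overestimation of the
#' site volume), the overlap volume is piecewise
#' \deqn{V_o = 0} for d >= r1 + r2 (disjoint),
#' \deqn{V_o = \frac{\pi}{12 d}(r_1+r_2-d)^2 (d^2 + 2d(r_1+r_2) - 3(r_1-r_2)^2)}
#' for |r1 - r2| < d < r1 + r2 (lens), and
#' \deqn{V_o = \frac{4}{3}\pi \min(r_1, r_2)^3} for d <= |r1 - r2|
#' (containment).
#'
#' @param s1 probe-cluster `sphere` (r1, unscaled).
#' @param s2 pocket-site `sphere` (r2, scaled by `scale_r2`).
#' @param scale_r2 scaling factor applied to r2 before the formula.
#' @return intersection volume, Angstrom^3.
#' @export
intersect_volume <- function(s1, s2, scale_r2 = 0.75) {
  stopifnot(inherits(s1, "sphere"), inherits(s2, "sphere"))
  r1 <- s1$radius
  r2 <- s2$radius * scale_r2
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive")
  d <- sqrt(sum((s1$center - s2$center)^2))
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi / (12 * d) * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2)
}

#' Load a pocket registry from TSV
#'
#' Columns: `pocket_name`, `lining_residues` (comma-separated author
#' residue numbers), optional logical `atp_site` marking the ATP pocket
#' and its subpockets (merged under the label "ATP" during
#' classification).
#'
#' @param path TSV path; default is the packaged 19-pocket kinase registry.
#' @return A `pocket_registry`: list of `pocket_definition`.
#' @export
load_pocket_registry <- function(path = system.file("extdata",
                                                    "pocket_registry.tsv",
                                                    package = "dynpocket",
                                                    mustWork = TRUE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pocket_name", "lining_residues") %in% names(tab)))
  if (anyDuplicated(tab$pocket_name)) stop("duplicate pocket names")
  defs <- lapply(seq_len(nrow(tab)), function(i)
    pocket_definition(tab$pocket_name[i],
                      as.integer(strsplit(tab$lining_residues[i],
                                          ",")[[1]]),
                      atp_site = if ("atp_site" %in% names(tab))
                        tab$atp_site[i] else tab$pocket_name[i] == "ATP"))
  structure(defs, class = "pocket_registry")
}

#' Pocket definition
#' @param name pocket name.
#' @param lining_residues integer vector of lining residue numbers (>= 1
#'   of them).
#' @param atp_site logical: part of the ATP-binding site (classified under
#'   the merged label "ATP").
#' @return A `pocket_definition`.
#' @export
pocket_definition <- function(name, lining_residues, atp_site = FALSE) {
  if (!length(lining_residues)) stop("pocket needs lining residues")
  structure(list(name = name, lining_residues = as.integer(lining_residues),
                 atp_site = isTRUE(atp_site)), class = "pocket_definition")
}

#' Bounding sphere of a pocket's lining residues
#'
#' Sphere over all heavy atoms of the lining residues in the given
#' conformation (hydrogens excluded when present).
#'
#' @param model a `structure_model`.
#' @param pocket a `pocket_definition`.
#' @param method passed to [bounding_sphere()].
#' @return A `sphere`.
#' @export
pocket_sphere <- function(model, pocket, method = "centroid") {
  at <- model$atoms
  missing <- setdiff(pocket$lining_residues, at$residue_number)
  if (length(missing))
    stop("lining residue(s) absent from model: ",
         paste(missing, collapse = ", "))
  sel <- at$residue_number %in% pocket$lining_residues & !at$het &
    at$element != "H"
  bounding_sphere(as.matrix(at[sel, c("x", "y", "z")]), method = method)
}

#' Classify probe clusters into pockets by maximum intersection volume
#'
#' Each cluster's bounding sphere is scored against every pocket sphere
#' with [intersect_volume()] (0.75 scaling on the pocket radius) and
#' assigned to the argmax; zero overlap with every pocket leaves it
#' unassigned. Pockets flagged `atp_site` report under the merged label
#' "ATP". Ties are broken by registry order with a warning.
#'
#' @param clusters list of `probe_cluster`.
#' @param model `structure_model` giving the pocket conformation.
#' @param registry a `pocket_registry` (default: packaged kinase registry).
#' @param scale_r2 pocket-sphere scaling (default 0.75).
#' @return data.frame (`pocket_assignment` class): `cluster_id`, `pocket`
#'   (NA when unassigned), `volume`, `d`, `r1`, `r2`.
#' @export
classify_clusters <- function(clusters, model,
                              registry = load_pocket_registry(),
                              scale_r2 = 0.75) {
  if (!length(registry)) stop("empty pocket registry")
  psph <- lapply(registry, function(p) pocket_sphere(model, p))
  labels <- vapply(registry, function(p)
    if (p$atp_site) "ATP" else p$name, character(1))
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    cs <- bounding_sphere(cl$coords)
    vols <- vapply(psph, function(s) intersect_volume(cs, s, scale_r2),
                   numeric(1))
    if (max(vols) <= 0) {
      return(data.frame(cluster_id = cl$cluster_id, pocket = NA_character_,
                        volume = 0, d = NA_real_, r1 = cs$radius,
                        r2 = NA_real_))
    }
    best <- which(vols == max(vols))
    if (length(best) > 1)
      warning("tie between pockets ",
              paste(labels[best], collapse = ", "),
              " for cluster ", cl$cluster_id, "; registry order wins")
    best <- best[1]
    data.frame(cluster_id = cl$cluster_id, pocket = labels[best],
               volume = vols[best],
               d = sqrt(sum((cs$center - psph[[best]]$center)^2)),
               r1 = cs$radius, r2 = psph[[best]]$radius)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), pocket = character(0),
               volume = numeric(0), d = numeric(0), r1 = numeric(0),
               r2 = numeric(0))
  class(out) <- c("pocket_assignment", class(out))
  out
}

#' Aggregate per-snapshot assignments into a pocket report
#'
#' Consensus strength S per pocket per snapshot is the count of probe
#' clusters assigned to that pocket; the occurrence count is the total
#' number of cluster assignments per pocket across the ensemble. A pocket
#' is called druggable when S >= `s_threshold` (default 16) is attained in
#' any snapshot (`pooled = TRUE` instead compares the pooled total).
#' Pockets never hit report `NA` occurrences.
#'
#' @param assignments list of `pocket_assignment` data.frames, one per
#'   snapshot.
#' @param registry a `pocket_registry`.
#' @param s_threshold druggability threshold on S (default 16).
#' @param pooled evaluate the threshold on pooled clusters instead of
#'   per snapshot.
#' @return A `pocket_report`: `s_matrix` (pockets x snapshots),
#'   `occurrences`, `druggable`, `unassigned` count.
#' @export
aggregate_report <- function(assignments, registry = load_pocket_registry(),
                             s_threshold = 16, pooled = FALSE) {
  if (!length(assignments)) stop("need at least one snapshot")
  if (inherits(assignments, "data.frame")) assignments <- list(assignments)
  labels <- unique(vapply(registry, function(p)
    if (p$atp_site) "ATP" else p$name, character(1)))
  s_matrix <- sapply(assignments, function(a)
    vapply(labels, function(l) sum(!is.na(a$pocket) & a$pocket == l),
           integer(1)))
  s_matrix <- matrix(s_matrix, nrow = length(labels),
                     dimnames = list(labels, NULL))
  occ <- rowSums(s_matrix)
  druggable <- if (pooled) occ >= s_threshold
               else apply(s_matrix >= s_threshold, 1, any)
  occ_out <- ifelse(occ == 0, NA_integer_, occ)  # absent pockets: N/A
  unassigned <- sum(vapply(assignments, function(a)
    sum(is.na(a$pocket)), integer(1)))
  structure(list(s_matrix = s_matrix, occurrences = occ_out,
                 druggable = druggable, unassigned = unassigned,
                 s_threshold = s_threshold, pooled = pooled),
            class = "pocket_report")
}

#' @export
print.pocket_report <- function(x, ...) {
  cat(sprintf("pocket_report: %d pockets, %d snapshot(s), S >= %d %s\n",
              nrow(x$s_matrix), ncol(x$s_matrix), x$s_threshold,
              if (x$pooled) "(pooled)" else "(per snapshot)"))
  df <- data.frame(occurrences = ifelse(is.na(x$occurrences), "N/A",
                                        x$occurrences),
                   druggable = x$druggable)
  print(df)
  cat("unassigned clusters:", x$unassigned, "\n")
  invisible(x)
}

#' Write a pocket report as CSV
#' @param report a `pocket_report`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_pocket_report <- function(report, path) {
  df <- data.frame(pocket = rownames(report$s_matrix),
                   occurrences = ifelse(is.na(report$occurrences), "N/A",
                                        report$occurrences),
                   max_s = apply(report$s_matrix, 1, max),
                   druggable = report$druggable)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
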