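.shift_atom_types <- c("CA", "CB", "C", "N", "H")

#' Load an experimental/predicted observable table
#'
#' TSV with a declared header. For `kind = "shifts"`: columns
#' `residue_number`, `atom_type` (one of CA, CB, C, N, H), `shift_ppm`,
#' and optionally `snapshot_ns` for predicted per-snapshot values. For
#' `kind = "rdc"`: columns `residue_number`, `residue_name`, `rdc_hz`.
#' Duplicate (residue, atom) / residue keys are rejected.
#'
#' @param path TSV path.
#' @param kind `"shifts"` or `"rdc"`.
#' @return data.frame of typed records (zero rows, with a warning, for an
#'   empty file).
#' @export
load_observable_table <- function(path, kind = c("shifts", "rdc")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    warning("empty observable table: ", path)
    return(tab)
  }
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at line %d of %s: '%s'",
                   col, bad[1] + 1L, path, tab[[col]][bad[1]]))
    v
  }
  if (kind == "rdc") {
    stopifnot(all(c("residue_number", "residue_name", "rdc_hz") %in%
                    names(tab)))
    tab$rdc_hz <- num_col("rdc_hz")
    if (anyDuplicated(tab$residue_number))
      stop("duplicate residue key(s): ",
           paste(unique(tab$residue_number[duplicated(tab$residue_number)]),
                 collapse = ", "))
  } else {
    stopifnot(all(c("residue_number", "atom_type", "shift_ppm") %in%
                    names(tab)))
    tab$shift_ppm <- num_col("shift_ppm")
    bad_at <- setdiff(unique(tab$atom_type), .shift_atom_types)
    if (length(bad_at))
      stop("unknown atom type(s): ", paste(bad_at, collapse = ", "))
    key <- paste(tab$residue_number, tab$atom_type,
                 if ("snapshot_ns" %in% names(tab)) tab$snapshot_ns else "")
    if (anyDuplicated(key))
      stop("duplicate (residue, atom) key(s) in ", path)
  }
  tab
}

#' Packaged experimental RDC table (39 residues)
#' @return data.frame with `residue_number`, `residue_name`, `rdc_hz`.
#' @export
rdc_table <- function() {
  load_observable_table(system.file("extdata", "rdc_experimental.tsv",
                                    package = "dynpocket", mustWork = TRUE),
                        kind = "rdc")
}

#' Ensemble-average predicted shifts over snapshots
#'
#' Arithmetic mean per (residue, atom_type) key across snapshots, with
#' the contributing snapshot count retained.
#'
#' @param predicted data.frame of predicted shift records with
#'   `residue_number`, `atom_type`, `shift_ppm`, `snapshot_ns`.
#' @return data.frame with `residue_number`, `atom_type`, `shift_ppm`
#'   (mean), `n_snapshots`.
#' @export
ensemble_average <- function(predicted) {
  stopifnot(nrow(predicted) >= 1)
  key <- interaction(predicted$residue_number, predicted$atom_type,
                     drop = TRUE)
  agg <- stats::aggregate(predicted$shift_ppm, by = list(key = key),
                          FUN = function(v) c(mean(v), length(v)))
  parts <- do.call(rbind, strsplit(as.character(agg$key), ".", fixed = TRUE))
  data.frame(residue_number = as.integer(parts[, 1]),
             atom_type = parts[, 2],
             shift_ppm = agg$x[, 1],
             n_snapshots = as.integer(agg$x[, 2]))
}

.match_keyed <- function(sim, exp) {
  shared <- intersect(names(sim), names(exp))
  dropped <- (length(sim) - length(shared)) + (length(exp) - length(shared))
  if (dropped > 0)
    message(dropped, " unmatched record(s) excluded from comparison")
  list(x = unname(sim[shared]), y = unname(exp[shared]), keys = shared)
}

#' Regress experimental observables on simulated ones
#'
#' Ordinary least squares with simulated values on the x-axis and
#' experimental on the y-axis; r^2 is the squared Pearson correlation of
#' the matched pairs. Outliers are the `top_k` keys with the largest
#' absolute residual from the fitted line.
#'
#' @param sim,exp named numeric vectors keyed by residue (or
#'   residue.atom); only the key intersection enters the fit.
#' @param top_k number of outliers to report (default 6).
#' @return A `regression_report`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `outliers` (data.frame key/residual).
#' @export
regress_observables <- function(sim, exp, top_k = 6) {
  m <- .match_keyed(sim, exp)
  if (length(m$x) < 2) stop("fewer than 2 matched keys")
  if (stats::sd(m$x) == 0) stop("degenerate fit: zero variance in simulated values")
  fit <- stats::lm(m$y ~ m$x)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  r2 <- stats::cor(m$x, m$y)^2
  res <- abs(stats::residuals(fit))
  k <- min(top_k, length(res))
  ord <- order(res, decreasing = TRUE)[seq_len(k)]
  structure(list(slope = a, intercept = b, r_squared = r2,
                 n_points = length(m$x),
                 outliers = data.frame(key = m$keys[ord],
                                       residual = unname(res[ord]))),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("regression_report: y = %.4g x + %.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat("top outliers:", paste(x$outliers$key, collapse = ", "), "\n")
  invisible(x)
}

#' Per-snapshot Pearson correlation against experiment
#'
#' Pearson R between each snapshot's simulated values and the experimental
#' set (key intersection per snapshot), plus a probability density of the
#' R values.
#'
#' @param sim_by_snapshot named list of named numeric vectors, one per
#'   snapshot.
#' @param exp named numeric vector of experimental values.
#' @return A `correlation_density`: `r_values`, `density`
#'   (a `density_estimate`, NULL when < 2 snapshots).
#' @export
per_snapshot_correlation <- function(sim_by_snapshot, exp) {
  stopifnot(length(sim_by_snapshot) >= 1)
  r <- vapply(sim_by_snapshot, function(sim) {
    m <- suppressMessages(.match_keyed(sim, exp))
    if (length(m$x) < 2) stop("a snapshot has fewer than 2 matched keys")
    stats::cor(m$x, m$y)
  }, numeric(1))
  dens <- if (length(r) >= 2 && stats::sd(r) > 0) density_estimate(r) else NULL
  structure(list(r_values = r, density = dens),
            class = "correlation_density")
}
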