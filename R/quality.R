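# Map quality against crystallographic contacts, cutoff optimization by
# grid scan, and docking-pose evaluation by RMSD.

#' Score a predicted residue set against a crystallographic reference
#'
#' Reproduction is the number of crystallographic contact residues
#' identified by the site map divided by the number of crystallographic
#' contact residues observed; correctness is the same numerator divided by
#' the total number of mapped residues. Their product is the single-number
#' map-quality score: values near 1 mean the map recovers the
#' crystallographic contacts without erroneous extras.
#'
#' @param predicted character vector of predicted residue labels (for a
#'   site map, the union of the important hydrogen-bond and van der Waals
#'   sets).
#' @param reference character vector of crystallographic contact residues;
#'   must be non-empty.
#' @return Object of class `quality_report`: list with `reproduction`,
#'   `correctness`, `product`, `n_reference`, `n_mapped`.
#' @export
score_map <- function(predicted, reference) {
  reference <- unique(as.character(reference))
  predicted <- unique(as.character(predicted))
  if (length(reference) == 0L) stop("reference residue set is empty")
  hits <- length(intersect(predicted, reference))
  reproduction <- hits / length(reference)
  correctness <- if (length(predicted) == 0L) 0 else hits / length(predicted)
  structure(list(reproduction = reproduction, correctness = correctness,
                 product = reproduction * correctness,
                 n_reference = length(reference),
                 n_mapped = length(predicted)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: reproduction %.2f, correctness %.2f, product %.2f (%d mapped / %d reference)\n",
              x$reproduction, x$correctness, x$product, x$n_mapped, x$n_reference))
  invisible(x)
}

#' Predicted residue set of a site map
#'
#' Union of the important hydrogen-bond and van der Waals residues —
#' the residue-level prediction scored against crystallographic contacts.
#'
#' @param map a [site_map()] with important sets populated.
#' @return character vector of residue labels.
#' @export
mapped_residues <- function(map) {
  sort(union(map$important_hb, map$important_vdw))
}

#' Score a site map against a crystallographic contact set
#'
#' @param map a [site_map()] with important sets populated.
#' @param reference character vector of contact residue labels.
#' @return A `quality_report` (see [score_map()]).
#' @export
map_quality <- function(map, reference) {
  score_map(mapped_residues(map), reference)
}

#' Grid scan of cumulative-sum cutoffs
#'
#' For every pair of hydrogen-bond and van der Waals cutoffs on the given
#' grids (by default 0-100% in 10% steps), the important sets of every
#' case are recomputed, scored against the case's reference set, and the
#' mean and standard deviation of the reproduction-times-correctness
#' product recorded. The best grid point maximizes the mean product; ties
#' go to the lowest hydrogen-bond, then lowest van der Waals cutoff.
#'
#' @param cases list of `list(map = site_map, reference = character)`.
#' @param hb_grid,vdw_grid cutoff grids, fractions in `[0, 1]`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Object of class `cutoff_scan`: list with `grid` (data.frame of
#'   `hb_cutoff`, `vdw_cutoff`, `mean_product`, `sd_product`) and `best`
#'   (one row of `grid`).
#' @export
scan_cutoffs <- function(cases, hb_grid = seq(0, 1, by = 0.1),
                         vdw_grid = seq(0, 1, by = 0.1),
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(cases) == 0L) stop("at least one case is required")
  if (length(hb_grid) == 0L || length(vdw_grid) == 0L) stop("empty cutoff grid")
  if (any(hb_grid < 0 | hb_grid > 1) || any(vdw_grid < 0 | vdw_grid > 1))
    stop("grids must lie in [0, 1]")
  grid <- expand.grid(hb_cutoff = hb_grid, vdw_cutoff = vdw_grid,
                      KEEP.OUT.ATTRS = FALSE)
  prod_at <- function(hc, vc) {
    vapply(cases, function(cs) {
      m <- select_important(cs$map, hc, vc)
      score_map(mapped_residues(m), cs$reference)$product
    }, numeric(1))
  }
  stats_at <- t(mapply(function(hc, vc) {
    p <- prod_at(hc, vc)
    s <- if (length(p) < 2L) 0 else
      if (sd_type == "sample") stats::sd(p) else
        sqrt(mean((p - mean(p))^2))
    c(mean_product = mean(p), sd_product = s)
  }, grid$hb_cutoff, grid$vdw_cutoff))
  grid$mean_product <- stats_at[, "mean_product"]
  grid$sd_product <- stats_at[, "sd_product"]
  ord <- order(-grid$mean_product, grid$hb_cutoff, grid$vdw_cutoff)
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE]),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("cutoff_scan: %d grid points; best (hb=%.2f, vdw=%.2f) mean product %.3f\n",
              nrow(x$grid), x$best$hb_cutoff, x$best$vdw_cutoff,
              x$best$mean_product))
  invisible(x)
}

#' In-place RMSD between a docked pose and a reference ligand
#'
#' Heavy atoms are matched by atom name and the root-mean-square deviation
#' computed without re-superposition, as is standard when evaluating a
#' docking pose against the crystallographic binding mode in the same
#' receptor frame.
#'
#' @param pose ligand `structure_model`.
#' @param reference_ligand crystallographic ligand `structure_model`.
#' @param heavy_only drop hydrogens before matching (default).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, reference_ligand, heavy_only = TRUE) {
  a <- pose$atoms
  b <- reference_ligand$atoms
  if (heavy_only) {
    a <- a[!a$is_hydrogen, , drop = FALSE]
    b <- b[!b$is_hydrogen, , drop = FALSE]
  }
  hit <- match(a$name, b$name)
  ok <- which(!is.na(hit))
  if (length(ok) == 0L)
    stop("no atom-name correspondence between pose and reference ligand")
  dx <- a$x[ok] - b$x[hit[ok]]
  dy <- a$y[ok] - b$y[hit[ok]]
  dz <- a$z[ok] - b$z[hit[ok]]
  sqrt(mean(dx^2 + dy^2 + dz^2))
}

#' Summarize docking performance over a set of cases
#'
#' Aggregates per-case top-ranked-pose RMSD and best-pose RMSD into
#' mean +/- SD rows and counts successes at the conventional 2.0 Angstrom
#' criterion for reproducing a crystallographic binding mode.
#'
#' @param per_case data.frame with columns `top_rmsd`, `best_rmsd` and
#'   optionally `best_rank`; `NA` rows (failed dockings) are dropped
#'   per column.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @param success_threshold RMSD below which a pose counts as a success
#'   (Angstrom).
#' @return Object of class `docking_summary`: per-column `mean`, `sd`,
#'   `n`, `n_success`, plus `sd_undefined` flag when a column has a single
#'   observation.
#' @export
summarize_docking <- function(per_case, sd_type = c("sample", "population"),
                              success_threshold = 2.0) {
  sd_type <- match.arg(sd_type)
  if (nrow(per_case) == 0L) stop("at least one case is required")
  col_stats <- function(x) {
    x <- x[!is.na(x)]
    sd_undef <- length(x) < 2L
    s <- if (sd_undef) 0 else
      if (sd_type == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
    list(mean = mean(x), sd = s, n = length(x),
         n_success = sum(x < success_threshold), sd_undefined = sd_undef)
  }
  structure(list(top = col_stats(per_case$top_rmsd),
                 best = col_stats(per_case$best_rmsd),
                 success_threshold = success_threshold,
                 sd_type = sd_type),
            class = "docking_summary")
}

#' @export
print.docking_summary <- function(x, ...) {
  cat(sprintf("docking_summary (success < %.1f A):\n", x$success_threshold))
  cat(sprintf("  top  pose: %.1f +/- %.1f A (n=%d, %d successes)\n",
              x$top$mean, x$top$sd, x$top$n, x$top$n_success))
  cat(sprintf("  best pose: %.1f +/- %.1f A (n=%d, %d successes)\n",
              x$best$mean, x$best$sd, x$best$n, x$best$n_success))
  invisible(x)
}
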