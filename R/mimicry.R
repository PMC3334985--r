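# Peptide mimicry of carbohydrate recognition: peptide fragmentation,
# pooled fragment maps, and the signed d-statistic comparing two maps.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Fragment a peptide into overlapping windows
#'
#' Mimotope peptides are docked as overlapping short fragments (hexamers
#' by default) because full-length flexible peptides dock poorly; the
#' fragment maps are pooled afterwards with [pool_fragment_tallies()].
#'
#' @param sequence one-letter peptide sequence (20 standard residues).
#' @param window fragment length (default 6).
#' @param step window step (default 1: maximally overlapping).
#' @return Object of class `peptide_fragment_set`: list with `parent`,
#'   `window`, `step`, and `fragments` (character vector, N- to
#'   C-terminal order).
#' @export
fragment_peptide <- function(sequence, window = 6L, step = 1L) {
  sequence <- toupper(trimws(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% AA1))
  if (length(bad) > 0L)
    stop("non-standard residue letter(s) at position(s): ",
         paste(bad, collapse = ", "))
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (length(chars) < window)
    stop("sequence (length ", length(chars),
         ") is shorter than the window (", window, ")")
  starts <- seq.int(1L, length(chars) - window + 1L, by = step)
  frags <- vapply(starts, function(s)
    paste(chars[s:(s + window - 1L)], collapse = ""), character(1))
  structure(list(parent = sequence, window = as.integer(window),
                 step = as.integer(step), fragments = frags),
            class = "peptide_fragment_set")
}

#' @export
print.peptide_fragment_set <- function(x, ...) {
  cat(sprintf("peptide_fragment_set: %s -> %d fragments (window %d, step %d)\n",
              x$parent, length(x$fragments), x$window, x$step))
  invisible(x)
}

#' Pool fragment tallies into one site map
#'
#' Raw interaction counts of all fragments are summed per residue and
#' family first, then normalized once (pool-then-normalize), so fragments
#' with more interactions weigh proportionally more. Pooling a single
#' tally is identical to normalizing it.
#'
#' @param tallies list of [interaction_tally()]s, one per fragment.
#' @return A [site_map()] with pooled contributions.
#' @export
pool_fragment_tallies <- function(tallies) {
  if (length(tallies) == 0L) stop("at least one tally is required")
  sum_family <- function(fam) {
    acc <- integer()
    for (t in tallies) {
      v <- t[[fam]]
      for (nm in names(v)) acc[nm] <- (if (nm %in% names(acc)) acc[nm] else 0L) + v[nm]
    }
    acc
  }
  hb <- sum_family("hb")
  vdw <- sum_family("vdw")
  if ((length(hb) == 0L || sum(hb) == 0) && (length(vdw) == 0L || sum(vdw) == 0))
    stop("pooled tallies contain no interactions")
  res <- unique(do.call(rbind, lapply(tallies, function(t) t$residues)))
  n_poses <- sum(vapply(tallies, function(t) t$n_poses_used, integer(1)))
  normalize_tally(interaction_tally(hb = hb, vdw = vdw,
                                    n_poses_used = n_poses, residues = res))
}

#' Compare two site maps residue-by-residue with the d-statistic
#'
#' Contributions of one family are expressed in percent and each residue
#' becomes a point (x, y) = (carbohydrate %, mimic %). The d-statistic is
#' the signed distance of that point from the line y = x representing
#' equivalent recognition: positive d means the residue interacts more
#' with the mimic, negative d more with the carbohydrate. The default is
#' the perpendicular distance d = (y - x) / sqrt(2) in percentage points;
#' `d_mode = "vertical"` computes y - x instead. Residues with |d| above
#' the threshold (3.00 by default) vary significantly from equivalence.
#'
#' @param carb carbohydrate-derived [site_map()].
#' @param mimic mimic-derived [site_map()].
#' @param family `"HB"` or `"VDW"`.
#' @param d_mode `"perpendicular"` (default) or `"vertical"`.
#' @param threshold significance threshold on |d| (percentage points).
#' @return data.frame over the union of residue supports: `label`,
#'   `carb_pct`, `mimic_pct`, `d`, `significant`, sorted by descending
#'   |d|.
#' @export
compare_maps <- function(carb, mimic, family = c("HB", "VDW"),
                         d_mode = c("perpendicular", "vertical"),
                         threshold = 3.00) {
  family <- match.arg(family)
  d_mode <- match.arg(d_mode)
  fam <- if (family == "HB") "hb" else "vdw"
  labs <- sort(union(names(carb[[fam]]), names(mimic[[fam]])))
  fill <- function(m) {
    v <- m[[fam]][labs]
    100 * ifelse(is.na(v), 0, v)
  }
  x <- fill(carb); y <- fill(mimic)
  d <- if (d_mode == "perpendicular") (y - x) / sqrt(2) else y - x
  out <- data.frame(label = labs, carb_pct = x, mimic_pct = y, d = d,
                    significant = abs(d) > threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$d), out$label), , drop = FALSE]
}

#' Mimicry classification report
#'
#' Counts significant deviations per family and direction and classifies
#' the mimic: a "structural mimic" shows no significant deviation in
#' either family; any significant deviation makes it a "partial
#' structural mimic" (with the divergent residues listed); deviations in
#' both families set the both-family flag.
#'
#' @param hb_comparison,vdw_comparison outputs of [compare_maps()] for the
#'   two families.
#' @param max_significant number of significant residues tolerated before
#'   the classification degrades from full to partial mimicry (default 0).
#' @return Object of class `mimicry_report`: counts per family/direction,
#'   divergent residue labels, `classification`, `both_families` flag.
#' @export
mimicry_report <- function(hb_comparison, vdw_comparison,
                           max_significant = 0L) {
  fam_counts <- function(cmp) {
    sig <- cmp[cmp$significant, , drop = FALSE]
    list(n_significant = nrow(sig),
         n_toward_mimic = sum(sig$d > 0),
         n_toward_carb = sum(sig$d < 0),
         residues = sig$label)
  }
  hb <- fam_counts(hb_comparison)
  vdw <- fam_counts(vdw_comparison)
  total_sig <- hb$n_significant + vdw$n_significant
  classification <- if (total_sig <= max_significant)
    "structural mimic" else "partial structural mimic"
  structure(list(hb = hb, vdw = vdw,
                 classification = classification,
                 both_families = hb$n_significant > 0 && vdw$n_significant > 0),
            class = "mimicry_report")
}

#' @export
print.mimicry_report <- function(x, ...) {
  cat("mimicry_report:", x$classification, "\n")
  cat(sprintf("  HB : %d significant (%d toward mimic, %d toward carbohydrate)\n",
              x$hb$n_significant, x$hb$n_toward_mimic, x$hb$n_toward_carb))
  if (x$hb$n_significant > 0)
    cat("       ", paste(x$hb$residues, collapse = ", "), "\n")
  cat(sprintf("  VDW: %d significant (%d toward mimic, %d toward carbohydrate)\n",
              x$vdw$n_significant, x$vdw$n_toward_mimic, x$vdw$n_toward_carb))
  if (x$vdw$n_significant > 0)
    cat("       ", paste(x$vdw$residues, collapse = ", "), "\n")
  invisible(x)
}
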