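# Site maps: tally interactions over a ranked pose ensemble, normalize
# per interaction family, and select important residues with dual
# cumulative-sum cutoffs.

#' Construct an interaction tally
#'
#' @param hb named non-negative integer vector of hydrogen-bond counts per
#'   residue label.
#' @param vdw named non-negative integer vector of van der Waals counts.
#' @param n_poses_used number of poses the counts were aggregated over.
#' @param residues optional data.frame mapping `label` to `chain`.
#' @return Object of class `interaction_tally`.
#' @export
interaction_tally <- function(hb = integer(), vdw = integer(),
                              n_poses_used = 1L, residues = NULL) {
  if (any(hb < 0) || any(vdw < 0)) stop("counts must be non-negative")
  if (n_poses_used < 1L) stop("n_poses_used must be >= 1")
  structure(list(hb = hb, vdw = vdw, n_poses_used = as.integer(n_poses_used),
                 residues = residues), class = "interaction_tally")
}

#' @export
print.interaction_tally <- function(x, ...) {
  cat(sprintf("interaction_tally: %d HB over %d residues, %d VDW over %d residues (%d poses)\n",
              sum(x$hb), length(x$hb), sum(x$vdw), length(x$vdw), x$n_poses_used))
  invisible(x)
}

records_to_tally <- function(records, n_poses_used,
                             count_mode = c("pair", "residue_per_pose")) {
  count_mode <- match.arg(count_mode)
  if (count_mode == "residue_per_pose" && nrow(records) > 0L)
    records <- records[!duplicated(records[, c("pose_rank", "chain", "label",
                                               "kind")]), , drop = FALSE]
  count_family <- function(kind) {
    r <- records[records$kind == kind, , drop = FALSE]
    if (nrow(r) == 0L) return(integer())
    tab <- table(r$label)
    stats::setNames(as.integer(tab), names(tab))
  }
  res <- if (nrow(records) > 0L)
    unique(records[, c("chain", "label")]) else NULL
  interaction_tally(hb = count_family("HB"), vdw = count_family("VDW"),
                    n_poses_used = n_poses_used, residues = res)
}

#' Tally interactions over the top-ranked poses of an ensemble
#'
#' Interactions occurring in the top `top_n` ranked poses are detected
#' geometrically and tallied per protein residue and interaction type.
#' The counting unit is the atom pair per pose, so one residue can
#' contribute several counts in a single pose; `count_mode =
#' "residue_per_pose"` instead counts a residue at most once per pose and
#' family.
#'
#' @param ensemble a [pose_ensemble()] with its receptor attached.
#' @param criteria an [interaction_criteria()].
#' @param top_n number of top-ranked poses to use (default 100, the
#'   standard ensemble depth for site mapping); fewer are used when the
#'   ensemble is smaller.
#' @param count_mode `"pair"` (default) or `"residue_per_pose"`.
#' @return An [interaction_tally()].
#' @export
tally_ensemble <- function(ensemble, criteria = interaction_criteria(),
                           top_n = 100L,
                           count_mode = c("pair", "residue_per_pose")) {
  count_mode <- match.arg(count_mode)
  if (length(ensemble$poses) == 0L) stop("pose ensemble is empty")
  if (top_n < 1L) stop("top_n must be >= 1")
  if (is.null(ensemble$receptor)) stop("ensemble has no receptor attached")
  n_use <- min(as.integer(top_n), length(ensemble$poses))
  recs <- vector("list", n_use)
  for (i in seq_len(n_use))
    recs[[i]] <- detect_contacts(ensemble$poses[[i]], ensemble$receptor,
                                 criteria, pose_rank = i)
  records_to_tally(do.call(rbind, recs), n_poses_used = n_use,
                   count_mode = count_mode)
}

#' Tally interactions from a precomputed per-pose interaction table
#'
#' Ingests interaction records exported by a docking program or another
#' detection tool, bypassing geometric detection. The table must be a CSV
#' with columns `pose_rank`, `chain`, `residue_label` and `kind`
#' (`HB`/`VDW`); each row is one interaction occurrence, so duplicated
#' rows count twice.
#'
#' @param path CSV file.
#' @param count_mode as in [tally_ensemble()].
#' @return An [interaction_tally()].
#' @export
tally_from_table <- function(path, count_mode = c("pair", "residue_per_pose")) {
  count_mode <- match.arg(count_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("pose_rank", "chain", "residue_label", "kind")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("interaction table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("interaction table is empty")
  bad <- setdiff(unique(df$kind), c("HB", "VDW"))
  if (length(bad) > 0L)
    stop("unknown interaction kind(s): ", paste(bad, collapse = ", "))
  records <- data.frame(chain = df$chain, label = df$residue_label,
                        kind = df$kind, ligand_atom = "", protein_atom = "",
                        pose_rank = as.integer(df$pose_rank),
                        stringsAsFactors = FALSE)
  records_to_tally(records, n_poses_used = max(records$pose_rank),
                   count_mode = count_mode)
}

#' Construct a site map
#'
#' Usually produced by [normalize_tally()] and [select_important()] rather
#' than directly.
#'
#' @param hb,vdw named numeric vectors of per-residue fractional
#'   contributions; each family sums to 1 when non-empty.
#' @param hb_cutoff,vdw_cutoff cumulative-sum cutoffs (fractions).
#' @param important_hb,important_vdw character vectors of selected residue
#'   labels.
#' @param n_poses number of poses behind the map.
#' @param residues optional data.frame mapping `label` to `chain`.
#' @return Object of class `site_map`.
#' @export
site_map <- function(hb = numeric(), vdw = numeric(),
                     hb_cutoff = 0.90, vdw_cutoff = 0.40,
                     important_hb = character(), important_vdw = character(),
                     n_poses = NA_integer_, residues = NULL) {
  for (v in list(hb, vdw)) {
    if (length(v) > 0L) {
      if (is.null(names(v)) || any(names(v) == ""))
        stop("contributions must be named by residue label")
      if (any(v < 0)) stop("contributions must be non-negative")
      if (abs(sum(v) - 1) > 1e-9)
        stop("contributions must sum to 1 per family (got ", sum(v), ")")
    }
  }
  structure(list(hb = hb, vdw = vdw, hb_cutoff = hb_cutoff,
                 vdw_cutoff = vdw_cutoff,
                 important_hb = as.character(important_hb),
                 important_vdw = as.character(important_vdw),
                 n_poses = n_poses, residues = residues),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("site_map: %d HB residues, %d VDW residues (cutoffs %.0f%%/%.0f%%)\n",
              length(x$hb), length(x$vdw), 100 * x$hb_cutoff, 100 * x$vdw_cutoff))
  if (length(x$important_hb) > 0L)
    cat("  important HB: ", paste(x$important_hb, collapse = ", "), "\n", sep = "")
  if (length(x$important_vdw) > 0L)
    cat("  important VDW: ", paste(x$important_vdw, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Normalize an interaction tally into fractional contributions
#'
#' Each residue's count is divided by the total number of interactions
#' observed in its family; normalization is performed separately for
#' hydrogen bonding and van der Waals interactions. A family with zero
#' total yields an empty contribution map with a warning.
#'
#' @param tally an [interaction_tally()].
#' @return A [site_map()] carrying contributions (no important sets yet).
#' @export
normalize_tally <- function(tally) {
  norm1 <- function(counts, fam) {
    if (length(counts) == 0L || sum(counts) == 0) {
      if (length(counts) == 0L || sum(counts) == 0)
        warning("no ", fam, " interactions observed; contribution map is empty")
      return(numeric())
    }
    counts[counts > 0] / sum(counts)
  }
  hb <- norm1(tally$hb, "hydrogen-bond")
  vdw <- norm1(tally$vdw, "van der Waals")
  site_map(hb = hb, vdw = vdw, n_poses = tally$n_poses_used,
           residues = tally$residues)
}

# Cumulative-sum selection for one contribution family. Residues are taken
# in descending contribution order until the running cumulative sum first
# reaches the cutoff; the crossing residue is included, and residues tied
# with it in contribution are all included together. Ties in the sort are
# broken by label for reproducible output.
select_cumulative <- function(contrib, cutoff) {
  if (length(contrib) == 0L || cutoff <= 0) return(character())
  ord <- order(-contrib, names(contrib))
  v <- contrib[ord]
  cum <- cumsum(v)
  k <- which(cum >= cutoff - 1e-12)[1]
  if (is.na(k)) k <- length(v)
  sel <- names(v)[seq_len(k)]
  ties <- names(v)[v == v[k]]
  sort(union(sel, ties))
}

#' Select important residues by cumulative-sum cutoff
#'
#' Normalized contributions are sorted from greatest to least and the
#' cumulative sum computed; all residues up to and including the one at
#' which the cumulative sum first reaches the cutoff are deemed important
#' for recognition. The two families use separate cutoffs; the defaults
#' (90% for hydrogen bonding, 40% for van der Waals) are the optimum found
#' for antibody recognition of acidic sugars. The earlier single-cutoff
#' scheme is recovered by passing the same value (e.g. 0.80) for both.
#'
#' @param map a [site_map()] with contributions.
#' @param hb_cutoff,vdw_cutoff cumulative-sum cutoffs in `[0, 1]`.
#' @return The map with `important_hb`/`important_vdw` populated and the
#'   cutoffs recorded.
#' @export
select_important <- function(map, hb_cutoff = 0.90, vdw_cutoff = 0.40) {
  if (hb_cutoff < 0 || hb_cutoff > 1 || vdw_cutoff < 0 || vdw_cutoff > 1)
    stop("cutoffs must lie in [0, 1]")
  map$hb_cutoff <- hb_cutoff
  map$vdw_cutoff <- vdw_cutoff
  map$important_hb <- select_cumulative(map$hb, hb_cutoff)
  map$important_vdw <- select_cumulative(map$vdw, vdw_cutoff)
  map
}

#' Full site-mapping pipeline for one pose ensemble
#'
#' Tally, normalize and select in one call.
#'
#' @inheritParams tally_ensemble
#' @inheritParams select_important
#' @param map unused; present for generic symmetry.
#' @return A [site_map()] with contributions and important sets.
#' @export
map_ensemble <- function(ensemble, criteria = interaction_criteria(),
                         top_n = 100L, hb_cutoff = 0.90, vdw_cutoff = 0.40,
                         count_mode = c("pair", "residue_per_pose")) {
  tally <- tally_ensemble(ensemble, criteria, top_n,
                          count_mode = match.arg(count_mode))
  select_important(normalize_tally(tally), hb_cutoff, vdw_cutoff)
}
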