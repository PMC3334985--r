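# Dynamic site mapping: maps over multiple receptor conformers,
# ensemble-average maps, per-conformer correlation, conformer selection.

#' Ensemble-average site map over receptor conformers
#'
#' Per-residue arithmetic mean of the contributions over all maps, per
#' interaction family, on the union of residue supports: a residue absent
#' from a conformer's map contributes 0 in that conformer. The averaged
#' families each still sum to 1 when every input map does.
#'
#' @param maps list of at least two [site_map()]s.
#' @return A [site_map()] with averaged contributions.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) < 2L) stop("ensemble averaging needs at least two maps")
  avg1 <- function(fam) {
    labs <- sort(unique(unlist(lapply(maps, function(m) names(m[[fam]])))))
    if (length(labs) == 0L) return(numeric())
    acc <- rowMeans(vapply(maps, function(m) {
      v <- m[[fam]][labs]
      ifelse(is.na(v), 0, v)
    }, numeric(length(labs))))
    stats::setNames(acc, labs)
  }
  res <- unique(do.call(rbind, lapply(maps, function(m) m$residues)))
  hb <- avg1("hb"); vdw <- avg1("vdw")
  # renormalize to absorb floating-point drift only; masses are already ~1
  if (length(hb) > 0L) hb <- hb / sum(hb)
  if (length(vdw) > 0L) vdw <- vdw / sum(vdw)
  site_map(hb = hb, vdw = vdw, residues = res)
}

#' Squared correlation between two site maps
#'
#' Squared Pearson correlation of the per-residue contributions of one
#' interaction family, computed over the union of the two residue
#' supports with zeros filled for absent residues. A constant vector makes
#' the correlation undefined: the result is `NA` with a warning, never a
#' silent 0. `method = "origin"` instead returns the R-squared of a
#' regression through the origin.
#'
#' @param map1,map2 [site_map()]s.
#' @param family `"HB"` or `"VDW"`.
#' @param method `"pearson"` (default) or `"origin"`.
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
map_r2 <- function(map1, map2, family = c("HB", "VDW"),
                   method = c("pearson", "origin")) {
  family <- match.arg(family)
  method <- match.arg(method)
  fam <- if (family == "HB") "hb" else "vdw"
  labs <- sort(union(names(map1[[fam]]), names(map2[[fam]])))
  if (length(labs) < 2L)
    stop("need at least two residues in the union support")
  fill <- function(m) {
    v <- m[[fam]][labs]
    ifelse(is.na(v), 0, v)
  }
  x <- fill(map1); y <- fill(map2)
  if (method == "origin") {
    if (sum(x^2) == 0 || sum(y^2) == 0) {
      warning("zero vector; origin r-squared undefined")
      return(NA_real_)
    }
    return(sum(x * y)^2 / (sum(x^2) * sum(y^2)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant contribution vector; Pearson r-squared undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Conformer similarity score
#'
#' Weighted mean of the hydrogen-bond and van der Waals map correlations,
#' weighted by the respective cumulative-sum cutoffs:
#' `(a * r2_hb + b * r2_vdw) / (a + b)`. With the standard cutoffs
#' (a = 0.9, b = 0.4) the hydrogen-bond agreement dominates, reflecting
#' its greater weight in residue selection.
#'
#' @param r2_hb,r2_vdw squared map correlations in `[0, 1]` (vectorized).
#' @param a hydrogen-bond cutoff used as weight (fraction).
#' @param b van der Waals cutoff used as weight (fraction).
#' @return similarity in `[0, 1]` (full precision; report to 2 decimals).
#' @export
similarity_score <- function(r2_hb, r2_vdw, a = 0.9, b = 0.4) {
  if (a + b <= 0) stop("cutoff weights must satisfy a + b > 0")
  if (any(c(r2_hb, r2_vdw) < 0 | c(r2_hb, r2_vdw) > 1, na.rm = TRUE))
    stop("r-squared values must lie in [0, 1]")
  (a * r2_hb + b * r2_vdw) / (a + b)
}

#' Bundle one conformer's site map for dynamic mapping
#'
#' @param conformer_id identifier (integer or string).
#' @param sitemap the conformer's [site_map()].
#' @param n_poses number of docked poses behind the map; conformers with
#'   fewer than `min_poses` (see [select_conformer()]) are excluded from
#'   dynamic mapping because their maps are unreliable.
#' @return Object of class `conformer_map_set`.
#' @export
conformer_map_set <- function(conformer_id, sitemap, n_poses) {
  structure(list(conformer_id = conformer_id, sitemap = sitemap,
                 n_poses = as.integer(n_poses)), class = "conformer_map_set")
}

#' Select the conformer most representative of the ensemble average
#'
#' Conformers with fewer than `min_poses` poses are excluded; the
#' ensemble-average map is computed over the remaining conformers; each
#' conformer's maps are correlated to the average per family and combined
#' into the similarity score; the conformer with the highest similarity is
#' selected. Ties are all reported and the lowest id selected with a
#' warning.
#'
#' @param sets list of [conformer_map_set()]s.
#' @param a,b similarity weights, normally the two cumulative-sum cutoffs.
#' @param min_poses minimum pose count for inclusion (default 10).
#' @param method correlation method passed to [map_r2()].
#' @return list with `selected` (conformer id), `table` (data.frame:
#'   `conformer`, `n_poses`, `included`, `r2_hb`, `r2_vdw`, `similarity`),
#'   `average` (the ensemble-average [site_map()]), and `tied` (ids tied
#'   at the maximum).
#' @export
select_conformer <- function(sets, a = 0.9, b = 0.4, min_poses = 10L,
                             method = c("pearson", "origin")) {
  method <- match.arg(method)
  n_poses <- vapply(sets, function(s) s$n_poses, integer(1))
  ids <- vapply(sets, function(s) as.character(s$conformer_id), character(1))
  included <- n_poses >= min_poses
  if (sum(included) < 2L)
    stop("fewer than two conformers satisfy min_poses = ", min_poses)
  maps <- lapply(sets[included], function(s) s$sitemap)
  avg <- ensemble_average(maps)
  r2h <- r2v <- sim <- rep(NA_real_, length(sets))
  for (i in which(included)) {
    r2h[i] <- map_r2(sets[[i]]$sitemap, avg, "HB", method)
    r2v[i] <- map_r2(sets[[i]]$sitemap, avg, "VDW", method)
    sim[i] <- similarity_score(r2h[i], r2v[i], a, b)
  }
  tab <- data.frame(conformer = ids, n_poses = n_poses, included = included,
                    r2_hb = r2h, r2_vdw = r2v, similarity = sim,
                    stringsAsFactors = FALSE)
  best <- max(sim[included], na.rm = TRUE)
  tied <- ids[included & !is.na(sim) & abs(sim - best) < 1e-12]
  if (length(tied) > 1L)
    warning("similarity tie between conformers: ",
            paste(tied, collapse = ", "), "; selecting the lowest id")
  selected <- sort(tied)[1]
  list(selected = selected, table = tab, average = avg, tied = tied)
}

#' Dynamic site mapping over a set of receptor conformers
#'
#' Runs the full pipeline: map each conformer's pose ensemble, exclude
#' conformers with too few poses, and select the conformer whose maps are
#' most similar to the ensemble average.
#'
#' @param ensembles list of [pose_ensemble()]s, one per receptor conformer.
#' @param ids conformer identifiers (default 1..n).
#' @param criteria an [interaction_criteria()].
#' @param top_n poses per conformer used for tallying.
#' @param hb_cutoff,vdw_cutoff cumulative-sum cutoffs; also the similarity
#'   weights `a` and `b`.
#' @param min_poses minimum ensemble size for inclusion.
#' @return As [select_conformer()], plus `maps` (per-conformer site maps).
#' @export
dynamic_site_map <- function(ensembles, ids = seq_along(ensembles),
                             criteria = interaction_criteria(),
                             top_n = 100L, hb_cutoff = 0.90,
                             vdw_cutoff = 0.40, min_poses = 10L) {
  if (length(ensembles) < 2L) stop("dynamic mapping needs >= 2 conformers")
  sets <- vector("list", length(ensembles))
  for (i in seq_along(ensembles)) {
    m <- map_ensemble(ensembles[[i]], criteria, top_n, hb_cutoff, vdw_cutoff)
    sets[[i]] <- conformer_map_set(ids[i], m, length(ensembles[[i]]$poses))
  }
  out <- select_conformer(sets, a = hb_cutoff, b = vdw_cutoff,
                          min_poses = min_poses)
  out$maps <- lapply(sets, function(s) s$sitemap)
  out
}
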