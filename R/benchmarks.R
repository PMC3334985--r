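# Published benchmark tables bundled with the package. These are the
# printed reference values of the original validation study and serve as
# inputs for the aggregation and regression checks; none of them is
# recomputed from docking runs here.

#' Bundled benchmark tables
#'
#' * `"chp3_conformers"`: per-conformer squared map correlations
#'   (hydrogen bonding and van der Waals) against the ensemble-average map
#'   for the ten retained HCDR3 loop conformers of the anti-ganglioside
#'   antibody chP3, together with the published similarity column.
#' * `"validation_map_quality"`: reproduction and correctness of the
#'   optimized site maps and of the top docked pose for the nine
#'   antichlamydial antibody / Kdo-antigen validation complexes.
#' * `"validation_docking"`: top-pose and best-pose RMSD (with best-pose
#'   rank) for four docking programs on the same nine validation
#'   complexes; `NA` marks dockings that produced no poses.
#'
#' @param name one of `"chp3_conformers"`, `"validation_map_quality"`,
#'   `"validation_docking"`.
#' @return data.frame.
#' @export
benchmark_table <- function(name = c("chp3_conformers",
                                     "validation_map_quality",
                                     "validation_docking")) {
  name <- match.arg(name)
  file <- switch(name,
                 chp3_conformers = "chp3_conformer_r2.csv",
                 validation_map_quality = "validation_map_quality.csv",
                 validation_docking = "validation_docking_rmsd.csv")
  path <- system.file("extdata", file, package = "sitemapr")
  if (path == "") stop("bundled table not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
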