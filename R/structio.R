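# Structure input/output: receptor and pose-ensemble reading, residue
# labeling, and serialization of site maps.

#' Construct a structure model
#'
#' A `structure_model` is the package's light-weight container for a set of
#' atoms with residue identity. Residue identity is the triplet
#' (chain, author sequence number, insertion code); the display `label` is
#' cosmetic metadata (for example an IMGT-style label such as `"111.2H"`)
#' and defaults to `<seq><insert><chain>`.
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `chain`, `resno`, `insert`, `resname`. Optional columns
#'   `is_hydrogen` and `label` are derived when absent.
#' @param source character tag recording where the model came from.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "") {
  req <- c("name", "element", "x", "y", "z", "chain", "resno", "insert", "resname")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (any(atoms$element == ""))
    stop("every atom needs a non-empty element symbol")
  if (is.null(atoms$is_hydrogen))
    atoms$is_hydrogen <- atoms$element == "H"
  if (is.null(atoms$label))
    atoms$label <- default_residue_label(atoms$chain, atoms$resno, atoms$insert)
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

default_residue_label <- function(chain, resno, insert) {
  paste0(resno, insert, chain)
}

residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = "|")
}

#' Residue table of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `label`, in order of first appearance.
#' @export
residues <- function(model) {
  a <- model$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx], insert = a$insert[idx],
             resname = a$resname[idx], label = a$label[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.structure_model <- function(x, ...) {
  r <- residues(x)
  cat(sprintf("structure_model: %d atoms, %d residues [%s]\n",
              nrow(x$atoms), nrow(r), x$source))
  invisible(x)
}

bio3d_to_atoms <- function(pdb_atom) {
  data.frame(
    name = trimws(pdb_atom$elety),
    element = toupper(trimws(ifelse(is.na(pdb_atom$elesy) | pdb_atom$elesy == "",
                                    substr(trimws(pdb_atom$elety), 1L, 1L),
                                    pdb_atom$elesy))),
    x = pdb_atom$x, y = pdb_atom$y, z = pdb_atom$z,
    chain = ifelse(is.na(pdb_atom$chain), "", pdb_atom$chain),
    resno = pdb_atom$resno,
    insert = ifelse(is.na(pdb_atom$insert), "", pdb_atom$insert),
    resname = trimws(pdb_atom$resid),
    stringsAsFactors = FALSE)
}

# Residue names treated as solvent/buffer/ions and always dropped on read.
SOLVENT_RESNAMES <- c("HOH", "WAT", "DOD", "SO4", "PO4", "GOL", "EDO", "PEG",
                      "ACT", "DMS", "MPD", "TRS", "NA", "CL", "K", "MG", "CA",
                      "ZN", "MN", "FE", "CU", "NI", "CO", "CD", "BR", "IOD")

#' Read a receptor structure from a PDB file
#'
#' Hydrogens are retained when present. HETATM records (ligands, waters,
#' buffer molecules, ions) are excluded from the receptor by default, so the
#' residue set is the protein only.
#'
#' @param path PDB file.
#' @param label_map optional path to a residue label mapping table (see
#'   [read_label_map()]), or a data.frame as returned by it.
#' @param keep_hetero keep HETATM records other than solvent/ions (used when
#'   reading a crystallographic complex that carries its ligand).
#' @return A [structure_model()].
#' @export
read_receptor <- function(path, label_map = NULL, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keep_hetero)
    keep <- keep | (at$type == "HETATM" & !(trimws(at$resid) %in% SOLVENT_RESNAMES))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms retained from '", path, "'")
  model <- structure_model(bio3d_to_atoms(at), source = path)
  if (!is.null(label_map)) {
    if (is.character(label_map)) label_map <- read_label_map(label_map)
    model <- apply_label_map(model, label_map)
  }
  model
}

#' Read a residue label mapping table
#'
#' Whitespace- or tab-delimited, no header. Either three fields per row
#' (`chain  resno[insert]  label`) or two (`chain:resno[insert]  label`).
#' Example row: `H 100A 111.2H` maps residue 100, insertion code A, chain H
#' to the display label `111.2H`.
#'
#' @param path mapping file.
#' @return data.frame with columns `chain`, `resno`, `insert`, `label`.
#' @export
read_label_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty label map: ", path)
  parse_row <- function(ln) {
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) == 2L && grepl(":", f[1])) {
      ck <- strsplit(f[1], ":", fixed = TRUE)[[1]]
      f <- c(ck[1], ck[2], f[2])
    }
    if (length(f) != 3L) stop("malformed label-map row: '", ln, "'")
    m <- regmatches(f[2], regexec("^(-?[0-9]+)([A-Za-z]?)$", f[2]))[[1]]
    if (length(m) == 0L) stop("malformed residue id in label map: '", f[2], "'")
    data.frame(chain = f[1], resno = as.integer(m[2]), insert = m[3],
               label = f[3], stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(lines, parse_row))
}

#' Apply a residue label map to a structure model
#'
#' Mapped residues get the supplied display label; unmapped residues keep
#' their default `<seq><insert><chain>` label. Map rows that match no
#' residue raise a warning, not an error.
#'
#' @param model a `structure_model`.
#' @param map data.frame from [read_label_map()].
#' @return The relabeled model.
#' @export
apply_label_map <- function(model, map) {
  akey <- residue_key(model$atoms$chain, model$atoms$resno, model$atoms$insert)
  mkey <- residue_key(map$chain, map$resno, map$insert)
  if (anyDuplicated(mkey)) stop("duplicate residues in label map")
  hit <- match(akey, mkey)
  model$atoms$label[!is.na(hit)] <- map$label[hit[!is.na(hit)]]
  unused <- setdiff(mkey, akey)
  if (length(unused) > 0L)
    warning("label map rows match no residue: ", paste(unused, collapse = ", "))
  model
}

#' Construct a pose ensemble
#'
#' @param receptor `structure_model` of the receptor, or `NULL`.
#' @param poses list of ligand `structure_model`s; element 1 is the
#'   top-ranked pose.
#' @param scores optional numeric per-pose score.
#' @param source character tag.
#' @return Object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor, poses, scores = NULL, source = "") {
  if (length(poses) == 0L) stop("pose ensemble is empty")
  if (!is.null(scores) && length(scores) != length(poses))
    stop("scores length must match pose count")
  structure(list(receptor = receptor, poses = poses, scores = scores,
                 source = source), class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("pose_ensemble: %d poses%s [%s]\n", length(x$poses),
              if (is.null(x$scores)) "" else ", scored", x$source))
  invisible(x)
}

#' @export
length.pose_ensemble <- function(x) length(x$poses)

#' Read a ranked ligand pose ensemble
#'
#' Accepts a multi-model PDB (`MODEL`/`ENDMDL`, one ligand per model) or an
#' SD file (one ligand per record). Record order in the file is taken as the
#' docking rank order (rank 1 first) unless `rank_by_score = TRUE` and
#' scores are present, in which case poses are re-sorted ascending by score.
#' For SD files a per-record numeric data field named by `score_tag`
#' (case-insensitive) is captured as the pose score.
#'
#' @param path pose file (`.pdb` or `.sdf`/`.sd`/`.mol`).
#' @param receptor optional receptor `structure_model` attached to the
#'   ensemble.
#' @param format `"auto"`, `"pdb"` or `"sdf"`.
#' @param score_tag SD data field holding the docking score.
#' @param rank_by_score re-rank poses by ascending score.
#' @return A [pose_ensemble()].
#' @export
read_pose_ensemble <- function(path, receptor = NULL,
                               format = c("auto", "pdb", "sdf"),
                               score_tag = "score", rank_by_score = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "sd", "mol")) "sdf" else "pdb"
  }
  ens <- if (format == "pdb") read_poses_pdb(path) else
    read_poses_sdf(path, score_tag)
  if (length(ens$poses) == 0L) stop("no ligand records found in '", path, "'")
  if (rank_by_score && !is.null(ens$scores)) {
    ord <- order(ens$scores)
    ens$poses <- ens$poses[ord]
    ens$scores <- ens$scores[ord]
  }
  pose_ensemble(receptor, ens$poses, ens$scores, source = path)
}

read_poses_pdb <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
                  error = function(e) stop("cannot parse pose PDB '", path,
                                           "': ", conditionMessage(e)))
  atoms <- bio3d_to_atoms(pdb$atom)
  if (nrow(atoms) == 0L) stop("no ligand atoms in pose file '", path, "'")
  nmod <- nrow(pdb$xyz)
  poses <- lapply(seq_len(nmod), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    a <- atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    structure_model(a, source = sprintf("%s#%d", path, i))
  })
  # optional per-model score from "REMARK ... score <value>" lines
  lines <- readLines(path, warn = FALSE)
  sc <- regmatches(lines, regexec("^REMARK.*[Ss]core[ =:]+(-?[0-9.]+)", lines))
  sc <- vapply(sc, function(m) if (length(m) == 2L) as.numeric(m[2]) else NA_real_,
               numeric(1))
  sc <- sc[!is.na(sc)]
  scores <- if (length(sc) == nmod) sc else NULL
  list(poses = poses, scores = scores)
}

read_poses_sdf <- function(path, score_tag) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("cannot parse SD file '", path,
                                           "': ", conditionMessage(e)))
  n <- length(sdf)
  if (n == 0L) stop("no records in SD file '", path, "'")
  poses <- vector("list", n)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rec <- sdf[[i]]
    ab <- ChemmineR::atomblock(rec)
    elem <- sub("_[0-9]+$", "", rownames(ab))
    poses[[i]] <- structure_model(data.frame(
      name = rownames(ab), element = elem,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      chain = "L", resno = 1L, insert = "", resname = "LIG",
      stringsAsFactors = FALSE), source = sprintf("%s#%d", path, i))
    db <- ChemmineR::datablock(rec)
    hit <- which(tolower(names(db)) == tolower(score_tag))
    if (length(hit) == 1L) scores[i] <- suppressWarnings(as.numeric(db[[hit]]))
  }
  list(poses = poses, scores = if (all(is.na(scores))) NULL else scores)
}

#' Write a pose ensemble as a multi-model PDB
#'
#' All poses must share one atom topology (the usual case for rigid-probe
#' fixtures and single-ligand docking output).
#'
#' @param ensemble a [pose_ensemble()].
#' @param path output file.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  n_at <- vapply(ensemble$poses, function(p) nrow(p$atoms), integer(1))
  if (length(unique(n_at)) != 1L)
    stop("poses differ in atom count; cannot write one multi-model PDB")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ensemble$poses)) {
    a <- ensemble$poses[[i]]$atoms
    writeLines(sprintf("MODEL     %4d", i), con)
    if (!is.null(ensemble$scores))
      writeLines(sprintf("REMARK   3 score %.4f", ensemble$scores[i]), con)
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), substr(a$name, 1, 4), substr(a$resname, 1, 3),
      substr(a$chain, 1, 2), a$resno, a$x, a$y, a$z, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure model as a single-model PDB
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param record `"ATOM"` or `"HETATM"`.
#' @export
write_structure <- function(model, path, record = "ATOM") {
  a <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    record, seq_len(nrow(a)), substr(a$name, 1, 4), substr(a$resname, 1, 3),
    substr(a$chain, 1, 2), a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a site map to CSV or JSON
#'
#' One row per residue in the union of the hydrogen-bond and van der Waals
#' supports: chain, label, percentage contribution to each interaction type
#' (2 decimals in CSV), and flags marking membership of the important sets.
#' JSON keeps full precision so that a round trip reproduces contributions
#' exactly.
#'
#' @param map a `site_map` (see [normalize_tally()], [select_important()]).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_sitemap <- function(map, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- sitemap_as_table(map)
  if (format == "csv") {
    out <- df
    out$pct_hb <- sprintf("%.2f", out$pct_hb)
    out$pct_vdw <- sprintf("%.2f", out$pct_vdw)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      hb_contrib = as.list(map$hb), vdw_contrib = as.list(map$vdw),
      hb_cutoff = map$hb_cutoff, vdw_cutoff = map$vdw_cutoff,
      important_hb = as.list(map$important_hb),
      important_vdw = as.list(map$important_vdw),
      n_poses = map$n_poses,
      residues = map$residues)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sitemap_as_table <- function(map) {
  labs <- sort(union(names(map$hb), names(map$vdw)))
  chain <- rep("", length(labs))
  if (!is.null(map$residues) && nrow(map$residues) > 0L) {
    hit <- match(labs, map$residues$label)
    chain[!is.na(hit)] <- map$residues$chain[hit[!is.na(hit)]]
  }
  data.frame(
    chain = chain, label = labs,
    pct_hb = 100 * ifelse(is.na(map$hb[labs]), 0, map$hb[labs]),
    pct_vdw = 100 * ifelse(is.na(map$vdw[labs]), 0, map$vdw[labs]),
    important_hb = labs %in% map$important_hb,
    important_vdw = labs %in% map$important_vdw,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a site map written by [write_sitemap()]
#'
#' @param path CSV or JSON file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A `site_map`.
#' @export
read_sitemap <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "json") {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    res <- if (!is.null(p$residues) && length(p$residues))
      as.data.frame(p$residues, stringsAsFactors = FALSE) else NULL
    return(site_map(hb = unlist(p$hb_contrib), vdw = unlist(p$vdw_contrib),
                    hb_cutoff = p$hb_cutoff, vdw_cutoff = p$vdw_cutoff,
                    important_hb = unlist(p$important_hb),
                    important_vdw = unlist(p$important_vdw),
                    n_poses = p$n_poses, residues = res))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chain = "character", label = "character"))
  hb <- stats::setNames(df$pct_hb / 100, df$label)
  vdw <- stats::setNames(df$pct_vdw / 100, df$label)
  site_map(hb = hb[hb > 0], vdw = vdw[vdw > 0],
           important_hb = df$label[df$important_hb],
           important_vdw = df$label[df$important_vdw],
           residues = df[, c("chain", "label")])
}

#' Export a PyMOL coloring script for a site map
#'
#' Writes each residue's percentage contribution into the b-factor and
#' applies a monochrome gradient, one object per interaction type, so that
#' color depth reflects the residue's involvement in ligand recognition.
#' Map residues absent from the receptor are listed in a warning block at
#' the top of the script; the script remains valid.
#'
#' @param map a `site_map`.
#' @param receptor receptor `structure_model` or path to its PDB file.
#' @param path output `.pml` script.
#' @param receptor_file PDB filename the script should load (defaults to
#'   the path given in `receptor`, or the model's `source`).
#' @export
export_pymol_coloring <- function(map, receptor, path, receptor_file = NULL) {
  if (is.character(receptor)) {
    if (is.null(receptor_file)) receptor_file <- receptor
    receptor <- read_receptor(receptor)
  } else if (is.null(receptor_file)) {
    receptor_file <- receptor$source
  }
  res <- residues(receptor)
  tab <- sitemap_as_table(map)
  hit <- match(tab$label, res$label)
  missing <- tab$label[is.na(hit)]
  lines <- c("# sitemapr per-residue interaction coloring")
  if (length(missing) > 0L)
    lines <- c(lines, paste0("# WARNING: residue not found in receptor: ", missing))
  lines <- c(lines, sprintf("load %s, sitemap_hb", receptor_file),
             "create sitemap_vdw, sitemap_hb",
             "alter sitemap_hb, b=0.0", "alter sitemap_vdw, b=0.0")
  ok <- which(!is.na(hit))
  for (i in ok) {
    sel <- sprintf("chain %s and resi %s%s", res$chain[hit[i]],
                   res$resno[hit[i]], res$insert[hit[i]])
    lines <- c(lines,
               sprintf("alter (sitemap_hb and %s), b=%.2f", sel, tab$pct_hb[i]),
               sprintf("alter (sitemap_vdw and %s), b=%.2f", sel, tab$pct_vdw[i]))
  }
  max_hb <- max(c(tab$pct_hb, 0))
  max_vdw <- max(c(tab$pct_vdw, 0))
  lines <- c(lines,
             sprintf("spectrum b, white_red, sitemap_hb, minimum=0, maximum=%.2f",
                     max(max_hb, 1e-6)),
             sprintf("spectrum b, white_blue, sitemap_vdw, minimum=0, maximum=%.2f",
                     max(max_vdw, 1e-6)),
             "scene hb_map, store", "disable sitemap_hb", "enable sitemap_vdw",
             "scene vdw_map, store")
  writeLines(lines, path)
  invisible(path)
}
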