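# Small in-code fixtures shared across the suite.

mk_model <- function(name, element, x, y, z, chain = "A", resno = 1L,
                     insert = "", resname = "GLY", source = "fixture") {
  structure_model(data.frame(
    name = name, element = element, x = x, y = y, z = z,
    chain = chain, resno = resno, insert = insert, resname = resname,
    stringsAsFactors = FALSE), source = source)
}

# single polar probe atom at a position
mk_probe <- function(x, y = 0, z = 0, name = "O1", element = "O") {
  mk_model(name, element, x, y, z, chain = "L", resname = "LIG")
}

# receptor residue with donor N and its hydrogen
mk_donor_residue <- function(n_pos = c(0, 0, 0), h_pos = c(1, 0, 0),
                             resno = 1L, chain = "A") {
  mk_model(c("N", "HN"), c("N", "H"),
           x = c(n_pos[1], h_pos[1]), y = c(n_pos[2], h_pos[2]),
           z = c(n_pos[3], h_pos[3]), chain = chain, resno = resno)
}

# a site map directly from named contribution vectors
mk_map <- function(hb = numeric(), vdw = numeric()) {
  site_map(hb = hb, vdw = vdw)
}

# write a minimal 2-residue receptor PDB and return its path
write_mini_receptor <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   ALA H 100A      5.000   0.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  ALA H 100A      6.450   0.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 201       8.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  path
}

write_mini_poses_pdb <- function(path = tempfile(fileext = ".pdb"),
                                 n_models = 3L) {
  con <- file(path, "w")
  for (i in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK   3 score %.2f", -8 + i), con)
    writeLines(sprintf(
      "HETATM    1  O1  LIG L   1    %8.3f   0.000   0.000  1.00  0.00           O",
      2.0 + i), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}

write_mini_poses_sdf <- function(path = tempfile(fileext = ".sdf"),
                                 scores = c(-7.25, -6.90)) {
  block <- function(x_off, score) c(
    "pose", "  synth", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0", 2.9 + x_off),
    sprintf("%10.4f    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0", 3.6 + x_off),
    "  1  2  1  0", "M  END",
    "> <score>", sprintf("%.2f", score), "", "$$$$")
  writeLines(unlist(lapply(seq_along(scores),
                           function(i) block((i - 1) * 0.1, scores[i]))), path)
  path
}

# independent brute-force contact oracle: naive double loops and explicit
# trigonometry, no shared code with the package detectors
oracle_contacts <- function(pose, receptor, crit = interaction_criteria()) {
  lp <- pose$atoms
  rp <- receptor$atoms
  dist3 <- function(p, q) sqrt(sum((p - q)^2))
  pos <- function(df, i) c(df$x[i], df$y[i], df$z[i])
  attached_h <- function(df, i) {
    out <- integer()
    for (k in which(df$is_hydrogen)) {
      ds <- vapply(which(!df$is_hydrogen), function(j) dist3(pos(df, k), pos(df, j)),
                   numeric(1))
      nearest <- which(!df$is_hydrogen)[which.min(ds)]
      if (nearest == i && min(ds) <= 1.3) out <- c(out, k)
    }
    out
  }
  polar <- function(df) which(df$element %in% c("N", "O") & !df$is_hydrogen)
  sys_has_h <- any(lp$is_hydrogen) || any(rp$is_hydrogen)
  hb <- list(); vdw <- list()
  donor_ok <- function(ddf, di, adf, ai) {
    d <- dist3(pos(ddf, di), pos(adf, ai))
    if (!sys_has_h) return(d <= crit$hb_heavy_only_da_max)
    hs <- attached_h(ddf, di)
    if (length(hs) == 0) return(FALSE)
    for (h in hs) {
      v1 <- pos(ddf, di) - pos(ddf, h)
      v2 <- pos(adf, ai) - pos(ddf, h)
      ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= crit$hb_angle_min) return(TRUE)
    }
    FALSE
  }
  for (ri in polar(rp)) for (li in polar(lp)) {
    if (dist3(pos(rp, ri), pos(lp, li)) > crit$hb_da_max) next
    if (donor_ok(rp, ri, lp, li) || donor_ok(lp, li, rp, ri))
      hb[[length(hb) + 1]] <- c(ri, li)
  }
  for (ri in which(!rp$is_hydrogen)) for (li in which(!lp$is_hydrogen)) {
    if (dist3(pos(rp, ri), pos(lp, li)) > crit$vdw_max) next
    is_hb <- any(vapply(hb, function(p) p[1] == ri && p[2] == li, logical(1)))
    if (crit$exclude_hbonded_pairs_from_vdw && is_hb) next
    vdw[[length(vdw) + 1]] <- c(ri, li)
  }
  mk <- function(lst, kind) {
    if (length(lst) == 0) return(NULL)
    do.call(rbind, lapply(lst, function(p) data.frame(
      label = rp$label[p[1]], kind = kind, ligand_atom = lp$name[p[2]],
      protein_atom = rp$name[p[1]], stringsAsFactors = FALSE)))
  }
  out <- rbind(mk(hb, "HB"), mk(vdw, "VDW"))
  if (is.null(out)) return(data.frame(label = character(), kind = character(),
                                      ligand_atom = character(),
                                      protein_atom = character()))
  out[order(out$kind, out$label, out$protein_atom, out$ligand_atom), ,
      drop = FALSE]
}
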