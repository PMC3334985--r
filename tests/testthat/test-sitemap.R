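test_that("ensemble tallying aggregates atom-pair counts over the top-ranked poses", {
  # pocket where pose targets are programmed exactly (quota assignment)
  spec <- fixture_spec(3, hb_profile = c(1, 0, 0), vdw_profile = c(0, 1, 0),
                       n_poses = 2, seed = 1)
  ens <- make_pose_ensemble(spec, assignment = "quota")
  tally <- tally_ensemble(ens, top_n = 2)
  expect_s3_class(tally, "interaction_tally")
  expect_equal(sum(tally$hb), 2L)
  expect_equal(names(tally$hb), "1A")
  expect_equal(sum(tally$vdw), 2L)
  expect_equal(tally$n_poses_used, 2L)

  # top_n = 1 uses only the first pose
  expect_equal(sum(tally_ensemble(ens, top_n = 1)$hb), 1L)

  # 150-pose ensemble, default top_n: exactly 100 poses used
  spec150 <- fixture_spec(3, n_poses = 150, seed = 2)
  ens150 <- make_pose_ensemble(spec150)
  expect_equal(tally_ensemble(ens150)$n_poses_used, 100L)

  expect_error(tally_ensemble(pose_ensemble(NULL, list(mk_probe(1))), top_n = 0))
})

test_that("precomputed interaction tables tally like detected records", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("pose_rank,chain,residue_label,kind",
               "1,A,1A,HB", "1,A,1A,HB", "2,A,2A,VDW", "2,A,1A,HB"), csv)
  t <- tally_from_table(csv)
  expect_equal(sum(t$hb), 3L)
  expect_equal(sum(t$vdw), 1L)
  expect_equal(unname(t$hb["1A"]), 3L)

  # duplicated rows are genuine multiplicities
  csv_dup <- tempfile(fileext = ".csv")
  writeLines(c("pose_rank,chain,residue_label,kind", "1,A,1A,HB", "1,A,1A,HB"),
             csv_dup)
  expect_equal(sum(tally_from_table(csv_dup)$hb), 2L)

  csv_bad <- tempfile(fileext = ".csv")
  writeLines(c("pose_rank,chain,residue_label,kind", "1,A,1A,XX"), csv_bad)
  expect_error(tally_from_table(csv_bad), "unknown interaction kind")

  csv_empty <- tempfile(fileext = ".csv")
  writeLines("pose_rank,chain,residue_label,kind", csv_empty)
  expect_error(tally_from_table(csv_empty), "empty")
})

test_that("exporting detected records to a table and re-tallying reproduces the tally", {
  spec <- fixture_spec(4, hb_profile = c(.4, .3, .2, .1),
                       vdw_profile = c(.1, .2, .3, .4), n_poses = 12, seed = 6)
  ens <- make_pose_ensemble(spec)
  direct <- tally_ensemble(ens, top_n = 12)
  recs <- do.call(rbind, lapply(seq_along(ens$poses), function(i)
    detect_contacts(ens$poses[[i]], ens$receptor, pose_rank = i)))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(pose_rank = recs$pose_rank, chain = recs$chain,
                              residue_label = recs$label, kind = recs$kind),
                   csv, row.names = FALSE)
  via_table <- tally_from_table(csv)
  expect_equal(via_table$hb[sort(names(via_table$hb))],
               direct$hb[sort(names(direct$hb))])
  expect_equal(via_table$vdw[sort(names(via_table$vdw))],
               direct$vdw[sort(names(direct$vdw))])
})

test_that("normalization divides by the family total and flags empty families", {
  t <- interaction_tally(hb = c(A = 3L, B = 1L), vdw = c(A = 2L))
  m <- normalize_tally(t)
  expect_equal(m$hb, c(A = 0.75, B = 0.25))
  expect_equal(m$vdw, c(A = 1.0))
  expect_equal(sum(m$hb), 1)

  t1 <- interaction_tally(hb = c(A = 5L), vdw = integer())
  expect_warning(m1 <- normalize_tally(t1), "van der Waals")
  expect_equal(m1$hb, c(A = 1.0))
  expect_length(m1$vdw, 0L)
})

test_that("cumulative-sum selection includes the crossing residue and whole tie groups", {
  m <- mk_map(hb = c(A = 0.5, B = 0.3, C = 0.15, D = 0.05))
  expect_equal(select_important(m, 0.8, 0)$important_hb, c("A", "B"))
  expect_equal(select_important(m, 0.9, 0)$important_hb, c("A", "B", "C"))
  expect_equal(select_important(m, 0, 0)$important_hb, character())
  expect_setequal(select_important(m, 1, 0)$important_hb, c("A", "B", "C", "D"))

  # a tie straddling the crossing point is included as a whole
  m_tie <- mk_map(hb = c(A = 0.4, B = 0.3, C = 0.3))
  expect_setequal(select_important(m_tie, 0.7, 0)$important_hb,
                  c("A", "B", "C"))
})

test_that("selection is monotone in the cutoff and invariant to count scaling", {
  set.seed(42)
  for (rep in 1:5) {
    counts <- stats::setNames(sample.int(20, 6, replace = TRUE), LETTERS[1:6])
    m <- normalize_tally(interaction_tally(hb = counts, vdw = counts * 3L))
    # scale invariance: multiplying all counts leaves the map unchanged
    m_scaled <- normalize_tally(interaction_tally(hb = counts * 7L,
                                                  vdw = counts * 21L))
    expect_equal(m$hb, m_scaled$hb)
    expect_equal(m$vdw, m_scaled$vdw)
    # nested important sets along increasing cutoffs
    cuts <- seq(0, 1, by = 0.1)
    sets <- lapply(cuts, function(cc) select_important(m, cc, cc)$important_hb)
    for (i in seq_along(cuts)[-1])
      expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})
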