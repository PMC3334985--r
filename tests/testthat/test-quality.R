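test_that("reproduction and correctness follow set arithmetic against the reference", {
  r <- score_map(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(c(r$reproduction, r$correctness, r$product), c(1, 1, 1))

  r2 <- score_map(c("A", "B", "E"), c("A", "B", "C", "D"))
  expect_equal(r2$reproduction, 0.5)
  expect_equal(r2$correctness, 2 / 3)
  expect_equal(r2$product, r2$reproduction * r2$correctness, tolerance = 1e-12)

  # 10 predicted residues containing all 8 reference residues
  r3 <- score_map(paste0("R", 1:10), paste0("R", 1:8))
  expect_equal(r3$reproduction, 1.0)
  expect_equal(r3$correctness, 0.8)

  expect_equal(score_map(character(), "A")$correctness, 0)
  expect_error(score_map("A", character()), "empty")
})

test_that("adding a non-reference residue degrades correctness but not reproduction", {
  ref <- c("A", "B", "C")
  base <- score_map(c("A", "B"), ref)
  worse <- score_map(c("A", "B", "Z"), ref)
  expect_equal(worse$reproduction, base$reproduction)
  expect_lt(worse$correctness, base$correctness)
})

test_that("cutoff scan recovers the exhaustive-grid optimum", {
  # cases built so hydrogen bonding needs a deep cutoff and vdW a shallow one
  mk_case <- function(hb, vdw, ref) list(map = mk_map(hb = hb, vdw = vdw),
                                         reference = ref)
  cases <- list(
    mk_case(hb = c(A = 0.4, B = 0.3, C = 0.2, D = 0.1),
            vdw = c(E = 0.7, F = 0.2, G = 0.1),
            ref = c("A", "B", "C", "E")),
    mk_case(hb = c(P = 0.5, Q = 0.3, R = 0.2),
            vdw = c(S = 0.6, T = 0.3, U = 0.1),
            ref = c("P", "Q", "R", "S")))
  scan <- scan_cutoffs(cases)
  # independent exhaustive oracle over the same 11x11 grid
  oracle_best <- NULL
  for (hc in seq(0, 1, 0.1)) for (vc in seq(0, 1, 0.1)) {
    prods <- vapply(cases, function(cs) {
      sel_fam <- function(contrib, cutoff) {
        if (cutoff <= 0) return(character())
        v <- sort(contrib, decreasing = TRUE)
        k <- which(cumsum(v) >= cutoff - 1e-12)[1]
        names(v)[v >= v[k]]
      }
      pred <- union(sel_fam(cs$map$hb, hc), sel_fam(cs$map$vdw, vc))
      hits <- length(intersect(pred, cs$reference))
      (hits / length(cs$reference)) *
        (if (length(pred) == 0) 0 else hits / length(pred))
    }, numeric(1))
    m <- mean(prods)
    if (is.null(oracle_best) || m > oracle_best$m + 1e-12)
      oracle_best <- list(hc = hc, vc = vc, m = m)
  }
  expect_equal(scan$best$hb_cutoff, oracle_best$hc)
  expect_equal(scan$best$vdw_cutoff, oracle_best$vc)
  expect_equal(scan$best$mean_product, oracle_best$m, tolerance = 1e-12)

  # degenerate case: top residue alone is the full reference ->
  # every positive cutoff is perfect, ties resolve to the smallest point
  one <- list(mk_case(hb = c(A = 1.0), vdw = numeric(), ref = "A"))
  s1 <- scan_cutoffs(one)
  expect_equal(s1$best$hb_cutoff, 0.1)
  expect_equal(s1$best$mean_product, 1)

  expect_error(scan_cutoffs(cases, hb_grid = numeric()), "empty")
})

test_that("pose RMSD is in-place, name-matched, and order-invariant", {
  ref <- mk_model(c("C1", "C2", "O1"), c("C", "C", "O"),
                  x = c(0, 1, 2), y = 0, z = 0, resname = "LIG")
  expect_equal(pose_rmsd(ref, ref), 0)

  shifted <- ref
  shifted$atoms$x <- shifted$atoms$x + 3
  shifted$atoms$y <- shifted$atoms$y + 4
  expect_equal(pose_rmsd(shifted, ref), 5)

  # atom order must not matter
  perm <- ref
  perm$atoms <- perm$atoms[c(3, 1, 2), ]
  expect_equal(pose_rmsd(perm, shifted), 5)

  # independent cross-check against bio3d's rmsd with superposition off
  set.seed(3)
  noisy <- ref
  noisy$atoms$x <- noisy$atoms$x + rnorm(3, sd = 0.5)
  noisy$atoms$z <- noisy$atoms$z + rnorm(3, sd = 0.5)
  want <- bio3d::rmsd(as.numeric(t(cbind(ref$atoms$x, ref$atoms$y, ref$atoms$z))),
                      as.numeric(t(cbind(noisy$atoms$x, noisy$atoms$y, noisy$atoms$z))),
                      fit = FALSE)
  expect_equal(pose_rmsd(noisy, ref), want, tolerance = 1e-3)

  other <- mk_model("ZZ", "C", 0, 0, 0)
  expect_error(pose_rmsd(other, ref), "correspondence")
})

test_that("docking summaries aggregate mean, SD and the 2 A success count", {
  df <- data.frame(top_rmsd = c(1.5, 2.5, 3.5), best_rmsd = c(1.0, 1.0, 4.0))
  s <- summarize_docking(df)
  expect_equal(s$top$mean, 2.5)
  expect_equal(s$top$sd, sd(df$top_rmsd))
  expect_equal(s$best$n_success, 2L)
  expect_false(s$top$sd_undefined)

  s1 <- summarize_docking(data.frame(top_rmsd = 1.2, best_rmsd = 1.2))
  expect_equal(s1$top$sd, 0)
  expect_true(s1$top$sd_undefined)

  s_eq <- summarize_docking(data.frame(top_rmsd = c(2, 2, 2),
                                       best_rmsd = c(2, 2, 2)))
  expect_equal(s_eq$best$sd, 0)
  expect_equal(s_eq$best$n_success, 0L)  # success is strictly below threshold

  s_pop <- summarize_docking(df, sd_type = "population")
  expect_equal(s_pop$top$sd, sqrt(2 / 3))
})
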