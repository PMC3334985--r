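# Synthetic fixtures: toy binding sites and pose ensembles with
# programmed per-residue contact frequencies, so every downstream stage
# is testable with known ground truth and no external structures.

#' Specification of a synthetic fixture
#'
#' Describes a toy binding site and the target per-residue contact
#' frequencies a generated pose ensemble should realize. All randomness is
#' fixed by `seed`.
#'
#' @param n_residues number of pocket residues (>= 2).
#' @param hb_profile,vdw_profile target contact-frequency profiles; numeric
#'   vectors of length `n_residues` (optionally named by residue label)
#'   summing to 1. Default: uniform.
#' @param n_poses number of poses to generate.
#' @param seed integer fixing the pseudo-random stream.
#' @param jitter standard deviation (Angstrom) of Gaussian noise added to
#'   probe coordinates; 0 keeps the contact geometry exact.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues, hb_profile = NULL, vdw_profile = NULL,
                         n_poses = 100L, seed = 1L, jitter = 0) {
  if (n_residues < 2L) stop("a pocket needs at least two residues")
  if (n_poses < 1L) stop("n_poses must be >= 1")
  if (jitter < 0) stop("jitter must be non-negative")
  norm_profile <- function(p, what) {
    if (is.null(p)) p <- rep(1 / n_residues, n_residues)
    if (length(p) != n_residues)
      stop(what, " must have length n_residues")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(what, " must be non-negative and sum to 1")
    p
  }
  structure(list(n_residues = as.integer(n_residues),
                 hb_profile = norm_profile(hb_profile, "hb_profile"),
                 vdw_profile = norm_profile(vdw_profile, "vdw_profile"),
                 n_poses = as.integer(n_poses), seed = as.integer(seed),
                 jitter = jitter), class = "fixture_spec")
}

# ring geometry shared by site and probe placement
ring_geometry <- function(n) {
  radius <- max(8, 4.5 / sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  list(radius = radius, ux = cos(theta), uy = sin(theta))
}

#' Build a toy binding site
#'
#' Pocket residues are arranged on a ring, each carrying one polar
#' donor/acceptor nitrogen with an explicit hydrogen pointing radially
#' outward, and one apolar carbon displaced below the ring plane. The
#' spacing guarantees that a probe placed against one residue contacts no
#' other, so realized contact frequencies equal the placement frequencies.
#'
#' @param spec a [fixture_spec()].
#' @return A [structure_model()] with `n_residues` residues on chain A.
#' @export
make_binding_site <- function(spec) {
  n <- spec$n_residues
  g <- ring_geometry(n)
  r <- g$radius
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      name = c("N", "HN", "CB"),
      element = c("N", "H", "C"),
      x = c(r * g$ux[i], (r + 1.0) * g$ux[i], r * g$ux[i]),
      y = c(r * g$uy[i], (r + 1.0) * g$uy[i], r * g$uy[i]),
      z = c(0, 0, -5),
      chain = "A", resno = i, insert = "", resname = "SIT",
      stringsAsFactors = FALSE)
  }))
  structure_model(atoms, source = sprintf("synthetic pocket (n=%d)", n))
}

# largest-remainder apportionment of n draws to probabilities p
quota_counts <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(-(raw - counts), seq_along(p))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate a pose ensemble realizing target contact profiles
#'
#' Each pose is a rigid two-atom probe: a polar oxygen placed 2.9 Angstrom
#' outside the donor nitrogen of one residue (a guaranteed hydrogen bond
#' at 180 degrees) and an apolar carbon placed 3.6 Angstrom outside the
#' apolar carbon of another (a guaranteed van der Waals contact). Target
#' residues are drawn per pose from the profiles, so the expected recovered
#' site map equals the programmed profiles. `assignment = "quota"` uses
#' largest-remainder apportionment instead of sampling, making realized
#' frequencies match the profiles to rounding.
#'
#' @param spec a [fixture_spec()].
#' @param site optional pre-built pocket from [make_binding_site()].
#' @param assignment `"multinomial"` (default) or `"quota"`.
#' @return A [pose_ensemble()] with the pocket attached as receptor.
#' @export
make_pose_ensemble <- function(spec, site = NULL,
                               assignment = c("multinomial", "quota")) {
  assignment <- match.arg(assignment)
  if (is.null(site)) site <- make_binding_site(spec)
  n <- spec$n_residues
  g <- ring_geometry(n)
  r <- g$radius
  withr::with_seed(spec$seed, {
    if (assignment == "multinomial") {
      hb_target <- sample.int(n, spec$n_poses, replace = TRUE,
                              prob = spec$hb_profile)
      vdw_target <- sample.int(n, spec$n_poses, replace = TRUE,
                               prob = spec$vdw_profile)
    } else {
      hb_target <- rep(seq_len(n), quota_counts(spec$hb_profile, spec$n_poses))
      vdw_target <- rep(seq_len(n), quota_counts(spec$vdw_profile, spec$n_poses))
    }
    noise <- if (spec$jitter > 0)
      matrix(stats::rnorm(6L * spec$n_poses, sd = spec$jitter), ncol = 6L)
    else matrix(0, nrow = spec$n_poses, ncol = 6L)
    poses <- lapply(seq_len(spec$n_poses), function(p) {
      i <- hb_target[p]; j <- vdw_target[p]
      structure_model(data.frame(
        name = c("O1", "C1"), element = c("O", "C"),
        x = c((r + 2.9) * g$ux[i] + noise[p, 1],
              (r + 3.6) * g$ux[j] + noise[p, 4]),
        y = c((r + 2.9) * g$uy[i] + noise[p, 2],
              (r + 3.6) * g$uy[j] + noise[p, 5]),
        z = c(0 + noise[p, 3], -5 + noise[p, 6]),
        chain = "L", resno = 1L, insert = "", resname = "PRB",
        stringsAsFactors = FALSE), source = sprintf("probe pose %d", p))
    })
  })
  pose_ensemble(site, poses, scores = -seq_len(spec$n_poses) / 10,
                source = sprintf("synthetic ensemble (seed=%d)", spec$seed))
}

#' Generate a conformer series with a planted centroid
#'
#' Builds pose ensembles for a series of pseudo-conformers whose contact
#' profiles scatter around a common base profile. The planted conformer
#' keeps the base profile exactly while the others receive double-centered
#' perturbations (zero-sum across residues and across conformers), so the
#' ensemble-average profile equals the base and the planted conformer is
#' the unique maximizer of the similarity score whenever `divergence > 0`.
#' Poses are assigned by quota so realized maps match the profiles to
#' rounding.
#'
#' @param spec a [fixture_spec()] providing the base profiles, pose count
#'   and seed.
#' @param n_conformers number of conformers (>= 2).
#' @param divergence perturbation magnitude in `[0, 1]`, as a fraction of
#'   the smallest base-profile entry; 0 makes all conformers identical.
#' @param planted index of the centroid conformer (default 1).
#' @return list of [pose_ensemble()]s with attributes `planted` (the
#'   planted index) and `profiles` (list of per-conformer hb/vdw profiles).
#' @export
make_conformer_series <- function(spec, n_conformers, divergence,
                                  planted = 1L) {
  if (n_conformers < 2L) stop("need at least two conformers")
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  if (planted < 1L || planted > n_conformers) stop("planted index out of range")
  n <- spec$n_residues
  perturb <- function(base, seed_off) {
    m <- n_conformers - 1L
    w <- withr::with_seed(spec$seed + seed_off,
                          matrix(stats::runif(m * n), nrow = m))
    # two-way centering: every row and every column of w sums to zero, so
    # profiles stay normalized and the conformer mean stays exactly at base
    w <- w - outer(rowMeans(w), rep(1, n)) -
      outer(rep(1, m), colMeans(w)) + mean(w)
    v <- matrix(0, n_conformers, n)
    v[setdiff(seq_len(n_conformers), planted), ] <- w
    amp <- max(abs(v), 1e-12)
    scale <- divergence * min(base) / amp
    profs <- sweep(v * scale, 2, base, "+")
    profs[profs < 0] <- 0             # cannot trigger for divergence <= 1
    sweep(profs, 1, rowSums(profs), "/")
  }
  hb_profs <- perturb(spec$hb_profile, 1000L)
  vdw_profs <- perturb(spec$vdw_profile, 2000L)
  site <- make_binding_site(spec)
  out <- lapply(seq_len(n_conformers), function(k) {
    sp <- fixture_spec(n, hb_profile = hb_profs[k, ],
                       vdw_profile = vdw_profs[k, ],
                       n_poses = spec$n_poses, seed = spec$seed + k,
                       jitter = spec$jitter)
    make_pose_ensemble(sp, site = site, assignment = "quota")
  })
  attr(out, "planted") <- as.integer(planted)
  attr(out, "profiles") <- list(hb = hb_profs, vdw = vdw_profs)
  out
}
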