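#' Seeded synthetic-data generators
#'
#' Deterministic generators providing every input the pipeline consumes
#' without external data: pseudo-atomic antibody-receptor surrogates, DLS
#' correlograms with known decay rate, trajectories with prescribed
#' contact-persistence schedules, and titratable-group sets.  The same
#' spec + seed always yields identical output; the caller's RNG state is
#' left untouched.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# a lobe of overlapping pseudo-atom beads: two parallel rows along `dir`
lobe_beads <- function(origin, dir, length, n_beads, thickness) {
  dir <- dir / sqrt(sum(dir^2))
  perp <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(1, 0, 0)
  perp <- perp - sum(perp * dir) * dir
  perp <- perp / sqrt(sum(perp^2))
  t <- seq(0, length, length.out = n_beads)
  rbind(
    t(vapply(t, function(s) origin + s * dir + (thickness / 2) * perp, numeric(3))),
    t(vapply(t, function(s) origin + s * dir - (thickness / 2) * perp, numeric(3))))
}

#' Pseudo-atomic antibody-receptor complex surrogate
#'
#' Builds a Y-shaped three-lobe antibody surrogate (two Fab arms + one Fc
#' stem of overlapping pseudo-atom beads) with one (`"1:1"`) or two
#' (`"1:2"`) elongated receptor lobes attached at the Fab tips.  Models are
#' rigid hinge perturbations of the arms (and attached receptors) plus
#' independent per-atom Gaussian jitter of prescribed RMS.  Lobe geometry
#' is fixed so the 1:1 surrogate is hydrodynamically smaller than the 1:2,
#' mirroring the size ordering of real antibody-receptor complexes; no
#' attempt is made to match any particular measured value.
#'
#' Chains: `H`/`L` Fab arms, `F` Fc, `X` (and `Y`) receptors.  Bead masses
#' are set so the surrogate molar masses are 149 kDa (antibody) plus
#' 88.7 kDa per receptor.
#'
#' @param stoichiometry `"1:1"` or `"1:2"` (antibody : receptor).
#' @param n_models number of ensemble models (>= 1).
#' @param jitter_rms per-atom 3-D displacement RMS, A.
#' @param seed integer seed.
#' @param hinge_sd hinge perturbation of the arm orientations, degrees.
#' @param bead_radius pseudo-atom radius, A.
#' @return A [hc_structure()].
#' @export
pseudo_complex <- function(stoichiometry = c("1:1", "1:2"), n_models = 8,
                           jitter_rms = 1.0, seed = 1, hinge_sd = 4,
                           bead_radius = 9) {
  stoichiometry <- match.arg(stoichiometry)
  if (n_models < 1) stop("n_models must be >= 1")
  if (jitter_rms < 0) stop("jitter_rms must be >= 0")
  arm_dir <- list(c(sin(50 * pi / 180), cos(50 * pi / 180), 0),
                  c(-sin(50 * pi / 180), cos(50 * pi / 180), 0))
  hinge <- c(0, 0, 0)
  fc <- lobe_beads(hinge, c(0, -1, 0), 42, 7, 16)
  arm1 <- lobe_beads(hinge, arm_dir[[1]], 48, 8, 16)
  arm2 <- lobe_beads(hinge, arm_dir[[2]], 48, 8, 16)
  tip1 <- hinge + 48 * arm_dir[[1]]
  tip2 <- hinge + 48 * arm_dir[[2]]
  rec1 <- lobe_beads(tip1, arm_dir[[1]], 55, 9, 14)
  beads <- list(F = fc, H = arm1, L = arm2, X = rec1)
  if (stoichiometry == "1:2") beads$Y <- lobe_beads(tip2, arm_dir[[2]], 55, 9, 14)

  chain <- rep(names(beads), vapply(beads, nrow, integer(1)))
  base <- do.call(rbind, beads)
  n_ab <- nrow(fc) + nrow(arm1) + nrow(arm2)
  mass <- numeric(nrow(base))
  mass[chain %in% c("F", "H", "L")] <- 149000 / n_ab
  for (rc in c("X", "Y"))
    if (any(chain == rc)) mass[chain == rc] <- 88700 / sum(chain == rc)

  atoms <- tibble::tibble(
    element = "C", name = "CA",
    residue_id = seq_len(nrow(base)),
    residue_name = "BEA", chain_id = chain,
    radius = bead_radius, mass = mass)

  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  arm_sets <- list(c("H", "X"), if (stoichiometry == "1:2") c("L", "Y") else "L")
  models <- with_seed(seed, lapply(seq_len(n_models), function(k) {
    m <- base
    for (aset in arm_sets) {
      ang <- stats::rnorm(1, 0, hinge_sd)
      rows <- chain %in% aset
      m[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2, hinge) %*%
                           t(rot_z(ang)), 2, hinge, "+")
    }
    m + matrix(stats::rnorm(length(m), 0, jitter_rms / sqrt(3)), ncol = 3)
  }))
  hc_structure(atoms, models)
}

#' Synthetic DLS correlogram with known truth
#'
#' `g2(t) = baseline + beta exp(-2 D q^2 t) + N(0, sigma)` on log-spaced
#' lags.
#'
#' @param D diffusion coefficient, cm^2/s.
#' @param q scattering vector, 1/m (default: 633 nm, 173 degrees, n=1.33).
#' @param t_range lag range, s (log-spaced).
#' @param n_points number of lags (>= 20).
#' @param noise_sigma additive Gaussian noise SD.
#' @param beta coherence factor.
#' @param baseline long-time asymptote.
#' @param seed integer seed.
#' @return A [correlogram()].
#' @export
synth_correlogram <- function(D, q = scattering_vector(), t_range = c(1e-7, 1e-2),
                              n_points = 200, noise_sigma = 0.005,
                              beta = 0.9, baseline = 1, seed = 1) {
  if (D <= 0) stop("D must be positive")
  if (n_points < 20) stop("n_points must be >= 20")
  lags <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_points))
  gamma <- D * 1e-4 * q^2
  clean <- baseline + beta * exp(-2 * gamma * lags)
  noise <- if (noise_sigma > 0)
    with_seed(seed, stats::rnorm(n_points, 0, noise_sigma)) else 0
  correlogram(lags, clean + noise, baseline = baseline, beta = beta, q = q)
}

#' Synthetic trajectory with prescribed contact persistence
#'
#' Builds a two-chain ensemble of single-atom residues where each scheduled
#' pair (residue i of chain A vs residue i of chain B) is placed below the
#' cutoff in exactly `round(fraction * n_frames)` frames (frame subset
#' drawn deterministically per seed) and far above it otherwise.  Pairs are
#' spatially separated so no unscheduled contacts arise.
#'
#' @param pair_schedule numeric vector of persistence fractions in `[0, 1]`
#'   (one scheduled pair per element), or a data frame with columns
#'   `residue` and `fraction`.
#' @param n_frames number of frames (>= 1).
#' @param cutoff contact cutoff, A.
#' @param seed integer seed.
#' @return A [hc_structure()] with `n_frames` models.
#' @export
synth_trajectory <- function(pair_schedule, n_frames = 100, cutoff = 5.0,
                             seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (is.data.frame(pair_schedule)) {
    if (anyDuplicated(pair_schedule$residue))
      stop("conflicting schedules: duplicate residue entries")
    fractions <- pair_schedule$fraction
    res_ids <- pair_schedule$residue
  } else {
    fractions <- as.numeric(pair_schedule)
    res_ids <- seq_along(fractions)
  }
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  np <- length(fractions)
  atoms <- tibble::tibble(
    element = "C", name = "CA",
    residue_id = rep(res_ids, 2L),
    residue_name = "GLY",
    chain_id = rep(c("A", "B"), each = np),
    radius = 1.7, mass = 12.011)
  contact_frames <- with_seed(seed, lapply(fractions, function(fr) {
    k <- round(fr * n_frames)
    if (k == 0) integer(0) else sort(sample.int(n_frames, k))
  }))
  models <- lapply(seq_len(n_frames), function(fr) {
    xa <- cbind(100 * seq_len(np), 0, 0)
    on <- vapply(contact_frames, function(cf) fr %in% cf, logical(1))
    xb <- cbind(100 * seq_len(np), ifelse(on, cutoff - 1, cutoff + 45), 0)
    rbind(xa, xb)
  })
  hc_structure(atoms, models)
}

#' Synthetic titratable-group set
#'
#' @param n_acidic,n_basic group counts (>= 0).
#' @param pKa_acid,pKa_base site pKa values.
#' @return A [titration_model()] (empty model with a warning when both
#'   counts are zero).
#' @export
synth_titration <- function(n_acidic, n_basic, pKa_acid = 3.8,
                            pKa_base = 10.5) {
  if (n_acidic < 0 || n_basic < 0) stop("counts must be >= 0")
  rows <- list()
  if (n_acidic > 0)
    rows[[1]] <- tibble::tibble(label = "acid", pKa = pKa_acid,
                                charge_sign = -1, count = n_acidic)
  if (n_basic > 0)
    rows[[length(rows) + 1]] <- tibble::tibble(label = "base", pKa = pKa_base,
                                               charge_sign = 1, count = n_basic)
  if (!length(rows)) {
    warning("empty titration model")
    return(titration_model(tibble::tibble(label = character(), pKa = numeric(),
                                          charge_sign = numeric(),
                                          count = numeric())))
  }
  titration_model(dplyr::bind_rows(rows))
}
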