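#' Debye screening parameter
#'
#' For a monovalent electrolyte in water at 298 K the Debye length is
#' `1/kappa = 0.304 / sqrt(I)` nm (the standard constant, used verbatim at
#' 298 K so the textbook value is reproduced exactly).  At other
#' temperatures the full Debye expression
#' `kappa^2 = 2 e^2 N_A 1000 I / (eps0 eps_r(T) kB T)` is used with the
#' water permittivity polynomial unless `relative_permittivity` is given.
#'
#' @param ionic_strength ionic strength, mol/L.
#' @param temperature K (default 298).
#' @param relative_permittivity override for the dielectric constant.
#' @return kappa, 1/nm.
#' @export
debye_parameter <- function(ionic_strength, temperature = 298,
                            relative_permittivity = NULL) {
  if (any(ionic_strength <= 0)) stop("ionic_strength must be positive")
  if (abs(temperature - 298) < 0.5 && is.null(relative_permittivity))
    return(sqrt(ionic_strength) / 0.304)
  pc <- physical_constants()
  er <- if (is.null(relative_permittivity)) water_permittivity(temperature)
        else relative_permittivity
  k2 <- 2 * pc$elementary_charge^2 * pc$avogadro * 1000 * ionic_strength /
    (pc$vacuum_permittivity * er * pc$boltzmann * temperature)
  sqrt(k2) * 1e-9
}

#' @rdname debye_parameter
#' @return `debye_length()`: the screening length `1/kappa`, nm.
#' @export
debye_length <- function(ionic_strength, temperature = 298,
                         relative_permittivity = NULL) {
  1 / debye_parameter(ionic_strength, temperature, relative_permittivity)
}

# static relative permittivity of water (CRC polynomial in Celsius)
water_permittivity <- function(temperature) {
  tc <- temperature - 273.15
  87.740 - 0.40008 * tc + 9.398e-4 * tc^2 - 1.410e-6 * tc^3
}

#' Henry's function (Ohshima's approximant)
#'
#' Smooth interpolation between the Hueckel limit `f(0) = 1` and the
#' Smoluchowski limit `f(Inf) = 3/2`:
#' `f = 1 + 1/2 * [1 + 2.5 / (ka (1 + 2 exp(-ka)))]^-3` (accurate to about
#' 1% against Henry's exact hydrodynamic result over the full range).
#'
#' @param kappa_a product of Debye parameter and particle radius
#'   (dimensionless, >= 0).
#' @return f in `[1, 1.5]`.
#' @export
henry_function <- function(kappa_a) {
  if (any(kappa_a < 0)) stop("kappa_a must be >= 0")
  out <- ifelse(kappa_a == 0, 1,
                1 + 0.5 * (1 + 2.5 / (kappa_a * (1 + 2 * exp(-kappa_a))))^(-3))
  out
}

#' Zeta potential from electrophoretic mobility (Henry's equation)
#'
#' `zeta = 3 eta mu_e / (2 eps f(ka))` with `eps = eps_r eps0`.
#'
#' @param mobility electrophoretic mobility, um cm / (V s).
#' @param conditions an [electro_conditions()].
#' @param f Henry's function value, in `[1, 1.5]`.
#' @return zeta potential, mV (same sign as the mobility).
#' @export
zeta_from_mobility <- function(mobility, conditions = electro_conditions(),
                               f = 1.5) {
  if (any(f < 1) || any(f > 1.5)) stop("f must be in [1, 1.5]")
  eps <- conditions$relative_permittivity *
    physical_constants()$vacuum_permittivity
  mu_si <- mobility * 1e-8          # um cm / (V s) -> m^2 / (V s)
  zeta_v <- 3 * eta_si(conditions) * mu_si / (2 * eps * f)
  zeta_v * 1e3
}

#' Debye-Hueckel-Henry effective charge from mobility
#'
#' `Z = 6 pi eta a mu_e (1 + ka) / (f(ka) e)`, the effective net charge of
#' a sphere of radius `a` inferred from its mobility under linearised
#' electrokinetics (valid for |zeta| below the thermal voltage).
#'
#' @param mobility electrophoretic mobility, um cm / (V s).
#' @param particle_radius hydrodynamic radius a, nm.
#' @param kappa Debye parameter, 1/nm.
#' @param conditions an [electro_conditions()].
#' @param f Henry's function value (default computed from `kappa * a`).
#' @return Effective charge in elementary charges (sign of the mobility).
#' @export
dhh_charge <- function(mobility, particle_radius, kappa,
                       conditions = electro_conditions(), f = NULL) {
  if (any(particle_radius <= 0)) stop("particle_radius must be positive")
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ka <- kappa * particle_radius
  if (is.null(f)) f <- henry_function(ka)
  if (any(f < 1) || any(f > 1.5)) stop("f must be in [1, 1.5]")
  e <- physical_constants()$elementary_charge
  mu_si <- mobility * 1e-8
  a_m <- particle_radius * 1e-9
  6 * pi * eta_si(conditions) * a_m * mu_si * (1 + ka) / (f * e)
}

#' Thermal voltage
#'
#' `k_B T / e` in mV; the Debye-Hueckel-Henry charge inversion assumes
#' |zeta| below this bound, so reductions warn beyond it.
#'
#' @param temperature K.
#' @return mV.
#' @export
thermal_voltage <- function(temperature = 298) {
  if (any(temperature < 0)) stop("temperature must be >= 0")
  pc <- physical_constants()
  pc$boltzmann * temperature / pc$elementary_charge * 1e3
}

#' Titratable-group model
#'
#' A set of acid/base groups with site pKa values for Henderson-Hasselbalch
#' net-charge titration.  This sequence/group-level model is an explicit
#' approximation to structure-based pKa calculations (PROPKA-class): it
#' ignores residue environment shifts, so theoretical charges derived from
#' it are indicative, not reference values.
#'
#' @param groups data frame with columns `label`, `pKa` (in (0, 14)),
#'   `charge_sign` (+1 basic, -1 acidic) and `count` (>= 1).
#' @return A `hc_titration` object.
#' @export
titration_model <- function(groups) {
  groups <- tibble::as_tibble(groups)
  need <- c("label", "pKa", "charge_sign", "count")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (nrow(groups)) {
    if (any(groups$pKa <= 0 | groups$pKa >= 14))
      stop("pKa values must lie in (0, 14)")
    if (!all(groups$charge_sign %in% c(-1, 1)))
      stop("charge_sign must be +1 or -1")
    if (any(groups$count < 1)) stop("count must be >= 1")
  }
  structure(list(groups = groups), class = "hc_titration")
}

# default side-chain pKa set (plus termini)
default_pka_table <- function() {
  tibble::tibble(
    residue = c("D", "E", "H", "C", "Y", "K", "R", "Nterm", "Cterm"),
    pKa = c(3.8, 4.5, 6.5, 8.3, 10.1, 10.5, 12.5, 8.0, 3.6),
    charge_sign = c(-1, -1, 1, -1, -1, 1, 1, 1, -1))
}

#' Build a titration model from a protein sequence
#'
#' Counts titratable side chains (D, E, H, C, Y, K, R) in a one-letter
#' sequence and applies a standard pKa set; chain termini optional.
#'
#' @param sequence one-letter amino-acid string (or vector of chains).
#' @param include_termini count one N- and one C-terminus per chain.
#' @param pka_table override table as in [default_pka_table()].
#' @return A [titration_model()].
#' @export
titration_from_sequence <- function(sequence, include_termini = TRUE,
                                    pka_table = default_pka_table()) {
  chains <- toupper(gsub("[^A-Za-z]", "", sequence))
  aa <- unlist(strsplit(chains, ""))
  counts <- table(aa)
  rows <- list()
  for (i in seq_len(nrow(pka_table))) {
    res <- pka_table$residue[i]
    if (res %in% c("Nterm", "Cterm")) next
    n <- if (res %in% names(counts)) as.integer(counts[[res]]) else 0L
    if (n > 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = res, pKa = pka_table$pKa[i],
        charge_sign = pka_table$charge_sign[i], count = n)
  }
  if (include_termini && length(chains)) {
    nt <- pka_table[pka_table$residue == "Nterm", ]
    ct <- pka_table[pka_table$residue == "Cterm", ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = "Nterm", pKa = nt$pKa, charge_sign = nt$charge_sign,
      count = length(chains))
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = "Cterm", pKa = ct$pKa, charge_sign = ct$charge_sign,
      count = length(chains))
  }
  titration_model(dplyr::bind_rows(rows))
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' `Z(pH) = sum_basic count / (1 + 10^(pH - pKa)) -
#'  sum_acidic count / (1 + 10^(pKa - pH))`.
#'
#' @param model a [titration_model()].
#' @param pH pH value(s) in `[0, 14]`.
#' @return Net charge in elementary charges (vectorised over `pH`).
#' @export
net_charge_at_pH <- function(model, pH) {
  if (any(pH < 0 | pH > 14)) stop("pH must be in [0, 14]")
  g <- model$groups
  if (!nrow(g)) {
    warning("empty titration model; net charge is 0")
    return(rep(0, length(pH)))
  }
  vapply(pH, function(p) {
    basic <- g$charge_sign > 0
    zb <- sum(g$count[basic] / (1 + 10^(p - g$pKa[basic])))
    za <- sum(g$count[!basic] / (1 + 10^(g$pKa[!basic] - p)))
    zb - za
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` where the Henderson-Hasselbalch net charge
#' crosses zero, to |Z| < 1e-6.  Requires at least one acidic and one
#' basic group (otherwise the charge never changes sign).
#'
#' @param model a [titration_model()].
#' @return pI, pH units.
#' @export
isoelectric_point <- function(model) {
  g <- model$groups
  if (!nrow(g) || !any(g$charge_sign > 0) || !any(g$charge_sign < 0))
    stop("isoelectric point needs at least one acidic and one basic group")
  lo <- 0; hi <- 14
  zlo <- net_charge_at_pH(model, lo)
  zhi <- net_charge_at_pH(model, hi)
  if (zlo <= 0 || zhi >= 0)
    stop("net charge does not change sign on [0, 14]")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    zm <- net_charge_at_pH(model, mid)
    if (abs(zm) < 1e-6) return(mid)
    if (zm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Assemble an electrokinetics report table
#'
#' For each record (mobility, particle radius) computes the Debye
#' parameter, Henry's function, zeta potential, effective charge from
#' mobility (Z_EM), the theoretical Henderson-Hasselbalch charge and pI
#' when a titration model is supplied, and `delta_z = |Z_EM - Z_theory|`.
#' If the records already carry `z_effective` / `z_theory` columns (e.g.
#' transcribed instrument and pKa-package outputs), those printed values
#' are used for `delta_z` instead of the recomputed ones.
#'
#' @param records data frame with columns `name`, `mobility`
#'   (um cm / (V s)) and `particle_radius` (nm); optionally `z_effective`,
#'   `z_theory`.
#' @param titration_models optional named list of [titration_model()]s
#'   keyed by record name.
#' @param conditions an [electro_conditions()].
#' @param pH pH at which theoretical charges are evaluated (default 7.5).
#' @return A tibble mirroring the electrostatics report columns.
#' @export
build_table2 <- function(records, titration_models = NULL,
                         conditions = electro_conditions(), pH = 7.5) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) return(records)
  if (!"particle_radius" %in% names(records) || any(is.na(records$particle_radius)))
    stop("record missing particle_radius: ",
         paste(records$name[is.na(records$particle_radius)], collapse = ", "))
  kappa <- debye_parameter(conditions$ionic_strength, conditions$temperature)
  ka <- kappa * records$particle_radius
  f <- henry_function(ka)
  zeta <- zeta_from_mobility(records$mobility, conditions, f)
  z_em <- dhh_charge(records$mobility, records$particle_radius, kappa,
                     conditions, f)
  tv <- thermal_voltage(conditions$temperature)
  if (any(abs(zeta) > tv))
    warning("some |zeta| exceed the thermal voltage; DHH charges are extrapolations there")
  z_th <- rep(NA_real_, nrow(records))
  pI <- rep(NA_real_, nrow(records))
  if (!is.null(titration_models)) {
    for (i in seq_len(nrow(records))) {
      tm <- titration_models[[records$name[i]]]
      if (!is.null(tm)) {
        z_th[i] <- net_charge_at_pH(tm, pH)
        pI[i] <- tryCatch(isoelectric_point(tm), error = function(e) NA_real_)
      }
    }
  }
  z_eff_out <- if ("z_effective" %in% names(records)) records$z_effective else z_em
  if ("z_theory" %in% names(records)) z_th <- records$z_theory
  tibble::tibble(name = records$name, mobility = records$mobility,
                 particle_radius = records$particle_radius,
                 kappa = kappa, kappa_a = ka, henry_f = f,
                 zeta = zeta, z_em_computed = z_em,
                 z_effective = z_eff_out, z_theory = z_th,
                 delta_z = abs(z_eff_out - z_th), pI = pI)
}
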