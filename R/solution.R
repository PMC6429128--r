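#' Hydrodynamic radius from intrinsic viscosity (Einstein relation)
#'
#' Inverts the Einstein viscosity relationship `[eta] = 2.5 N_A V_e / M_w`
#' with `V_e = (4/3) pi r_h^3`, giving
#' `r_h = (3 [eta] M_w / (10 pi N_A))^(1/3)`.
#'
#' @param molecular_weight molar mass, g/mol.
#' @param intrinsic_viscosity intrinsic viscosity, cm^3/g.
#' @return Hydrodynamic radius, nm.
#' @export
radius_from_viscosity <- function(molecular_weight, intrinsic_viscosity) {
  if (any(molecular_weight <= 0) || any(intrinsic_viscosity <= 0))
    stop("molecular_weight and intrinsic_viscosity must be positive")
  NA_ <- physical_constants()$avogadro
  r_cm <- (3 * intrinsic_viscosity * molecular_weight / (10 * pi * NA_))^(1 / 3)
  r_cm * 1e7
}

#' Intrinsic viscosity from hydrodynamic radius (Einstein relation)
#'
#' Exact inverse of [radius_from_viscosity()]:
#' `[eta] = 2.5 N_A (4/3) pi r_h^3 / M_w`.
#'
#' @param molecular_weight molar mass, g/mol.
#' @param r_h hydrodynamic radius, nm.
#' @return Intrinsic viscosity, cm^3/g.
#' @export
viscosity_from_radius <- function(molecular_weight, r_h) {
  if (any(molecular_weight <= 0) || any(r_h <= 0))
    stop("molecular_weight and r_h must be positive")
  NA_ <- physical_constants()$avogadro
  2.5 * NA_ * (4 / 3) * pi * (r_h * 1e-7)^3 / molecular_weight
}

#' Stokes-Einstein hydrodynamic radius from a diffusion coefficient
#'
#' `r_h = k_B T / (6 pi eta D)`.
#'
#' @param diffusion translational diffusion coefficient, cm^2/s.
#' @param conditions a [solvent_conditions()].
#' @return Hydrodynamic radius, nm.
#' @export
stokes_einstein_radius <- function(diffusion, conditions = solvent_conditions()) {
  if (any(diffusion <= 0)) stop("diffusion must be positive")
  kB <- physical_constants()$boltzmann
  r_m <- kB * conditions$temperature /
    (6 * pi * eta_si(conditions) * diffusion * 1e-4)
  r_m * 1e9
}

#' @rdname stokes_einstein_radius
#' @param r_h hydrodynamic radius, nm.
#' @return `diffusion_from_radius()`: diffusion coefficient, cm^2/s.
#' @export
diffusion_from_radius <- function(r_h, conditions = solvent_conditions()) {
  if (any(r_h <= 0)) stop("r_h must be positive")
  kB <- physical_constants()$boltzmann
  kB * conditions$temperature /
    (6 * pi * eta_si(conditions) * r_h * 1e-9) * 1e4
}

#' Assemble a solution-properties report table
#'
#' Takes measurement records (one row per species: molar mass from SEC,
#' intrinsic viscosity, and/or DLS diffusion coefficient) and fills in the
#' two hydrodynamic radii: from `[eta]` via the Einstein relation and from
#' `D` via Stokes-Einstein.  Record pairs whose two radii differ by more
#' than 10% are flagged as anomalous (for compact glycoproteins the two
#' definitions agree within that band).
#'
#' @param records data frame with columns `name`, `molecular_weight` (kDa)
#'   and at least one of `intrinsic_viscosity` (cm^3/g) and `diffusion`
#'   (1e-7 cm^2/s).
#' @param conditions a [solvent_conditions()] (used for the DLS column).
#' @return A tibble with added columns `r_h_from_viscosity` (nm),
#'   `r_h_from_diffusion` (nm) and `anomalous`.
#' @export
build_table1 <- function(records, conditions = solvent_conditions()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L)
    return(tibble::tibble(name = character(), molecular_weight = numeric(),
                          intrinsic_viscosity = numeric(), diffusion = numeric(),
                          r_h_from_viscosity = numeric(),
                          r_h_from_diffusion = numeric(), anomalous = logical()))
  if (!"molecular_weight" %in% names(records) ||
      any(is.na(records$molecular_weight)))
    stop("record missing molecular_weight: ",
         paste(records$name[is.na(records$molecular_weight)], collapse = ", "))
  if (!"intrinsic_viscosity" %in% names(records))
    records$intrinsic_viscosity <- NA_real_
  if (!"diffusion" %in% names(records)) records$diffusion <- NA_real_
  if (any(is.na(records$intrinsic_viscosity) & is.na(records$diffusion)))
    stop("each record needs at least one of intrinsic_viscosity or diffusion")
  mw_g <- records$molecular_weight * 1e3
  out <- dplyr::mutate(
    records,
    r_h_from_viscosity = ifelse(
      is.na(.data$intrinsic_viscosity), NA_real_,
      radius_from_viscosity(mw_g, pmax(.data$intrinsic_viscosity, 1e-12))),
    r_h_from_diffusion = ifelse(
      is.na(.data$diffusion), NA_real_,
      stokes_einstein_radius(pmax(.data$diffusion, 1e-12) * 1e-7,
                             conditions)))
  dplyr::mutate(out, anomalous = !is.na(.data$r_h_from_viscosity) &
                  !is.na(.data$r_h_from_diffusion) &
                  abs(.data$r_h_from_viscosity - .data$r_h_from_diffusion) /
                    pmin(.data$r_h_from_viscosity, .data$r_h_from_diffusion) > 0.10)
}

#' Write a report table as CSV with table-style rounding
#'
#' Radii and viscosities are rounded to one decimal (the print convention);
#' use [jsonlite::write_json()] on the unrounded tibble for full precision.
#'
#' @param table tibble from [build_table1()] or [build_table2()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(table, path) {
  rnd <- intersect(c("intrinsic_viscosity", "r_h_from_viscosity",
                     "r_h_from_diffusion", "zeta", "z_effective", "z_theory",
                     "delta_z", "pI"), names(table))
  for (cn in rnd) table[[cn]] <- round(table[[cn]], 1)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
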