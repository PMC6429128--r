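#' Atomic structures and ensembles
#'
#' A `hc_structure` holds an ordered atom table plus one or more coordinate
#' models (an ensemble; multi-model PDB files stand in for MD snapshot
#' collections).  The atom table is a tibble with columns `element`, `name`,
#' `residue_id`, `residue_name`, `chain_id`, `radius` (van der Waals, A) and
#' `mass` (Da); `models` is a list of n x 3 coordinate matrices (A), all
#' congruent with the atom table.
#'
#' @param atoms tibble as described above.
#' @param models list of n x 3 numeric matrices, A.
#' @return A `hc_structure`.
#' @export
hc_structure <- function(atoms, models) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("element", "name", "residue_id", "residue_name", "chain_id",
            "radius", "mass")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (!length(models)) stop("at least one coordinate model is required")
  models <- lapply(models, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(atoms)
  ok <- vapply(models, function(m) nrow(m) == n && ncol(m) == 3L, logical(1))
  if (!all(ok))
    stop("all models must be n_atoms x 3 coordinate matrices congruent with the atom table")
  if (any(!vapply(models, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite coordinates")
  if (any(atoms$radius <= 0) || any(atoms$mass <= 0))
    stop("atom radii and masses must be positive")
  structure(list(atoms = atoms, models = models), class = "hc_structure")
}

#' @export
print.hc_structure <- function(x, ...) {
  cat(sprintf("<hc_structure> %d atoms, %d model(s), chains: %s\n",
              nrow(x$atoms), length(x$models),
              paste(unique(x$atoms$chain_id), collapse = " ")))
  invisible(x)
}

#' @rdname hc_structure
#' @param x object to test.
#' @export
is_hc_structure <- function(x) inherits(x, "hc_structure")

#' @export
length.hc_structure <- function(x) length(x$models)

# Bondi-style van der Waals radii (A), keyed by element symbol; elements
# absent from the table get the documented default of 1.70 A.
vdw_radii_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    NA_ = 2.27, MG = 1.73, K = 2.75, CA = 2.31, ZN = 1.39, FE = 1.40)
}

atomic_mass_table <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
    NA_ = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
    FE = 55.845)
}

element_radius <- function(element) {
  tab <- vdw_radii_table()
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  r <- unname(tab[key])
  r[is.na(r)] <- 1.70
  r
}

element_mass <- function(element) {
  tab <- atomic_mass_table()
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  m <- unname(tab[key])
  m[is.na(m)] <- 12.011
  m
}

# derive the element symbol from a PDB atom name when the element column is
# blank (common in synthetic files)
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "SE", "ZN", "FE", "MG", "NA", "CA")
  ifelse(two %in% known2 & !grepl("^C[A-Z]$", two) |
           two %in% c("CL", "BR", "SE", "ZN", "FE", "MG"),
         two, substr(nm, 1, 1))
}

#' Read an atomic structure (optionally multi-model) from PDB
#'
#' Wraps the bio3d PDB reader.  MODEL/ENDMDL blocks become ensemble models
#' (all must have the same atom count); HETATM records (glycans, ligands)
#' are included by default because sugars contribute materially to the
#' hydrodynamic surface; alternate locations keep the highest-occupancy
#' conformer; van der Waals radii and masses are assigned per element from
#' a Bondi-style table (default 1.70 A / 12.011 Da for unknown elements).
#'
#' @param path PDB file.
#' @param include_hetatm include HETATM records (default `TRUE`).
#' @return A [hc_structure()].
#' @export
read_pdb <- function(path, include_hetatm = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # fixed-width sanity check with line numbers before handing to bio3d
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("unparseable coordinate record at line %d of %s", i, path))
  }
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL blocks in ", path)
    counts <- vapply(seq_along(model_starts), function(k)
      sum(is_atom[model_starts[k]:ends[k]]), integer(1))
    if (length(unique(counts)) != 1)
      stop(sprintf("MODEL blocks differ in atom count in %s: %s",
                   path, paste(counts, collapse = ", ")))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!include_hetatm) keep <- at$type == "ATOM"
  # alternate locations: keep highest occupancy per (chain, resno, atom name)
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    o <- order(key, -replace(at$o, is.na(at$o), 1))
    dup <- duplicated(key[o])[order(o)]
    keep <- keep & !dup
  }
  idx <- which(keep)
  if (!length(idx)) stop("no atoms retained from ", path)
  elem <- at$elesy[idx]
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- guess_element(at$elety[idx][blank])
  elem <- trimws(elem)
  atoms <- tibble::tibble(
    element = elem,
    name = trimws(at$elety[idx]),
    residue_id = as.integer(at$resno[idx]),
    residue_name = trimws(at$resid[idx]),
    chain_id = ifelse(is.na(at$chain[idx]), " ", at$chain[idx]),
    radius = element_radius(elem),
    mass = element_mass(elem))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  models <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, cols], ncol = 3, byrow = TRUE))
  st <- hc_structure(atoms, models)
  for (k in seq_along(st$models)) {
    mk <- st$models[[k]]
    if (anyDuplicated(round(mk, 6)))
      warning(sprintf("model %d contains atoms at identical coordinates", k))
  }
  st
}

#' Write an atomic structure (optionally multi-model) to PDB
#'
#' Fixed-width PDB writer; coordinates are stored to 3 decimals (the PDB
#' field width), so a read/write roundtrip preserves them to 1e-3 A.
#' Multi-model structures are wrapped in MODEL/ENDMDL blocks.
#'
#' @param structure a [hc_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (any(nchar(a$name) > 4))
    stop("atom name exceeds the 4-character PDB field: ",
         a$name[which(nchar(a$name) > 4)[1]])
  if (any(nchar(a$residue_name) > 3))
    stop("residue name exceeds the 3-character PDB field")
  if (any(a$residue_id > 9999L))
    stop("residue number exceeds the 4-digit PDB field")
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  multi <- length(structure$models) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(structure$models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- structure$models[[k]]
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       (seq_len(nrow(a)) - 1L) %% 99999L + 1L, nm,
                       a$residue_name, a$chain_id, a$residue_id,
                       m[, 1], m[, 2], m[, 3], 1, 0, toupper(a$element)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Center of mass of one residue
#'
#' Mass-weighted mean position of a residue's atoms in one model, in A.
#'
#' @param structure a [hc_structure()].
#' @param model_index model number (1-based).
#' @param chain_id chain label.
#' @param residue_id residue sequence number (author numbering).
#' @param weighted mass-weighted (default) or geometric mean.
#' @return Length-3 numeric vector, A.
#' @export
residue_center_of_mass <- function(structure, model_index = 1L, chain_id,
                                   residue_id, weighted = TRUE) {
  if (model_index < 1L || model_index > length(structure$models))
    stop("model_index out of range")
  sel <- structure$atoms$chain_id == chain_id &
    structure$atoms$residue_id == residue_id
  if (!any(sel))
    stop(sprintf("no residue %s/%s in structure", chain_id, residue_id))
  m <- structure$models[[model_index]][sel, , drop = FALSE]
  w <- if (weighted) structure$atoms$mass[sel] else rep(1, sum(sel))
  colSums(m * w) / sum(w)
}

#' Total molar mass of a structure
#' @param structure a [hc_structure()].
#' @return Sum of atomic masses, g/mol.
#' @export
structure_mass <- function(structure) sum(structure$atoms$mass)
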