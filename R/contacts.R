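#' Residue selections
#'
#' A selection names a set of residues by chain (optionally restricted to
#' residue numbers).  Used by the contact-map operations to define the two
#' sides of an interface (e.g. antibody Fab chains vs receptor domain).
#'
#' @param chains character vector of chain ids.
#' @param residues optional integer vector restricting to these residue
#'   numbers (author numbering).
#' @return A `hc_selection`.
#' @export
residue_selection <- function(chains, residues = NULL) {
  structure(list(chains = chains, residues = residues),
            class = "hc_selection")
}

# residues (chain, id) covered by a selection
selection_residues <- function(structure, sel) {
  a <- structure$atoms
  keep <- a$chain_id %in% sel$chains
  if (!is.null(sel$residues)) keep <- keep & a$residue_id %in% sel$residues
  unique(tibble::tibble(chain_id = a$chain_id[keep],
                        residue_id = a$residue_id[keep]))
}

# residue centers of mass for one model, returned with the residue keys
residue_coms <- function(structure, model_index, residues, weighted = TRUE) {
  a <- structure$atoms
  m <- structure$models[[model_index]]
  key <- paste(a$chain_id, a$residue_id)
  want <- paste(residues$chain_id, residues$residue_id)
  idx <- key %in% want
  w <- if (weighted) a$mass[idx] else rep(1, sum(idx))
  df <- tibble::tibble(key = key[idx],
                       wx = m[idx, 1] * w, wy = m[idx, 2] * w,
                       wz = m[idx, 3] * w, w = w)
  agg <- dplyr::summarise(dplyr::group_by(df, .data$key),
                          x = sum(.data$wx) / sum(.data$w),
                          y = sum(.data$wy) / sum(.data$w),
                          z = sum(.data$wz) / sum(.data$w), .groups = "drop")
  agg[match(want, agg$key), c("x", "y", "z")]
}

#' Residue contacts in one frame
#'
#' A residue pair (one from each selection) is in contact when the distance
#' between residue centers of mass is strictly below `cutoff`.
#'
#' @param structure a [hc_structure()].
#' @param model_index frame to analyse.
#' @param selection_a,selection_b disjoint [residue_selection()]s.
#' @param cutoff contact cutoff, A (default 5).
#' @param weighted mass-weighted centers of mass (default) or geometric.
#' @return Tibble of contacting pairs: `chain_a`, `residue_a`, `chain_b`,
#'   `residue_b`, `distance`.
#' @export
frame_contacts <- function(structure, model_index = 1L, selection_a,
                           selection_b, cutoff = 5.0, weighted = TRUE) {
  ra <- selection_residues(structure, selection_a)
  rb <- selection_residues(structure, selection_b)
  if (!nrow(ra) || !nrow(rb)) stop("empty selection")
  if (nrow(dplyr::inner_join(ra, rb, by = c("chain_id", "residue_id"))))
    stop("selections overlap")
  ca <- as.matrix(residue_coms(structure, model_index, ra, weighted))
  cb <- as.matrix(residue_coms(structure, model_index, rb, weighted))
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  tibble::tibble(chain_a = ra$chain_id[hit[, 1]],
                 residue_a = ra$residue_id[hit[, 1]],
                 chain_b = rb$chain_id[hit[, 2]],
                 residue_b = rb$residue_id[hit[, 2]],
                 distance = sqrt(pmax(d2[hit], 0)))
}

#' Persistent contacts over an ensemble
#'
#' Computes per-frame contacts for every model and keeps pairs whose
#' presence fraction is strictly greater than `threshold` (the map of
#' interface contacts conserved along a trajectory; a single reference
#' structure is simply a 1-model ensemble).
#'
#' @inheritParams frame_contacts
#' @param threshold persistence fraction required (strict, default 0.90).
#' @return A `hc_contact_map`: tibble of `chain_a`, `residue_a`, `chain_b`,
#'   `residue_b`, `persistence` with attributes `cutoff`, `threshold`,
#'   `n_models`.
#' @export
persistent_contacts <- function(structure, selection_a, selection_b,
                                cutoff = 5.0, threshold = 0.90,
                                weighted = TRUE) {
  n <- length(structure$models)
  if (!n) stop("empty ensemble")
  frames <- lapply(seq_len(n), function(k)
    frame_contacts(structure, k, selection_a, selection_b, cutoff, weighted))
  all <- dplyr::bind_rows(frames)
  if (!nrow(all)) {
    out <- tibble::tibble(chain_a = character(), residue_a = integer(),
                          chain_b = character(), residue_b = integer(),
                          persistence = numeric())
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(all, .data$chain_a, .data$residue_a, .data$chain_b,
                      .data$residue_b),
      persistence = dplyr::n() / n, .groups = "drop")
    out <- dplyr::filter(out, .data$persistence > threshold)
    out <- dplyr::arrange(out, .data$chain_a, .data$residue_a,
                          .data$chain_b, .data$residue_b)
  }
  structure(out, class = c("hc_contact_map", class(out)),
            cutoff = cutoff, threshold = threshold, n_models = n)
}

#' Compare two contact maps
#'
#' Partitions pairs by identity (persistence values ignored): contacts
#' shared by both maps, and those unique to either (e.g. crystallographic
#' contacts lost in simulation, and contacts gained).
#'
#' @param map_a,map_b contact maps (tibbles with the pair columns).
#' @return List of tibbles `shared`, `only_a`, `only_b`.
#' @export
compare_maps <- function(map_a, map_b) {
  keys <- c("chain_a", "residue_a", "chain_b", "residue_b")
  a <- tibble::as_tibble(map_a)[, keys]
  b <- tibble::as_tibble(map_b)[, keys]
  list(shared = dplyr::inner_join(a, b, by = keys),
       only_a = dplyr::anti_join(a, b, by = keys),
       only_b = dplyr::anti_join(b, a, by = keys))
}

#' Write a contact map as CSV plus a dense 0/1 matrix TSV
#'
#' @param map a `hc_contact_map`.
#' @param csv_path pair-list CSV output.
#' @param matrix_path optional dense 0/1 matrix TSV (rows: side a residues,
#'   columns: side b residues).
#' @return `csv_path`, invisibly.
#' @export
write_contact_map <- function(map, csv_path, matrix_path = NULL) {
  df <- tibble::as_tibble(map)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(matrix_path) && nrow(df)) {
    ra <- sort(unique(paste(df$chain_a, df$residue_a)))
    rb <- sort(unique(paste(df$chain_b, df$residue_b)))
    mat <- matrix(0L, length(ra), length(rb), dimnames = list(ra, rb))
    mat[cbind(match(paste(df$chain_a, df$residue_a), ra),
              match(paste(df$chain_b, df$residue_b), rb))] <- 1L
    utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE)
  }
  invisible(csv_path)
}
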