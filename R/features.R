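#' Accumulated-distance structural features of a residue
#'
#' The residue's surrounding patches are compared against the L
#' representative patches. With k surface neighbors: k >= 2 gives
#' K = choose(k, 2) 3-aa patches and feature j (1 <= j <= n3) is the sum
#' over the K patches of their structural similarity to 3-aa
#' representative Y_j, the 2-aa block being zero; k = 1 gives a single
#' 2-aa patch whose distances fill the 2-aa block (j > n3), the 3-aa block
#' being zero; k = 0 yields an all-zero vector flagged featureless (such
#' residues are excluded from training and prediction).
#'
#' @param complex a `complex_model`.
#' @param center_idx index of the (surface) residue in `complex$residues`.
#' @param index a `neighbor_index`.
#' @param reps a `representative_set`.
#' @return numeric vector of length `reps$L` with attributes `k`, `K` and
#'   `featureless`.
#' @export
structural_features <- function(complex, center_idx, index, reps) {
  stopifnot(inherits(reps, "representative_set"))
  n3 <- length(reps$reps_3aa)
  f <- numeric(reps$L)
  patches <- build_patches(complex, center_idx, index)
  k <- length(eligible_neighbors(complex, index, center_idx))
  if (length(patches) == 0L) {
    return(structure(f, k = k, K = 0L, featureless = TRUE))
  }
  m <- patches[[1L]]$m
  if (m == 2L) {
    d <- cpp_dss_cross(list(patches[[1L]]$coords),
                       lapply(reps$reps_2aa, function(p) p$coords), 2L, 5L)
    f[(n3 + 1L):reps$L] <- as.numeric(d)
  } else {
    d <- cpp_dss_cross(lapply(patches, function(p) p$coords),
                       lapply(reps$reps_3aa, function(p) p$coords), 3L, 5L)
    f[seq_len(n3)] <- colSums(d)
  }
  structure(f, k = k, K = length(patches), featureless = FALSE)
}

#' Amino-acid interface propensity
#'
#' Ratio of the (smoothed) frequency of an amino-acid type among surface
#' binding residues to its frequency among all surface residues, pooled
#' over the training complexes:
#' `[(N_int(a)+alpha) / (N_int+20 alpha)] / [(N_surf(a)+alpha) /
#' (N_surf+20 alpha)]`. The additive pseudo-count keeps the table finite
#' and positive for types absent from the interface.
#'
#' @param training_complexes annotated `complex_model`s.
#' @param alpha pseudo-count (default 1; 0 gives raw frequency ratios).
#' @return named numeric vector over the 20 amino acids.
#' @export
compute_propensity <- function(training_complexes, alpha = 1) {
  if (length(training_complexes) == 0L) {
    stop("empty training set in compute_propensity")
  }
  n_int <- n_surf <- structure(numeric(20), names = AA1)
  for (cx in training_complexes) {
    for (r in cx$residues) {
      if (is.na(r$is_surface) || !r$is_surface) next
      n_surf[r$aa] <- n_surf[r$aa] + 1
      if (isTRUE(r$is_binding)) n_int[r$aa] <- n_int[r$aa] + 1
    }
  }
  tot_int <- sum(n_int); tot_surf <- sum(n_surf)
  if (tot_surf == 0) stop("no surface residues in propensity training set")
  p_int <- (n_int + alpha) / (tot_int + 20 * alpha)
  p_surf <- (n_surf + alpha) / (tot_surf + 20 * alpha)
  p_int / p_surf
}

#' Assemble per-residue feature vectors
#'
#' One row per surface residue with a complete shape descriptor and at
#' least one surface neighbor: 60 structural features, 20 PSSM scores and
#' the interface propensity of the residue type (81 columns), plus
#' provenance and the binding label. Featureless (k = 0) residues are
#' excluded and their count reported via the `n_featureless` attribute.
#'
#' @param complexes list of annotated `complex_model`s.
#' @param reps a `representative_set`.
#' @param pssms named list of PSSM matrices keyed `"<source_id>|<chain>"`
#'   (rows follow the chain's parsed residue order).
#' @param prop propensity table from [compute_propensity()].
#' @param d_N neighbor cutoff in Angstrom.
#' @param same_chain_only passed to [build_neighbor_index()].
#' @return data.frame: provenance (`source_id`, `chain_id`, `seq_index`,
#'   `aa`), `label` (logical), then `f1..f60`, `pssm_*` (20), `propensity`.
#' @export
assemble_features <- function(complexes, reps, pssms, prop, d_N = 3.0,
                              same_chain_only = FALSE) {
  stopifnot(inherits(reps, "representative_set"))
  n3 <- length(reps$reps_3aa)
  rows <- list()
  n_featureless <- 0L
  for (cx in complexes) {
    index <- build_neighbor_index(cx, d_N = d_N,
                                  same_chain_only = same_chain_only)
    chain_pos <- chain_positions(cx)
    for (i in seq_along(cx$residues)) {
      r <- cx$residues[[i]]
      if (!isTRUE(r$is_surface) || is.null(r$shape_points)) next
      key <- paste(cx$source_id, r$chain_id, sep = "|")
      if (!key %in% names(pssms)) {
        stop("no PSSM supplied for chain ", key)
      }
      f <- structural_features(cx, i, index, reps)
      if (attr(f, "featureless")) {
        n_featureless <- n_featureless + 1L
        next
      }
      pssm_row <- pssms[[key]][chain_pos[[key]][[r$seq_index]], ]
      rows[[length(rows) + 1L]] <- c(
        list(source_id = cx$source_id, chain_id = r$chain_id,
             seq_index = r$seq_index, aa = r$aa, label = isTRUE(r$is_binding)),
        as.list(structure(as.numeric(f), names = paste0("f", seq_len(reps$L)))),
        as.list(structure(as.numeric(pssm_row),
                          names = paste0("pssm_", PSSM_AA))),
        list(propensity = unname(prop[r$aa])))
    }
  }
  if (length(rows) == 0L) {
    stop("no featured residues; check labels and neighbor cutoff")
  }
  df <- do.call(rbind, lapply(rows, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  attr(df, "n_featureless") <- n_featureless
  df
}

# Map residue seq_index -> row position within its chain (parsed order).
chain_positions <- function(cx) {
  out <- list()
  counters <- list()
  for (r in cx$residues) {
    key <- paste(cx$source_id, r$chain_id, sep = "|")
    counters[[key]] <- if (is.null(counters[[key]])) 1L else
      counters[[key]] + 1L
    out[[key]][[r$seq_index]] <- counters[[key]]
  }
  out
}

# Column names of the feature blocks, given the total dimensionality.
feature_columns <- function(df, blocks = c("structural", "pssm",
                                           "propensity")) {
  cols <- character(0)
  if ("structural" %in% blocks) cols <- c(cols, grep("^f[0-9]+$",
                                                     names(df), value = TRUE))
  if ("pssm" %in% blocks) cols <- c(cols, grep("^pssm_", names(df),
                                               value = TRUE))
  if ("propensity" %in% blocks) cols <- c(cols, "propensity")
  cols
}

#' Write a feature table as TSV
#'
#' @param features data.frame from [assemble_features()].
#' @param file output path; a JSON sidecar `<file>.json` records the
#'   representative-set file used, when given.
#' @param reps_file optional path of the representative-set artifact.
#' @export
write_features <- function(features, file, reps_file = NULL) {
  write.table(features, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reps_file)) {
    jsonlite::write_json(list(representative_set = reps_file,
                              n_rows = nrow(features)),
                         paste0(file, ".json"), auto_unbox = TRUE)
  }
  invisible(file)
}
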