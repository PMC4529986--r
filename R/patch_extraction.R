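#' Minimum inter-residue atom distance
#'
#' The smallest Euclidean distance over all heavy-atom pairs of the two
#' residues (hydrogens are excluded so the neighbor relation does not
#' depend on whether a structure was deposited with protons).
#'
#' @param r1,r2 residue models with at least one heavy atom each.
#' @return distance in Angstrom.
#' @export
residue_min_distance <- function(r1, r2) {
  a <- heavy_xyz(r1); b <- heavy_xyz(r2)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("residue without heavy atoms in residue_min_distance")
  }
  sqrt(max(0, min(cross_dist2(a, b))))
}

#' Build the surface neighbor relation
#'
#' Two surface residues are neighbors when their minimum heavy-atom
#' distance is at most `d_N`. Only surface residues participate; by
#' default residues of all protein chains of the complex may pair
#' (interfaces of multimers form continuous surfaces), restrict with
#' `same_chain_only`. Sequence-adjacent residues are included whenever
#' they satisfy the distance rule.
#'
#' @param complex a `complex_model` with surface labels assigned.
#' @param d_N neighbor distance cutoff in Angstrom (default 3.0).
#' @param same_chain_only restrict neighbor pairs to the same chain.
#' @return a `neighbor_index`: list of integer vectors (indices into
#'   `complex$residues`), one per residue, with attributes `d_N` and
#'   `surface`.
#' @export
build_neighbor_index <- function(complex, d_N = 3.0, same_chain_only = FALSE) {
  res <- complex$residues
  n <- length(res)
  surf <- vapply(res, function(r) {
    if (is.na(r$is_surface)) stop("surface labels required; run label_surface")
    r$is_surface
  }, logical(1L))
  nbrs <- rep(list(integer(0)), n)
  if (n >= 2L) {
    idx <- which(surf)
    # centroid + radius prefilter before the all-pairs atom scan
    cent <- t(vapply(idx, function(i) colMeans(heavy_xyz(res[[i]])),
                     numeric(3L)))
    rad <- vapply(seq_along(idx), function(k) {
      sqrt(max(rowSums(sweep(heavy_xyz(res[[idx[k]]]), 2, cent[k, ])^2)))
    }, numeric(1L))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (same_chain_only && res[[i]]$chain_id != res[[j]]$chain_id) next
        gap <- sqrt(sum((cent[a, ] - cent[b, ])^2)) - rad[a] - rad[b]
        if (gap > d_N) next
        if (residue_min_distance(res[[i]], res[[j]]) <= d_N) {
          nbrs[[i]] <- c(nbrs[[i]], j)
          nbrs[[j]] <- c(nbrs[[j]], i)
        }
      }
    }
  }
  structure(lapply(nbrs, sort), d_N = d_N, surface = surf,
            class = "neighbor_index")
}

# Neighbors of a residue that are eligible for patch construction
# (complete shape descriptor), ordered by chain then residue number.
eligible_neighbors <- function(complex, index, center_idx) {
  nb <- index[[center_idx]]
  nb <- nb[vapply(nb, function(j) {
    !is.null(complex$residues[[j]]$shape_points)
  }, logical(1L))]
  if (length(nb) == 0L) return(integer(0))
  ord <- order(vapply(nb, function(j) complex$residues[[j]]$chain_id,
                      character(1L)),
               vapply(nb, function(j) complex$residues[[j]]$resno,
                      numeric(1L)),
               vapply(nb, function(j) complex$residues[[j]]$seq_index,
                      character(1L)))
  nb[ord]
}

patch_origin <- function(complex, center, members) {
  list(source_id = complex$source_id,
       chain = complex$residues[[center]]$chain_id,
       center = complex$residues[[center]]$seq_index,
       residues = vapply(members, function(j) {
         paste0(complex$residues[[j]]$chain_id, ":",
                complex$residues[[j]]$seq_index)
       }, character(1L)))
}

#' Enumerate the patches around a residue
#'
#' With k eligible surface neighbors: k = 0 gives no patches (an isolated
#' residue is not considered part of an interaction surface); k = 1 gives
#' one 2-aa patch (center plus its neighbor); k >= 2 gives choose(k, 2)
#' 3-aa patches (center plus each unordered neighbor pair). Residue order
#' within a patch is canonical -- center first, then neighbors by
#' ascending residue number -- which cannot affect distances because
#' structural similarity minimizes over residue orders.
#'
#' @param complex a `complex_model`.
#' @param center_idx index of the center residue in `complex$residues`.
#' @param index a `neighbor_index` from [build_neighbor_index()].
#' @return list of `patch` objects (possibly empty).
#' @export
build_patches <- function(complex, center_idx, index) {
  center <- complex$residues[[center_idx]]
  if (is.null(center$shape_points)) return(list())
  nb <- eligible_neighbors(complex, index, center_idx)
  k <- length(nb)
  if (k == 0L) return(list())
  if (k == 1L) {
    members <- c(center_idx, nb)
    return(list(new_patch(residues = complex$residues[members],
                          origin = patch_origin(complex, center_idx, members))))
  }
  pairs <- combn(nb, 2L, simplify = FALSE)
  lapply(pairs, function(pr) {
    members <- c(center_idx, pr)
    new_patch(residues = complex$residues[members],
              origin = patch_origin(complex, center_idx, members))
  })
}

#' Extract template patches from a training set
#'
#' Template (positive) patches are all patches constructed around surface
#' residues known to bind RNA, pooled over the training complexes and
#' split by size class. No deduplication is applied: repeated geometries
#' carry weight in clustering exactly as often as they occur.
#'
#' @param training_complexes list of annotated `complex_model`s (surface
#'   and binding labels assigned).
#' @param d_N neighbor distance cutoff in Angstrom.
#' @param same_chain_only passed to [build_neighbor_index()].
#' @return list with `templates_3aa` and `templates_2aa` (lists of
#'   `patch`).
#' @export
extract_templates <- function(training_complexes, d_N = 3.0,
                              same_chain_only = FALSE) {
  t3 <- list(); t2 <- list()
  for (cx in training_complexes) {
    index <- build_neighbor_index(cx, d_N = d_N,
                                  same_chain_only = same_chain_only)
    for (i in seq_along(cx$residues)) {
      r <- cx$residues[[i]]
      if (is.na(r$is_surface) || is.na(r$is_binding)) {
        stop("surface and binding labels required before template extraction")
      }
      if (!r$is_surface || !r$is_binding || is.null(r$shape_points)) next
      for (p in build_patches(cx, i, index)) {
        p$is_template <- TRUE
        if (p$m == 3L) t3[[length(t3) + 1L]] <- p else
          t2[[length(t2) + 1L]] <- p
      }
    }
  }
  list(templates_3aa = t3, templates_2aa = t2)
}
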