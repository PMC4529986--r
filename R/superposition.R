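#' Construct a surface patch
#'
#' A patch is the rigid point set formed by the five-point shape
#' descriptors of two or three residues (residue-major point order:
#' N, CA, C, O, side-chain center for each residue in turn).
#'
#' @param residues list of residue models (length 2 or 3), each with a
#'   complete shape descriptor; alternatively `coords` may be supplied
#'   directly.
#' @param coords optional (5m) x 3 coordinate matrix (residue-major).
#' @param aa amino-acid one-letter codes of the member residues.
#' @param origin provenance list (source_id, chain, center seq index,
#'   member seq indices).
#' @param is_template whether the patch was extracted around a known
#'   binding residue.
#' @return an object of class `patch` with fields `m` (2 or 3), `n` (5),
#'   `coords`, `aa`, `origin`, `is_template`.
#' @export
new_patch <- function(residues = NULL, coords = NULL, aa = NULL,
                      origin = list(), is_template = FALSE) {
  if (is.null(coords)) {
    stopifnot(length(residues) %in% c(2L, 3L))
    sp <- lapply(residues, function(r) {
      if (is.null(r$shape_points)) {
        stop("residue ", r$chain_id, ":", r$seq_index,
             " has no shape descriptor")
      }
      r$shape_points
    })
    coords <- do.call(rbind, sp)
    if (is.null(aa)) aa <- vapply(residues, function(r) r$aa, character(1L))
  }
  coords <- unname(as.matrix(coords))
  m <- nrow(coords) / 5L
  if (!m %in% c(2, 3) || nrow(coords) %% 5L != 0L) {
    stop("patch must contain 2 or 3 residues of 5 points each")
  }
  if (!all(is.finite(coords))) stop("patch coordinates must be finite")
  structure(list(m = as.integer(m), n = 5L, coords = coords,
                 aa = aa, origin = origin, is_template = is_template),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch: %d residues (%s)%s>\n", x$m,
              paste(x$aa, collapse = ""),
              if (isTRUE(x$is_template)) ", template" else ""))
  invisible(x)
}

check_same_m <- function(X, Y) {
  stopifnot(inherits(X, "patch"), inherits(Y, "patch"))
  if (X$m != Y$m) {
    stop("patch size mismatch: ", X$m, "-aa vs ", Y$m, "-aa")
  }
}

#' Least-squares distance between two equal-size patches
#'
#' The root of the minimized sum of squared point deviations between the
#' two point sets under the optimal proper rotation and translation, scale
#' fixed to 1. The rotation comes from the SVD of the cross-covariance of
#' the centered point sets, with the standard determinant correction so
#' that mirror superpositions are never produced. Point correspondence is
#' positional (i-th residue to i-th residue, j-th point to j-th point).
#'
#' @param X,Y patches with the same number of residues.
#' @return a `superposition_result`: list with `d_ls` (Angstrom),
#'   `rotation` (3x3, det +1), `translation`, `scale` (always 1).
#' @export
least_squares_distance <- function(X, Y) {
  check_same_m(X, Y)
  .perf$n_dls <- .perf$n_dls + 1L
  out <- cpp_ls_distance(X$coords, Y$coords)
  out$translation <- as.numeric(out$translation)
  class(out) <- "superposition_result"
  out
}

# permutations in lexicographic order (m = 2 or 3)
residue_permutations <- function(m) {
  if (m == 2L) {
    list(c(1L, 2L), c(2L, 1L))
  } else {
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  }
}

permute_patch <- function(X, perm) {
  idx <- unlist(lapply(perm, function(i) (i - 1L) * X$n + seq_len(X$n)))
  X$coords <- X$coords[idx, , drop = FALSE]
  X$aa <- X$aa[perm]
  X
}

#' Structural similarity between two patches
#'
#' The minimum least-squares distance over all residue-order
#' correspondences of `X` against `Y` (6 for 3-aa patches, 2 for 2-aa;
#' within-residue point order stays fixed). The first permutation in
#' lexicographic enumeration order wins on exact ties.
#'
#' @param X,Y patches with the same number of residues.
#' @return list with `d_ss` (Angstrom), `best_permutation` (indices into
#'   the residues of `X`) and `n_evaluated`.
#' @export
structural_similarity <- function(X, Y) {
  check_same_m(X, Y)
  perms <- residue_permutations(X$m)
  best <- Inf; best_perm <- perms[[1L]]
  for (p in perms) {
    d <- least_squares_distance(permute_patch(X, p), Y)$d_ls
    if (d < best) {
      best <- d
      best_perm <- p
    }
  }
  list(d_ss = best, best_permutation = best_perm,
       n_evaluated = length(perms))
}

# Fast d_SS (permutation loop in compiled code); equals
# structural_similarity()$d_ss -- asserted by tests.
dss <- function(X, Y) {
  check_same_m(X, Y)
  cpp_dss(X$coords, Y$coords, X$m, X$n)$d_ss
}

# Patch JSON serialization --------------------------------------------------

#' Write patches to JSON
#'
#' Serializes provenance, amino-acid types and the m x 5 x 3 coordinate
#' array at fixed 4-decimal precision; [read_patches()] round-trips the
#' file bit-stably at that precision.
#'
#' @param patches list of `patch` objects.
#' @param file output path.
#' @export
write_patches <- function(patches, file) {
  recs <- lapply(patches, function(p) {
    list(m = p$m, aa = p$aa, origin = p$origin,
         is_template = isTRUE(p$is_template),
         coords = round(unname(p$coords), 4))
  })
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read patches from JSON
#'
#' @param file path written by [write_patches()].
#' @return list of `patch` objects.
#' @export
read_patches <- function(file) {
  recs <- jsonlite::read_json(file, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    coords <- if (is.matrix(r$coords)) r$coords else
      do.call(rbind, lapply(r$coords, unlist))
    new_patch(coords = coords, aa = unlist(r$aa), origin = r$origin,
              is_template = isTRUE(r$is_template))
  })
}
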