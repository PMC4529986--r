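#' Subsample template patches
#'
#' Uniform sample without replacement of at most `n_max` patches,
#' deterministic for a fixed seed. Used to keep the pairwise distance
#' matrix of the 3-aa template pool tractable; 2-aa pools are small and
#' are never subsampled by the pipeline.
#'
#' @param templates list of `patch` objects.
#' @param n_max maximum number retained (default 10000).
#' @param seed integer seed.
#' @return list of `patch` objects.
#' @export
subsample_templates <- function(templates, n_max = 10000, seed = 1) {
  n <- length(templates)
  if (n <= n_max) return(templates)
  keep <- with_seed(seed, sample.int(n, n_max))
  templates[sort(keep)]
}

#' Pairwise structural-similarity matrix
#'
#' Materializes d_SS over all unordered pairs of a patch set (each pair
#' computed once; the matrix is symmetric with a zero diagonal).
#'
#' @param patches list of `patch` objects, all of the same size class.
#' @return a symmetric matrix of distances in Angstrom.
#' @export
pairwise_distances <- function(patches) {
  stopifnot(length(patches) >= 1L)
  m <- unique(vapply(patches, function(p) p$m, integer(1L)))
  if (length(m) != 1L) {
    stop("mixed patch size classes in pairwise_distances")
  }
  D <- cpp_dss_matrix(lapply(patches, function(p) p$coords), m, 5L)
  dimnames(D) <- list(seq_along(patches), seq_along(patches))
  D
}

#' Complete-linkage hierarchical clustering of patches
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the maximum pairwise member distance; the dendrogram is cut to exactly
#' `n_clusters` flat clusters. Single and average linkage are available
#' for comparison (they tend to produce ladder-shaped dendrograms on
#' template patches and are not used by the pipeline).
#'
#' @param dist symmetric distance matrix (from [pairwise_distances()]).
#' @param n_clusters number of flat clusters.
#' @param linkage one of "complete", "single", "average".
#' @return integer vector of cluster labels (1..n_clusters).
#' @export
cluster_complete_linkage <- function(dist, n_clusters,
                                     linkage = c("complete", "single",
                                                 "average")) {
  linkage <- match.arg(linkage)
  n <- nrow(dist)
  if (n_clusters > n) {
    stop("n_clusters (", n_clusters, ") exceeds number of patches (", n, ")")
  }
  if (n_clusters == n) return(seq_len(n))
  hc <- hclust(as.dist(dist), method = linkage)
  unname(cutree(hc, k = n_clusters))
}

#' Medoid of a patch cluster
#'
#' The cluster member with the smallest sum of squared distances to the
#' other members (ties go to the lowest member index). The representative
#' is always an actual member; shapes are never averaged.
#'
#' @param member_ids indices of the cluster members (into the rows of
#'   `dist`).
#' @param dist full pairwise distance matrix.
#' @return the index (from `member_ids`) of the medoid.
#' @export
select_centroid <- function(member_ids, dist) {
  if (length(member_ids) == 0L) stop("empty cluster in select_centroid")
  if (length(member_ids) == 1L) return(member_ids)
  sub <- dist[member_ids, member_ids, drop = FALSE]
  ss <- rowSums(sub^2)
  member_ids[which.min(ss)]
}

#' Build the representative patch set
#'
#' Subsamples the 3-aa template pool, clusters each size class with
#' complete linkage under d_SS, and selects the medoid of every cluster.
#' Representatives are assembled in a fixed order: the `n3` 3-aa
#' representatives first, then the `n2` 2-aa representatives, giving the
#' L = n3 + n2 axes of the structural feature space.
#'
#' @param templates_3aa,templates_2aa template patch lists.
#' @param n3,n2 cluster counts per size class (defaults 40 and 20).
#' @param n_max 3-aa subsample cap (default 10000).
#' @param seed subsampling seed.
#' @param linkage linkage passed to [cluster_complete_linkage()].
#' @return an object of class `representative_set`: list with `reps_3aa`,
#'   `reps_2aa`, `L`.
#' @export
build_representative_set <- function(templates_3aa, templates_2aa,
                                     n3 = 40, n2 = 20, n_max = 10000,
                                     seed = 1, linkage = "complete") {
  if (length(templates_3aa) < n3) {
    stop("too few 3-aa templates (", length(templates_3aa),
         ") for n3 = ", n3)
  }
  if (length(templates_2aa) < n2) {
    stop("too few 2-aa templates (", length(templates_2aa),
         ") for n2 = ", n2)
  }
  reps_for <- function(templates, k) {
    D <- pairwise_distances(templates)
    cl <- cluster_complete_linkage(D, k, linkage = linkage)
    lapply(seq_len(k), function(g) {
      templates[[select_centroid(which(cl == g), D)]]
    })
  }
  t3 <- subsample_templates(templates_3aa, n_max = n_max, seed = seed)
  structure(list(reps_3aa = reps_for(t3, n3),
                 reps_2aa = reps_for(templates_2aa, n2),
                 L = n3 + n2),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("<representative_set: %d 3-aa + %d 2-aa = L %d>\n",
              length(x$reps_3aa), length(x$reps_2aa), x$L))
  invisible(x)
}

#' Write / read a representative set (JSON)
#'
#' The serialized representative set is the model artifact consumed by
#' the feature stage; ordering is preserved.
#'
#' @param reps a `representative_set`.
#' @param file path.
#' @export
write_representative_set <- function(reps, file) {
  tmp3 <- tempfile(fileext = ".json"); tmp2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp3, tmp2)), add = TRUE)
  write_patches(reps$reps_3aa, tmp3)
  write_patches(reps$reps_2aa, tmp2)
  jsonlite::write_json(
    list(L = reps$L,
         reps_3aa = jsonlite::read_json(tmp3),
         reps_2aa = jsonlite::read_json(tmp2)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_representative_set
#' @export
read_representative_set <- function(file) {
  obj <- jsonlite::read_json(file)
  unpack <- function(recs) {
    lapply(recs, function(r) {
      new_patch(coords = do.call(rbind, lapply(r$coords, unlist)),
                aa = unlist(r$aa), origin = r$origin,
                is_template = isTRUE(r$is_template))
    })
  }
  structure(list(reps_3aa = unpack(obj$reps_3aa),
                 reps_2aa = unpack(obj$reps_2aa),
                 L = obj$L),
            class = "representative_set")
}
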