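#' Load a protein-RNA complex from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only) of the requested chains
#' into a per-residue structure model. Standard amino-acid residues of the
#' protein chains become residue models carrying the five-point shape
#' descriptor (backbone N, CA, C, O plus the side-chain center); residues
#' of the RNA chains contribute their atoms to the nucleotide atom set used
#' by the 5 A binding rule. Alternate locations are resolved to the highest
#' occupancy (first record on ties); nonstandard amino acids are skipped
#' with a message. Residues with an incomplete backbone are retained but
#' flagged ineligible for patch construction.
#'
#' @param pdb path to a PDB file, or a character vector/string of PDB text.
#' @param protein_chains chain identifiers to parse as protein.
#' @param rna_chains chain identifiers whose residues are treated as RNA
#'   nucleotides (may be empty for an apo protein).
#' @param source_id identifier stored with the model (defaults to the file
#'   name).
#' @return an object of class `complex_model`: a list with `residues` (list
#'   of residue models), `nucleotide_atoms` (data.frame) and `source_id`.
#' @export
load_complex <- function(pdb, protein_chains, rna_chains = character(),
                         source_id = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1L]], path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(source_id)) {
    source_id <- tools::file_path_sans_ext(basename(path))
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB input: ", conditionMessage(e)))
  atoms <- parsed$atom
  known <- unique(atoms$chain)
  missing <- setdiff(c(protein_chains, rna_chains), known)
  if (length(missing) > 0L) {
    stop("chain id(s) not present in PDB: ", paste(missing, collapse = ", "))
  }

  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$element <- guess_element(atoms)

  residues <- list()
  for (ch in protein_chains) {
    ca <- atoms[atoms$chain == ch & atoms$type %in% c("ATOM", "HETATM"), ,
                drop = FALSE]
    if (nrow(ca) == 0L) next
    key <- paste(ca$resno, ca$insert, sep = "|")
    for (k in unique(key)) {
      ra <- ca[key == k, , drop = FALSE]
      resid <- ra$resid[1L]
      if (!resid %in% names(AA3)) {
        if (!resid %in% c("HOH", "WAT")) {
          message("skipping nonstandard residue ", resid, " ", ch, ":",
                  ra$resno[1L])
        }
        next
      }
      ra <- resolve_altloc(ra)
      residues[[length(residues) + 1L]] <- new_residue(ra, ch)
    }
  }

  nuc <- atoms[atoms$chain %in% rna_chains & !atoms$resid %in% c("HOH", "WAT"),
               , drop = FALSE]
  nuc <- if (nrow(nuc) > 0L) {
    key <- paste(nuc$resno, nuc$insert, nuc$elety, sep = "|")
    nuc <- do.call(rbind, lapply(split(nuc, paste(nuc$resno, nuc$insert)),
                                 resolve_altloc))
    data.frame(name = nuc$elety, element = nuc$element,
               x = nuc$x, y = nuc$y, z = nuc$z, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), element = character(),
               x = numeric(), y = numeric(), z = numeric())
  }

  structure(list(residues = residues, nucleotide_atoms = nuc,
                 source_id = source_id,
                 protein_chains = protein_chains, rna_chains = rna_chains),
            class = "complex_model")
}

# Infer element symbols: trust the element column when present, otherwise
# strip digits/primes from the atom name and take the leading letter(s).
guess_element <- function(atoms) {
  el <- atoms$elesy
  fallback <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1",
                          gsub("[0-9']", "", atoms$elety)))
  bad <- is.na(el) | el == ""
  el[bad] <- fallback[bad]
  toupper(trimws(el))
}

# Keep the highest-occupancy alternate location per atom name
# (first record on ties).
resolve_altloc <- function(ra) {
  if (all(ra$alt == "")) return(ra)
  keep <- unlist(lapply(split(seq_len(nrow(ra)), ra$elety), function(idx) {
    idx[order(-ra$o[idx])][1L]
  }))
  ra[sort(keep), , drop = FALSE]
}

new_residue <- function(ra, chain) {
  atoms <- data.frame(name = ra$elety, element = ra$element,
                      x = ra$x, y = ra$y, z = ra$z, stringsAsFactors = FALSE)
  atoms$is_heavy <- !atoms$element %in% c("H", "D")
  res <- structure(list(
    chain_id = chain,
    resno = ra$resno[1L],
    seq_index = paste0(ra$resno[1L], ra$insert[1L]),
    aa3 = ra$resid[1L],
    aa = unname(AA3[[ra$resid[1L]]]),
    atoms = atoms,
    shape_points = NULL,
    sasa = NA_real_,
    is_surface = NA,
    is_binding = NA), class = "residue_model")
  res$shape_points <- tryCatch(shape_points(res), error = function(e) NULL)
  res
}

atom_xyz <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(residue$atoms[i, c("x", "y", "z")])
}

heavy_xyz <- function(residue) {
  a <- residue$atoms[residue$atoms$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Ordered 5-point shape descriptor: N, CA, C, O, side-chain center.
shape_points <- function(residue) {
  pts <- lapply(BACKBONE_ATOMS, atom_xyz, residue = residue)
  if (any(vapply(pts, is.null, logical(1L)))) {
    stop("incomplete backbone for residue ", residue$chain_id, ":",
         residue$seq_index)
  }
  m <- rbind(do.call(rbind, pts), side_chain_center(residue))
  rownames(m) <- c(BACKBONE_ATOMS, "SC")
  m
}

#' Side-chain center of a residue
#'
#' The unweighted mean of all heavy side-chain atoms (everything except the
#' backbone N, CA, C, O and terminal OXT). Glycine has no heavy side-chain
#' atom: its alpha hydrogen (HA/HA2/HA3, first found) is used when present
#' in the file; otherwise an idealized HA is constructed 1.09 A from CA
#' along the direction completing tetrahedral geometry given N, CA and C.
#' A non-glycine residue with no side-chain heavy atoms falls back to CA
#' with a warning.
#'
#' @param residue a residue model with a complete backbone.
#' @return a 3-vector (Angstrom).
#' @export
side_chain_center <- function(residue) {
  if (residue$aa3 == "GLY") {
    for (h in c("HA", "HA2", "HA3")) {
      p <- atom_xyz(residue, h)
      if (!is.null(p)) return(p)
    }
    return(idealized_ha(residue))
  }
  sc <- residue$atoms[residue$atoms$is_heavy &
                        !residue$atoms$name %in% c(BACKBONE_ATOMS, "OXT"), ,
                      drop = FALSE]
  if (nrow(sc) == 0L) {
    warning("residue ", residue$chain_id, ":", residue$seq_index, " (",
            residue$aa3, ") has no side-chain heavy atoms; using CA")
    return(atom_xyz(residue, "CA"))
  }
  unname(colMeans(as.matrix(sc[, c("x", "y", "z")])))
}

# Idealized alpha-hydrogen position: 1.09 A from CA, completing the
# tetrahedron spanned by the N-CA and C-CA bonds.
idealized_ha <- function(residue) {
  n <- atom_xyz(residue, "N"); ca <- atom_xyz(residue, "CA")
  cc <- atom_xyz(residue, "C")
  v1 <- unit(n - ca); v2 <- unit(cc - ca)
  if (sqrt(sum((v1 + v2)^2)) < 1e-6 || sqrt(sum(cross3(v1, v2)^2)) < 1e-6) {
    stop("degenerate backbone geometry (collinear N, CA, C) for glycine ",
         "HA construction")
  }
  bis <- unit(v1 + v2)
  perp <- unit(cross3(v1, v2))
  # remaining tetrahedral directions d satisfy d.v1 = d.v2 = cos(109.47 deg)
  cb <- sum(bis * v1)
  a <- (-1 / 3) / cb
  a <- max(min(a, 1), -1)
  b <- sqrt(max(0, 1 - a^2))
  ca + 1.09 * (a * bis + b * perp)
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley accessible area over the protein heavy atoms only (RNA
#' atoms do not occlude, so surface status reflects the protein alone),
#' with a deterministic sphere point set. Atoms are first rotated into a
#' PCA-based canonical frame so that areas are independent of the input
#' pose: rigidly moved copies of a complex yield identical areas.
#'
#' @param complex a `complex_model`.
#' @param probe_radius probe radius in Angstrom (water = 1.4).
#' @param n_sphere_points number of test points per atom.
#' @return the complex with per-residue `sasa` filled in (Angstrom^2).
#' @export
compute_sasa <- function(complex, probe_radius = 1.4, n_sphere_points = 960) {
  res <- complex$residues
  if (length(res) == 0L) return(complex)
  coords <- list(); radii <- list(); owner <- list()
  for (i in seq_along(res)) {
    xyz <- heavy_xyz(res[[i]])
    if (nrow(xyz) == 0L) next
    el <- res[[i]]$atoms$element[res[[i]]$atoms$is_heavy]
    r <- VDW_RADII[el]
    r[is.na(r)] <- VDW_DEFAULT
    coords[[length(coords) + 1L]] <- xyz
    radii[[length(radii) + 1L]] <- unname(r)
    owner[[length(owner) + 1L]] <- rep(i, nrow(xyz))
  }
  xyz <- do.call(rbind, coords)
  areas <- shrake_rupley(xyz, unlist(radii), probe = probe_radius,
                         n_points = n_sphere_points)
  per_res <- tapply(areas, unlist(owner), sum)
  for (i in seq_along(res)) res[[i]]$sasa <- 0
  for (k in names(per_res)) res[[as.integer(k)]]$sasa <- unname(per_res[[k]])
  complex$residues <- res
  complex
}

#' Label surface residues
#'
#' A residue is a surface residue iff its accessible area is strictly
#' greater than zero.
#'
#' @param complex a `complex_model` on which [compute_sasa()] has run.
#' @return the complex with `is_surface` set on every residue.
#' @export
label_surface <- function(complex) {
  complex$residues <- lapply(complex$residues, function(r) {
    if (is.na(r$sasa)) stop("compute_sasa must run before label_surface")
    r$is_surface <- r$sasa > 0
    r
  })
  complex
}

#' Label RNA-binding residues by the distance rule
#'
#' A residue is RNA-binding iff any of its atoms lies within `cutoff`
#' Angstrom (inclusive) of any nucleotide atom. Apo complexes (no
#' nucleotide atoms) label every residue non-binding.
#'
#' @param complex a `complex_model`.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return the complex with `is_binding` set on every residue.
#' @export
label_binding <- function(complex, cutoff = 5.0) {
  nuc <- complex$nucleotide_atoms
  nxyz <- as.matrix(nuc[, c("x", "y", "z"), drop = FALSE])
  complex$residues <- lapply(complex$residues, function(r) {
    if (nrow(nxyz) == 0L) {
      r$is_binding <- FALSE
      return(r)
    }
    axyz <- as.matrix(r$atoms[, c("x", "y", "z")])
    d2 <- min(cross_dist2(axyz, nxyz))
    r$is_binding <- sqrt(d2) <= cutoff
    r
  })
  complex
}

# Squared Euclidean cross-distance matrix between two n x 3 sets.
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Residue annotation table
#'
#' @param complex an annotated `complex_model`.
#' @param file optional path; when given the table is written as TSV.
#' @return a data.frame with chain, residue number, amino acid, SASA and
#'   the surface/binding labels.
#' @export
annotation_table <- function(complex, file = NULL) {
  df <- do.call(rbind, lapply(complex$residues, function(r) {
    data.frame(source_id = complex$source_id, chain_id = r$chain_id,
               seq_index = r$seq_index, aa_type = r$aa, sasa = r$sasa,
               is_surface = r$is_surface, is_binding = r$is_binding,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

# Apply a global rigid motion to every coordinate of a complex
# (protein atoms, shape points, nucleotide atoms). Used by invariance tests.
#' @export
transform_complex <- function(complex, rotation, translation = c(0, 0, 0)) {
  complex$residues <- lapply(complex$residues, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")])
    r$atoms[, c("x", "y", "z")] <- apply_rigid(xyz, rotation, translation)
    if (!is.null(r$shape_points)) {
      r$shape_points <- apply_rigid(r$shape_points, rotation, translation)
    }
    r
  })
  if (nrow(complex$nucleotide_atoms) > 0L) {
    nxyz <- as.matrix(complex$nucleotide_atoms[, c("x", "y", "z")])
    complex$nucleotide_atoms[, c("x", "y", "z")] <-
      apply_rigid(nxyz, rotation, translation)
  }
  complex
}
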