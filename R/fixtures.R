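# Synthetic desk-scale fixtures: toy protein-RNA complexes with known
# binding labels and planted surface-patch geometries, plus pseudo-PSSMs.
# Side chains are idealized (coordinates drive all downstream math, so
# chemical realism is not required); RNA nucleotides are minimal 4-atom
# pseudo-residues placed so the 5 A rule reproduces the intended labels.

#' Fixture specification
#'
#' @param n_proteins number of toy complexes.
#' @param residues_per_protein chain length of each toy protein.
#' @param motif planted 3-aa geometry around interior binding residues:
#'   `"linear"` (three alpha-carbons collinear at 5 A spacing) or
#'   `"fork"` (two 5 A arms 60 degrees apart around a stem).
#' @param jitter_sigma root-mean-square 3D displacement (A) applied to
#'   each planted residue position.
#' @param contact_fraction fraction of residues given an RNA nucleotide
#'   within 5 A (chain termini are always contacts, so every toy protein
#'   also yields 2-aa template patches).
#' @param seed master seed; all per-protein randomness derives from it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 24, residues_per_protein = 40,
                         motif = c("linear", "fork"), jitter_sigma = 0.2,
                         contact_fraction = 0.25, seed = 1) {
  motif <- match.arg(motif)
  stopifnot(n_proteins >= 1, residues_per_protein >= 6,
            jitter_sigma >= 0, contact_fraction >= 0, contact_fraction <= 1)
  structure(list(n_proteins = n_proteins,
                 residues_per_protein = residues_per_protein,
                 motif = motif, jitter_sigma = jitter_sigma,
                 contact_fraction = contact_fraction, seed = seed),
            class = "fixture_spec")
}

# arc geometry constants (Angstrom)
FIX_SPACING <- 5.0   # CA-CA spacing along the chain
FIX_RADIUS <- 60.0   # arc radius; gentle curvature keeps the chain open
FIX_TIP <- 6.0       # side-chain tip extension of contact residues
FIX_RNA <- 3.0       # nearest RNA atom distance from the contact tip
FIX_FREE_JITTER <- 1.2  # RMS displacement of unconstrained residues

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# choose interior contact positions with pairwise sequence gap >= 3
pick_interior_contacts <- function(n, n_needed) {
  if (n_needed == 0L) return(integer(0))
  cand <- sample(3:(n - 2L))
  chosen <- integer(0)
  for (c in cand) {
    if (all(abs(c - chosen) >= 3L)) chosen <- c(chosen, c)
    if (length(chosen) == n_needed) break
  }
  if (length(chosen) < n_needed) {
    stop("infeasible packing: cannot place ", n_needed,
         " interior contacts with gap >= 3 in a chain of ", n)
  }
  sort(chosen)
}

#' Generate one toy protein-RNA complex
#'
#' Emits parseable PDB text for a single protein chain (A) laid out along
#' a gentle arc with idealized backbone geometry, a single-atom-pair side
#' chain per residue, and an RNA chain (R) of minimal pseudo-nucleotides
#' placed exactly 3 A from each designated contact residue and at least
#' 8 A from every other residue (verified numerically; violations raise
#' an infeasible-packing error). Interior contact residues have their
#' (i-1, i, i+1) alpha-carbons arranged in the planted motif plus
#' Gaussian jitter; contact residues carry an extended side-chain tip
#' that reaches toward the RNA.
#'
#' @param spec a [fixture_spec()].
#' @param index protein index (drives the per-protein seed stream).
#' @return list with `pdb` (character lines), `truth` (data.frame of
#'   intended labels), `sequence`, `contacts` (residue numbers) and
#'   `interior_contacts`.
#' @export
make_toy_complex <- function(spec, index = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$residues_per_protein
  n_contacts <- max(2L, round(spec$contact_fraction * n))
  with_seed(child_seed(spec$seed, paste0("toy", index)), {
    interior <- pick_interior_contacts(n, n_contacts - 2L)
    contacts <- sort(unique(c(1L, n, interior)))

    # base alpha-carbon positions on the arc
    theta <- (seq_len(n) - 1L) * FIX_SPACING / FIX_RADIUS
    ca <- cbind(FIX_RADIUS * sin(theta), -FIX_RADIUS * cos(theta) + FIX_RADIUS,
                rep(0, n))
    outward <- cbind(sin(theta), -cos(theta), rep(0, n))
    tangent <- cbind(cos(theta), sin(theta), rep(0, n))

    # plant the motif around interior contacts
    for (c in interior) {
      t_c <- tangent[c, ]
      if (spec$motif == "linear") {
        ca[c - 1L, ] <- ca[c, ] - FIX_SPACING * t_c
        ca[c + 1L, ] <- ca[c, ] + FIX_SPACING * t_c
      } else {  # fork: two arms 60 degrees apart, bent away from the RNA
        ca[c - 1L, ] <- ca[c, ] - FIX_SPACING *
          as.numeric(rot_z(-30) %*% t_c)
        ca[c + 1L, ] <- ca[c, ] + FIX_SPACING *
          as.numeric(rot_z(30) %*% t_c)
      }
    }

    # local frames from the ideal (pre-jitter) trace, so that jitter acts
    # as a pure per-residue translation of an ideal-geometry residue
    ca0 <- ca
    prev_dir <- rbind(unit(ca0[1L, ] - ca0[2L, ]),
                      t(vapply(2:n, function(i) {
                        unit(ca0[i - 1L, ] - ca0[i, ])
                      }, numeric(3L))))
    next_dir <- rbind(t(vapply(seq_len(n - 1L), function(i) {
      unit(ca0[i + 1L, ] - ca0[i, ])
    }, numeric(3L))), unit(ca0[n, ] - ca0[n - 1L, ]))

    # jitter: planted residues (contacts and their flanks) get
    # jitter_sigma, free residues the larger default roughness
    planted <- sort(unique(c(contacts, interior - 1L, interior + 1L,
                             2L, n - 1L)))
    sig <- rep(FIX_FREE_JITTER, n)
    sig[planted] <- spec$jitter_sigma
    ca <- ca + matrix(rnorm(3 * n, 0, rep(sig, 3) / sqrt(3)), n, 3)

    # residue types: contacts biased to basic/polar residues
    aa <- character(n)
    free <- setdiff(seq_len(n), contacts)
    aa[contacts] <- sample(c("R", "K", "N", "H"), length(contacts),
                           replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    aa[free] <- sample(setdiff(AA1, "G"), length(free), replace = TRUE)

    atoms <- list()
    add_atom <- function(name, element, resno, resid, chain, xyz) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        name = name, element = element, resno = resno, resid = resid,
        chain = chain, x = xyz[1L], y = xyz[2L], z = xyz[3L],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)) {
      resid <- AA1TO3[[aa[i]]]
      np <- ca[i, ] + 1.45 * (if (i == 1L) -next_dir[1L, ] else prev_dir[i, ])
      cp <- ca[i, ] + 1.50 * (if (i == n) -prev_dir[n, ] else next_dir[i, ])
      axis <- if (i == n) -prev_dir[n, ] else next_dir[i, ]
      odir <- cross3(axis, outward[i, ])
      odir <- if (sqrt(sum(odir^2)) < 1e-6) c(0, 0, 1) else unit(odir)
      add_atom("N", "N", i, resid, "A", np)
      add_atom("CA", "C", i, resid, "A", ca[i, ])
      add_atom("C", "C", i, resid, "A", cp)
      add_atom("O", "O", i, resid, "A", cp + 1.23 * odir)
      add_atom("CB", "C", i, resid, "A", ca[i, ] + 1.53 * outward[i, ])
      if (i %in% contacts) {
        add_atom("CG", "C", i, resid, "A", ca[i, ] + FIX_TIP * outward[i, ])
      }
    }

    # minimal RNA pseudo-nucleotide per contact, outward of the tip
    zdir <- c(0, 0, 1)
    for (k in seq_along(contacts)) {
      c <- contacts[k]
      tip <- ca[c, ] + FIX_TIP * outward[c, ]
      p <- tip + FIX_RNA * outward[c, ]
      add_atom("P", "P", k, "U", "R", p)
      add_atom("O5'", "O", k, "U", "R", p + 0.8 * outward[c, ])
      add_atom("C1'", "C", k, "U", "R", p + 0.8 * outward[c, ] + 0.8 * zdir)
      add_atom("N9", "N", k, "U", "R", p + 1.6 * outward[c, ])
    }
    at <- do.call(rbind, atoms)

    # verify the placement contract: contacts within 5 A (exactly 3 by
    # construction), everything else no closer than 8 A to any RNA atom
    prot <- at[at$chain == "A", ]
    rna <- as.matrix(at[at$chain == "R", c("x", "y", "z")])
    mind <- vapply(seq_len(n), function(i) {
      axyz <- as.matrix(prot[prot$resno == i, c("x", "y", "z")])
      sqrt(min(cross_dist2(axyz, rna)))
    }, numeric(1L))
    if (any(mind[contacts] > 5)) {
      stop("infeasible packing: contact residue farther than 5 A from RNA")
    }
    if (any(mind[-contacts] < 8)) {
      stop("infeasible packing: non-contact residue within 8 A of RNA")
    }

    truth <- data.frame(chain_id = "A", seq_index = as.character(seq_len(n)),
                        aa = aa, is_surface = TRUE,
                        is_binding = seq_len(n) %in% contacts,
                        stringsAsFactors = FALSE)
    list(pdb = format_pdb(at), truth = truth,
         sequence = paste(aa, collapse = ""),
         contacts = contacts, interior_contacts = interior)
  })
}

# fixed-width PDB ATOM records (+TER/END)
format_pdb <- function(at) {
  lines <- vapply(seq_len(nrow(at)), function(i) {
    name <- at$name[i]
    name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_fmt, at$resid[i], at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i], 1.0, 0.0, at$element[i])
  }, character(1L))
  c(lines, "TER", "END")
}

#' Generate a self-contained benchmark
#'
#' Writes `n_proteins` toy complexes (PDB), their pseudo-PSSMs, per-protein
#' truth tables (TSV) and a JSON manifest to `dir`. Bit-reproducible for a
#' fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return the manifest (list), invisibly; `<dir>/manifest.json` on disk.
#' @export
make_benchmark <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_len(spec$n_proteins)) {
    toy <- make_toy_complex(spec, i)
    id <- sprintf("toy%02d", i)
    pdb_file <- file.path(dir, paste0(id, ".pdb"))
    pssm_file <- file.path(dir, paste0(id, "_A.pssm"))
    truth_file <- file.path(dir, paste0(id, "_truth.tsv"))
    writeLines(toy$pdb, pdb_file)
    make_pseudo_pssm(toy$sequence, seed = child_seed(spec$seed,
                                                     paste0("pssm", i)),
                     file = pssm_file)
    write.table(toy$truth, truth_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    entries[[i]] <- list(id = id, pdb = basename(pdb_file),
                         protein_chains = "A", rna_chains = "R",
                         pssms = list(A = basename(pssm_file)),
                         truth = basename(truth_file),
                         sequence = toy$sequence)
  }
  manifest <- list(spec = unclass(spec), proteins = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a benchmark written by [make_benchmark()]
#'
#' Reads every complex through the public PDB/PSSM readers and returns
#' them unannotated (see [annotate_complex()]).
#'
#' @param dir directory containing `manifest.json`.
#' @return list with `complexes`, `pssms` (keyed `"<id>|<chain>"`),
#'   `truth` (named list of data.frames), `manifest`.
#' @export
load_benchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  complexes <- list(); pssms <- list(); truth <- list()
  for (e in manifest$proteins) {
    cx <- load_complex(file.path(dir, e$pdb),
                       protein_chains = unlist(e$protein_chains),
                       rna_chains = unlist(e$rna_chains),
                       source_id = e$id)
    complexes[[e$id]] <- cx
    for (ch in names(e$pssms)) {
      pssms[[paste(e$id, ch, sep = "|")]] <-
        load_pssm(file.path(dir, e$pssms[[ch]]),
                  expected_sequence = e$sequence)
    }
    truth[[e$id]] <- read.table(file.path(dir, e$truth), sep = "\t",
                                header = TRUE, colClasses = c(
                                  seq_index = "character"))
  }
  list(complexes = complexes, pssms = pssms, truth = truth,
       manifest = manifest)
}

#' Annotate a complex (SASA, surface and binding labels)
#'
#' @param complex a `complex_model`.
#' @param probe_radius probe radius (A).
#' @param n_sphere_points SASA test points per atom.
#' @param cutoff binding distance cutoff (A).
#' @return the annotated complex.
#' @export
annotate_complex <- function(complex, probe_radius = 1.4,
                             n_sphere_points = 960, cutoff = 5.0) {
  complex <- compute_sasa(complex, probe_radius = probe_radius,
                          n_sphere_points = n_sphere_points)
  complex <- label_surface(complex)
  label_binding(complex, cutoff = cutoff)
}
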