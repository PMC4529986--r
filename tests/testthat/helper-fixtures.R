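# Shared helpers: tiny hand-built PDB fragments, random patches, and a
# lazily built (cached) benchmark shared across test files.

with_seed <- patchbind:::with_seed

# minimal PDB ATOM line
pdb_atom <- function(serial, name, resid, chain, resno, xyz, element,
                     occ = 1, alt = " ") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

# one residue with standard-ish backbone geometry at an offset, plus the
# requested side-chain atoms (named list name -> xyz relative to offset)
residue_lines <- function(resno, resid, offset, side = list(CB = c(1.5, 1.1, 0)),
                          chain = "A", serial0 = 0, skip = character()) {
  base <- list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.5, 0, 0),
               O = c(1.9, 1.15, 0))
  base <- base[setdiff(names(base), skip)]
  atoms <- c(base, side)
  lines <- character(0)
  for (i in seq_along(atoms)) {
    el <- substr(gsub("[0-9']", "", names(atoms)[i]), 1, 1)
    lines <- c(lines, pdb_atom(serial0 + i, names(atoms)[i], resid, chain,
                               resno, offset + atoms[[i]], el))
  }
  lines
}

# a straight synthetic chain: residues spaced `spacing` apart along x
chain_pdb <- function(n, spacing = 3.8, resid = "ALA", chain = "A") {
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, residue_lines(i, resid, c((i - 1) * spacing, 0, 0),
                                    chain = chain, serial0 = (i - 1) * 5))
  }
  c(lines, "TER", "END")
}

# A star-shaped fixture: a central residue with k neighbors placed on a
# circle within d_N, all others far away. Distances are controlled by
# construction and double-checked by the brute-force all-pairs oracle.
star_complex <- function(k, radius = 2.5, n_far = 2) {
  lines <- character(0)
  serial <- 0
  lines <- c(lines, residue_lines(1, "ALA", c(0, 0, 0), serial0 = serial))
  serial <- serial + 5
  for (j in seq_len(k)) {
    ang <- 2 * pi * (j - 1) / max(k, 1)
    # neighbor CA on a circle `radius` from the center CA
    lines <- c(lines, residue_lines(1 + j, "ALA",
                                    radius * c(cos(ang), sin(ang), 0),
                                    serial0 = serial))
    serial <- serial + 5
  }
  for (j in seq_len(n_far)) {
    lines <- c(lines, residue_lines(1 + k + j, "ALA",
                                    c(50 + 10 * j, 0, 0), serial0 = serial))
    serial <- serial + 5
  }
  cx <- load_complex(c(lines, "TER", "END"), "A")
  annotate_complex(cx)
}

random_patch <- function(m = 3, seed = NULL, scale = 3) {
  gen <- function() {
    new_patch(coords = matrix(rnorm(m * 5 * 3, sd = scale), m * 5, 3),
              aa = sample(patchbind:::AA1, m))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# cached shared benchmark (default study conditions; built once per run)
.bench_cache <- new.env(parent = emptyenv())

shared_benchmark <- function() {
  if (is.null(.bench_cache$bench)) {
    dir <- file.path(tempdir(), "patchbind-benchmark")
    spec <- fixture_spec(n_proteins = 24, residues_per_protein = 40,
                         motif = "linear", jitter_sigma = 0.2,
                         contact_fraction = 0.25, seed = 2024)
    make_benchmark(spec, dir)
    bench <- load_benchmark(dir)
    bench$complexes <- lapply(bench$complexes, annotate_complex)
    bench$dir <- dir
    bench$spec <- spec
    .bench_cache$bench <- bench
  }
  .bench_cache$bench
}

# small annotated toy complex for cheap per-test use
small_toy <- function(seed = 7, n = 24, motif = "linear",
                      jitter_sigma = 0.2, index = 1) {
  spec <- fixture_spec(n_proteins = 1, residues_per_protein = n,
                       motif = motif, jitter_sigma = jitter_sigma,
                       seed = seed)
  toy <- make_toy_complex(spec, index)
  cx <- load_complex(toy$pdb, "A", "R", source_id = paste0("toy-", seed))
  list(toy = toy, complex = annotate_complex(cx))
}
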