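test_that("toy complex round-trips coordinates and atom counts", {
  spec <- fixture_spec(n_proteins = 1, residues_per_protein = 10, seed = 3)
  toy <- make_toy_complex(spec, 1)
  cx <- load_complex(toy$pdb, "A", "R")
  expect_length(cx$residues, 10)
  # coordinates round-trip exactly at PDB precision
  ca_line <- toy$pdb[grepl("^ATOM", toy$pdb) &
                       substr(toy$pdb, 13, 16) == " CA " &
                       substr(toy$pdb, 23, 26) == "   1"]
  from_file <- as.numeric(c(substr(ca_line, 31, 38), substr(ca_line, 39, 46),
                            substr(ca_line, 47, 54)))
  expect_equal(patchbind:::atom_xyz(cx$residues[[1]], "CA"), from_file)
  # RNA atom count equals what was written for chain R
  n_rna_lines <- sum(grepl("^ATOM", toy$pdb) & substr(toy$pdb, 22, 22) == "R")
  expect_equal(nrow(cx$nucleotide_atoms), n_rna_lines)
})

test_that("residues with incomplete backbone are kept but patch-ineligible", {
  lines <- c(residue_lines(1, "ALA", c(0, 0, 0)),
             residue_lines(2, "ALA", c(3.8, 0, 0), serial0 = 10,
                           skip = "O"),
             residue_lines(3, "ALA", c(7.6, 0, 0), serial0 = 20),
             "TER", "END")
  cx <- load_complex(lines, "A")
  expect_length(cx$residues, 3)
  expect_null(cx$residues[[2]]$shape_points)
  expect_false(is.null(cx$residues[[1]]$shape_points))
  expect_equal(rownames(cx$residues[[1]]$shape_points),
               c("N", "CA", "C", "O", "SC"))
})

test_that("unknown chains and unparseable text raise errors", {
  lines <- chain_pdb(2)
  expect_error(load_complex(lines, "Z"), "chain")
  expect_error(load_complex("not a pdb at all\nreally not", "A"))
})

test_that("altloc resolves to highest occupancy, first on tie", {
  lines <- c(
    pdb_atom(1, "N", "ALA", "A", 1, c(-1.45, 0, 0), "N"),
    pdb_atom(2, "CA", "ALA", "A", 1, c(0, 0, 0), "C", occ = 0.4, alt = "A"),
    pdb_atom(3, "CA", "ALA", "A", 1, c(9, 9, 9), "C", occ = 0.6, alt = "B"),
    pdb_atom(4, "C", "ALA", "A", 1, c(1.5, 0, 0), "C"),
    pdb_atom(5, "O", "ALA", "A", 1, c(1.9, 1.15, 0), "O"),
    pdb_atom(6, "CB", "ALA", "A", 1, c(1.5, 1.1, 0), "C"),
    "TER", "END")
  cx <- load_complex(lines, "A")
  expect_equal(patchbind:::atom_xyz(cx$residues[[1]], "CA"), c(9, 9, 9))
})

test_that("side-chain center is the mean of heavy side-chain atoms", {
  ala <- residue_lines(1, "ALA", c(0, 0, 0), side = list(CB = c(1, 2, 3)))
  cx <- load_complex(c(ala, "END"), "A")
  expect_equal(side_chain_center(cx$residues[[1]]), c(1, 2, 3))

  ser <- residue_lines(1, "SER", c(0, 0, 0),
                       side = list(CB = c(0, 0, 0), OG = c(2, 0, 0)))
  cx <- load_complex(c(ser, "END"), "A")
  expect_equal(side_chain_center(cx$residues[[1]]), c(1, 0, 0))

  # side-chain-less non-glycine falls back to CA with a warning
  bare <- residue_lines(1, "SER", c(0, 0, 0), side = list())
  cx <- suppressWarnings(load_complex(c(bare, "END"), "A"))
  expect_warning(p <- side_chain_center(cx$residues[[1]]), "CA")
  expect_equal(p, c(0, 0, 0))
})

test_that("glycine uses file HA when present, else an idealized HA", {
  gly_ha <- residue_lines(1, "GLY", c(0, 0, 0),
                          side = list(HA = c(0.5, -0.9, 0.2)))
  cx <- load_complex(c(gly_ha, "END"), "A")
  expect_equal(side_chain_center(cx$residues[[1]]), c(0.5, -0.9, 0.2))

  gly <- residue_lines(1, "GLY", c(0, 0, 0), side = list())
  cx <- load_complex(c(gly, "END"), "A")
  r <- cx$residues[[1]]
  ha <- side_chain_center(r)
  ca <- patchbind:::atom_xyz(r, "CA")
  n <- patchbind:::atom_xyz(r, "N")
  cc <- patchbind:::atom_xyz(r, "C")
  # bond length and tetrahedral angles verify the construction
  expect_true(abs(sqrt(sum((ha - ca)^2)) - 1.09) < 1e-8)
  expect_gte(sqrt(sum((ha - ca)^2)), 1.0)
  expect_lte(sqrt(sum((ha - ca)^2)), 1.2)
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang(ha - ca, n - ca), ang(ha - ca, cc - ca), tolerance = 1e-6)
  expect_gt(ang(ha - ca, n - ca), 100)
})

test_that("isolated residues are exposed and a caged atom has zero area", {
  one <- load_complex(c(residue_lines(1, "ALA", c(0, 0, 0)), "END"), "A")
  one <- compute_sasa(one)
  expect_gt(one$residues[[1]]$sasa, 0)

  # engine-level: an atom enclosed in a tight cage of dummy atoms;
  # verified against a dense-point run (10000 points/atom)
  dirs <- patchbind:::sphere_points(200)
  cage <- rbind(c(0, 0, 0), dirs * 3.0)
  radii <- c(1.7, rep(1.7, nrow(dirs)))
  a960 <- shrake_rupley(cage, radii, probe = 1.4, n_points = 960)
  a10k <- shrake_rupley(cage, radii, probe = 1.4, n_points = 10000)
  expect_equal(a960[1], 0)
  expect_equal(a10k[1], 0)
})

test_that("per-residue areas converge as the point count doubles", {
  s <- small_toy(seed = 12, n = 10)
  cx <- s$complex
  cx1 <- compute_sasa(cx, n_sphere_points = 960)
  cx2 <- compute_sasa(cx, n_sphere_points = 1920)
  a1 <- vapply(cx1$residues, function(r) r$sasa, numeric(1))
  a2 <- vapply(cx2$residues, function(r) r$sasa, numeric(1))
  expect_true(all(abs(a1 - a2) / pmax(a2, 1) < 0.05))
})

test_that("surface labeling is the strict sign of the accessible area", {
  s <- small_toy(seed = 4, n = 12)
  cx <- s$complex
  cx$residues[[1]]$sasa <- 12.3
  cx$residues[[2]]$sasa <- 0
  cx <- label_surface(cx)
  expect_true(cx$residues[[1]]$is_surface)
  expect_false(cx$residues[[2]]$is_surface)
})

test_that("binding labels follow the 5 A rule inclusively and monotonely", {
  base <- residue_lines(1, "ALA", c(0, 0, 0))
  make_cx <- function(d) {
    # straight up from CB, clear of every other atom
    rna <- pdb_atom(99, "P", "U", "R", 1, c(1.5, 1.1, d), "P")
    load_complex(c(base, rna, "END"), "A", "R")
  }
  near <- label_binding(make_cx(4.9))
  far <- label_binding(make_cx(5.1))
  expect_true(near$residues[[1]]$is_binding)
  expect_false(far$residues[[1]]$is_binding)

  # designed contacts only; brute-force distance scan agrees
  s <- small_toy(seed = 21, n = 30)
  tab <- annotation_table(s$complex)
  expect_equal(sort(as.integer(tab$seq_index[tab$is_binding])),
               s$toy$contacts)
  nuc <- as.matrix(s$complex$nucleotide_atoms[, c("x", "y", "z")])
  brute <- vapply(s$complex$residues, function(r) {
    a <- as.matrix(r$atoms[, c("x", "y", "z")])
    min(sqrt(patchbind:::cross_dist2(a, nuc))) <= 5
  }, logical(1))
  expect_equal(tab$is_binding, brute)

  # monotone in the cutoff
  c3 <- label_binding(s$complex, cutoff = 3)
  c8 <- label_binding(s$complex, cutoff = 8)
  b3 <- vapply(c3$residues, function(r) r$is_binding, logical(1))
  b8 <- vapply(c8$residues, function(r) r$is_binding, logical(1))
  expect_true(all(b8[b3]))

  # apo complex: everything non-binding
  apo <- load_complex(chain_pdb(4), "A")
  apo <- label_binding(apo)
  expect_false(any(vapply(apo$residues, function(r) r$is_binding,
                          logical(1))))
})

test_that("labels and areas are invariant under global rigid motion", {
  s <- small_toy(seed = 31, n = 20)
  cx <- s$complex
  moved <- transform_complex(cx, random_rotation(5), c(11, -3, 7))
  moved <- annotate_complex(moved)
  a0 <- vapply(cx$residues, function(r) r$sasa, numeric(1))
  a1 <- vapply(moved$residues, function(r) r$sasa, numeric(1))
  expect_equal(a1, a0, tolerance = 1e-6)
  expect_true(all(a0 >= 0))
  expect_equal(vapply(moved$residues, function(r) r$is_surface, logical(1)),
               vapply(cx$residues, function(r) r$is_surface, logical(1)))
  expect_equal(vapply(moved$residues, function(r) r$is_binding, logical(1)),
               vapply(cx$residues, function(r) r$is_binding, logical(1)))
})

test_that("annotation table writes a readable TSV", {
  s <- small_toy(seed = 8, n = 10)
  f <- tempfile(fileext = ".tsv")
  tab <- annotation_table(s$complex, file = f)
  back <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(names(back), names(tab))
})
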