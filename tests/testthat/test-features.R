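toy_reps <- function(seed = 1) {
  t3 <- lapply(1:12, function(i) random_patch(3, seed = 5000 + i))
  t2 <- lapply(1:6, function(i) random_patch(2, seed = 6000 + i))
  build_representative_set(t3, t2, n3 = 4, n2 = 3, seed = seed)
}

test_that("exactly one structural block is nonzero per residue", {
  reps <- toy_reps()
  n3 <- length(reps$reps_3aa)
  for (k in 0:4) {
    cx <- annotate_complex(load_complex(
      c(unlist(lapply(seq_len(max(k + 1, 1)), function(i) {
        residue_lines(i, "ALA", if (i == 1) c(0, 0, 0) else
          2.5 * c(cos(2 * pi * i / 9), sin(2 * pi * i / 9), 0),
          serial0 = (i - 1) * 5)
      })), "END"), "A"))
    idx <- build_neighbor_index(cx, d_N = 3)
    f <- structural_features(cx, 1, idx, reps)
    expect_length(as.numeric(f), reps$L)
    expect_true(all(f >= 0))
    if (k == 0) {
      expect_true(attr(f, "featureless"))
      expect_true(all(f == 0))
    } else if (k == 1) {
      expect_true(all(f[seq_len(n3)] == 0))
      expect_gt(sum(f[(n3 + 1):reps$L]), 0)
      expect_equal(attr(f, "K"), 1L)
    } else {
      expect_true(all(f[(n3 + 1):reps$L] == 0))
      expect_equal(attr(f, "K"), choose(k, 2))
    }
  }
})

test_that("k = 1 features are plain distances; a matching rep scores zero", {
  # center + one neighbor -> its 2-aa patch; make one representative
  # geometrically identical to that patch
  lines <- c(residue_lines(1, "ALA", c(0, 0, 0)),
             residue_lines(2, "ALA", c(0, 0, 2.5), serial0 = 5), "END")
  cx <- annotate_complex(load_complex(lines, "A"))
  idx <- build_neighbor_index(cx, d_N = 3)
  own <- build_patches(cx, 1, idx)[[1]]
  t2 <- c(list(own), lapply(1:6, function(i) random_patch(2, seed = 80 + i)))
  t3 <- lapply(1:12, function(i) random_patch(3, seed = 90 + i))
  reps <- build_representative_set(t3, t2, n3 = 2, n2 = 7, seed = 1)
  f <- structural_features(cx, 1, idx, reps)
  expect_true(all(f[1:2] == 0))
  which_own <- which(vapply(reps$reps_2aa, function(p) {
    patchbind:::dss(p, own) < 1e-9
  }, logical(1)))
  expect_length(which_own, 1)
  expect_equal(f[2 + which_own], 0)
})

test_that("k >= 2 features equal the term-by-term accumulated distances", {
  cx <- annotate_complex(load_complex(
    c(residue_lines(1, "ALA", c(0, 0, 0)),
      residue_lines(2, "ALA", c(2.5, 0, 0), serial0 = 5),
      residue_lines(3, "ALA", c(0, 2.5, 0), serial0 = 10),
      residue_lines(4, "ALA", c(0, 0, 2.5), serial0 = 15), "END"), "A"))
  idx <- build_neighbor_index(cx, d_N = 3)
  reps <- toy_reps(seed = 3)
  n3 <- length(reps$reps_3aa)
  patches <- build_patches(cx, 1, idx)
  expect_length(patches, 3)  # K = C(3,2)
  f <- structural_features(cx, 1, idx, reps)
  for (j in seq_len(n3)) {
    manual <- sum(vapply(patches, function(p) {
      structural_similarity(p, reps$reps_3aa[[j]])$d_ss
    }, numeric(1)))
    expect_equal(f[j], manual, tolerance = 1e-9)
  }
})

test_that("structural features are invariant under global rigid motion", {
  s <- small_toy(seed = 17, n = 20)
  reps <- toy_reps(seed = 5)
  idx <- build_neighbor_index(s$complex, d_N = 3)
  moved <- transform_complex(s$complex, random_rotation(41), c(3, 1, -9))
  idx2 <- build_neighbor_index(moved, d_N = 3)
  for (i in c(2, 5, 10)) {
    f0 <- structural_features(s$complex, i, idx, reps)
    f1 <- structural_features(moved, i, idx2, reps)
    expect_lt(max(abs(f0 - f1)), 1e-6)
  }
})

test_that("noisier neighborhoods drift away from their representative", {
  # perturb the neighbor coordinates of a planted patch with growing
  # noise; the median distance to the matched representative must not
  # decrease
  spec <- fixture_spec(n_proteins = 1, residues_per_protein = 30,
                       motif = "linear", jitter_sigma = 0, seed = 77)
  toy <- make_toy_complex(spec, 1)
  cx <- annotate_complex(load_complex(toy$pdb, "A", "R", source_id = "p1"))
  templ <- extract_templates(list(cx))$templates_3aa
  rep_patch <- templ[[1]]
  meds <- vapply(seq_along(c(0, 0.2, 0.5, 1.0)), function(si) {
    sig <- c(0, 0.2, 0.5, 1.0)[si]
    draws <- vapply(1:30, function(d) {
      p <- rep_patch
      noise <- with_seed(1000 * si + d,
                         matrix(rnorm(30, sd = sig), 10, 3))
      p$coords[6:15, ] <- p$coords[6:15, ] + noise  # neighbors only
      patchbind:::dss(p, rep_patch)
    }, numeric(1))
    median(draws)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
  expect_equal(meds[1], 0)
})

test_that("PSSM files round-trip and sequence mismatches are reported", {
  seqs <- "ARNDCQEGHILK"
  txt <- make_pseudo_pssm(seqs, seed = 4)
  m <- load_pssm(txt, expected_sequence = seqs)
  expect_equal(dim(m), c(12L, 20L))
  expect_equal(colnames(m), patchbind:::PSSM_AA)
  # file path round-trip with identical values
  f <- tempfile(fileext = ".pssm")
  make_pseudo_pssm(seqs, seed = 4, file = f)
  expect_equal(load_pssm(f), m)

  expect_error(load_pssm(txt, expected_sequence = "ARNDQQEGHILK"),
               "position\\(s\\) 5")
  expect_error(load_pssm(txt, expected_sequence = "ARND"), "positions")
  expect_error(load_pssm("garbage\nlines\n"), "malformed")
  expect_error(make_pseudo_pssm("ARNB", seed = 1), "invalid")
})

test_that("noise-free pseudo-PSSM rows equal the substitution stub rows", {
  stub <- patchbind:::substitution_stub()
  m <- load_pssm(make_pseudo_pssm("AAGW", seed = 9, noise = 0))
  expect_equal(unname(m[1, ]), unname(stub["A", ]))
  expect_equal(m[1, ], m[2, ])
  expect_equal(unname(m[3, ]), unname(stub["G", ]))
  expect_equal(unname(m[4, ]), unname(stub["W", ]))
  # different seeds differ somewhere, same shape
  a <- load_pssm(make_pseudo_pssm("AAAAAAAA", seed = 1))
  b <- load_pssm(make_pseudo_pssm("AAAAAAAA", seed = 2))
  expect_equal(dim(a), dim(b))
  expect_false(all(a == b))
})

test_that("interface propensity is the smoothed frequency ratio", {
  # toy surface: 5 R and 5 L; interface 4 R + 1 L (alpha = 0)
  mk_res <- function(aa, binding) {
    structure(list(chain_id = "A", seq_index = "1", aa3 = patchbind:::AA1TO3[[aa]],
                   aa = aa, atoms = data.frame(), shape_points = NULL,
                   sasa = 1, is_surface = TRUE, is_binding = binding),
              class = "residue_model")
  }
  res <- c(lapply(1:4, function(i) mk_res("R", TRUE)),
           lapply(1, function(i) mk_res("R", FALSE)),
           lapply(1, function(i) mk_res("L", TRUE)),
           lapply(1:4, function(i) mk_res("L", FALSE)))
  cx <- structure(list(residues = res,
                       nucleotide_atoms = data.frame(),
                       source_id = "toy"), class = "complex_model")
  prop <- compute_propensity(list(cx), alpha = 0)
  expect_equal(unname(prop["R"]), (4 / 5) / (5 / 10))
  expect_equal(unname(prop["L"]), (1 / 5) / (5 / 10))

  # identical interface and surface composition -> all ratios 1
  res_eq <- c(lapply(1:2, function(i) mk_res("R", TRUE)),
              lapply(1:2, function(i) mk_res("L", TRUE)))
  cx_eq <- structure(list(residues = res_eq, nucleotide_atoms = data.frame(),
                          source_id = "eq"), class = "complex_model")
  prop_eq <- compute_propensity(list(cx_eq), alpha = 0)
  expect_equal(unname(prop_eq[c("R", "L")]), c(1, 1))

  # smoothing keeps absent types finite and positive
  prop1 <- compute_propensity(list(cx), alpha = 1)
  expect_true(all(is.finite(prop1) & prop1 > 0))

  # surface-frequency-weighted propensities average to exactly 1
  w <- c(R = 5, L = 5) / 10
  expect_equal(sum(unname(w * prop[c("R", "L")])), 1)

  expect_error(compute_propensity(list()), "empty")
})

test_that("assembled vectors have 60 structural + 20 PSSM + 1 propensity", {
  s <- small_toy(seed = 19, n = 24)
  templ <- extract_templates(list(s$complex))
  reps <- build_representative_set(templ$templates_3aa, templ$templates_2aa,
                                   n3 = 3, n2 = 2, seed = 1)
  seqs <- paste(vapply(s$complex$residues, function(r) r$aa, character(1)),
                collapse = "")
  pssms <- list()
  pssms[[paste(s$complex$source_id, "A", sep = "|")]] <-
    load_pssm(make_pseudo_pssm(seqs, seed = 2))
  prop <- compute_propensity(list(s$complex))
  feats <- assemble_features(list(s$complex), reps, pssms, prop)
  n_feature_cols <- length(patchbind:::feature_columns(feats))
  expect_equal(n_feature_cols, reps$L + 20 + 1)
  expect_equal(length(grep("^f[0-9]+$", names(feats))), reps$L)
  expect_equal(length(grep("^pssm_", names(feats))), 20)

  # provenance is bijective with the featured residues
  keys <- paste(feats$chain_id, feats$seq_index)
  expect_false(any(duplicated(keys)))
  eligible <- vapply(seq_along(s$complex$residues), function(i) {
    r <- s$complex$residues[[i]]
    isTRUE(r$is_surface) && !is.null(r$shape_points)
  }, logical(1))
  idx <- build_neighbor_index(s$complex, d_N = 3)
  k_pos <- vapply(seq_along(s$complex$residues), function(i) {
    length(patchbind:::eligible_neighbors(s$complex, idx, i)) > 0
  }, logical(1))
  expect_equal(nrow(feats), sum(eligible & k_pos))
  expect_equal(attr(feats, "n_featureless"), sum(eligible & !k_pos))

  # labels match the annotation
  tab <- annotation_table(s$complex)
  expect_equal(feats$label,
               tab$is_binding[match(keys, paste(tab$chain_id,
                                                tab$seq_index))])

  expect_error(assemble_features(list(s$complex), reps,
                                 list(), prop), "PSSM")
})

test_that("full-dimension contract: 81 columns under default cluster counts", {
  bench <- shared_benchmark()
  cxs <- bench$complexes[1:12]
  templ <- extract_templates(cxs)
  reps <- build_representative_set(templ$templates_3aa, templ$templates_2aa,
                                   n3 = 40, n2 = 20, seed = 7)
  prop <- compute_propensity(cxs)
  feats <- assemble_features(cxs[1], reps, bench$pssms, prop)
  expect_equal(length(patchbind:::feature_columns(feats)), 81)
  expect_equal(sum(grepl("^f[0-9]+$", names(feats))), 60)
})
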