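#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII position-specific scoring matrix dialect written by
#' PSI-BLAST (`-out_ascii_pssm`): after the header, one row per sequence
#' position with the position number, the query residue and at least 20
#' integer log-odds columns (the first 20 columns are kept; trailing
#' weighted-percentage columns are ignored). Scores are returned as the
#' raw integers -- no rescaling is applied by default.
#'
#' @param pssm path to the file, or its text.
#' @param expected_sequence amino-acid string the embedded query sequence
#'   must match; mismatching positions raise an error naming them.
#' @return integer matrix (positions x 20), columns in standard PSI-BLAST
#'   amino-acid order, with attribute `sequence`.
#' @export
load_pssm <- function(pssm, expected_sequence = NULL) {
  lines <- if (length(pssm) == 1L && !grepl("\n", pssm, fixed = TRUE) &&
               file.exists(pssm)) readLines(pssm) else
    unlist(strsplit(pssm, "\n", fixed = TRUE))
  toks <- lapply(trimws(lines), function(l) strsplit(l, "\\s+")[[1L]])
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 22L && grepl("^[0-9]+$", tk[1L]) &&
      tk[2L] %in% AA1 && all(grepl("^-?[0-9]+$", tk[3:22]))
  }, logical(1L))
  if (!any(is_row)) stop("malformed PSSM: no score rows found")
  rows <- toks[is_row]
  seq_letters <- vapply(rows, `[[`, character(1L), 2L)
  scores <- t(vapply(rows, function(tk) as.integer(tk[3:22]),
                     integer(20L)))
  colnames(scores) <- PSSM_AA
  if (!is.null(expected_sequence)) {
    expected <- strsplit(expected_sequence, "")[[1L]]
    if (length(expected) != length(seq_letters)) {
      stop("PSSM has ", length(seq_letters), " positions but expected ",
           length(expected))
    }
    bad <- which(expected != seq_letters)
    if (length(bad) > 0L) {
      stop("PSSM sequence mismatch at position(s) ",
           paste(bad, collapse = ", "))
    }
  }
  attr(scores, "sequence") <- paste(seq_letters, collapse = "")
  scores
}

# Fixed 20 x 20 substitution-matrix stub used for pseudo-PSSM rows.
# BLOSUM62 scores (from Biostrings when installed); a residue's stub row
# is its substitution-score row in PSI-BLAST column order.
substitution_stub <- function() {
  if (!is.null(.perf$stub)) return(.perf$stub)
  stub <- NULL
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    e <- new.env()
    ok <- tryCatch({
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e2) FALSE)
    if (ok && !is.null(e$BLOSUM62)) {
      stub <- unname(e$BLOSUM62[PSSM_AA, PSSM_AA])
    }
  }
  if (is.null(stub)) {
    # fallback: identity-dominant stub (+6 match / -2 mismatch)
    stub <- matrix(-2L, 20L, 20L)
    diag(stub) <- 6L
  }
  dimnames(stub) <- list(PSSM_AA, PSSM_AA)
  .perf$stub <- stub
  stub
}

#' Generate a pseudo-PSSM in the PSI-BLAST ASCII dialect
#'
#' Stand-in for a PSI-BLAST run: each position's 20 log-odds scores are
#' the substitution-matrix row of its residue type plus seeded integer
#' noise in {-noise, ..., +noise}. The output round-trips exactly through
#' [load_pssm()].
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param seed integer seed.
#' @param noise maximum absolute integer perturbation (default 1; 0 gives
#'   pure stub rows).
#' @param file optional output path.
#' @return the PSSM text (character vector of lines), invisibly when
#'   `file` is given.
#' @export
make_pseudo_pssm <- function(sequence, seed = 1, noise = 1, file = NULL) {
  letters <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(letters), AA1)
  if (length(bad) > 0L) {
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  stub <- substitution_stub()
  n <- length(letters)
  scores <- stub[letters, , drop = FALSE]
  if (noise > 0) {
    scores <- scores + with_seed(seed, matrix(
      sample.int(2L * noise + 1L, n * 20L, replace = TRUE) - noise - 1L,
      n, 20L))
  }
  header <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("            ", paste(sprintf("%3s", PSSM_AA), collapse = " "),
           "   ", paste(sprintf("%3s", PSSM_AA), collapse = " ")))
  body <- vapply(seq_len(n), function(i) {
    pct <- pmax(0L, scores[i, ] - min(scores[i, ]))
    paste0(sprintf("%5d %s  ", i, letters[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = " "), "   ",
           paste(sprintf("%3d", pct), collapse = " "),
           sprintf("  %4.2f %8.2f", 0.5, 1.0))
  }, character(1L))
  txt <- c(header, body, "")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
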