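# Lipobox motif scanning for lipoprotein candidates.

LIPOBOX_PATTERNS <- c(canonical = "[VL]..C", extended = "[LVI][ASTG][GAS]C")

#' Scan a sequence for lipobox motifs
#'
#' Bacterial lipoproteins carry an N-terminal lipobox whose conserved
#' cysteine is the lipidation site. The default pattern is the (V/L)XXC
#' class; an alternative stricter alphabet (\code{[LVI][ASTG][GAS]C}) is
#' available via `pattern = "extended"`. A hit is reported when the motif's
#' cysteine lies within the first `window` residues (lipoprotein signal
#' peptides are short, hence the default 40). Overlapping matches are all
#' reported. The `canonical` flag marks the exact 4-mer `LGCC`, the classic
#' lipidation sequence.
#'
#' @param sequence Ungapped amino-acid string.
#' @param window Number of N-terminal residues the cysteine may occupy
#'   (default 40, minimum 4).
#' @param pattern `"canonical"` for (V/L)XXC (default) or `"extended"`.
#' @return A tibble with one row per hit: `start` (1-based first residue of
#'   the motif), `motif`, `cys_position` (= start + 3) and `canonical`.
#' @export
#' @examples
#' scan_lipobox("MKRTLLPLLGCCSNAQE")
scan_lipobox <- function(sequence, window = 40,
                         pattern = c("canonical", "extended")) {
  pattern <- match.arg(pattern)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop_input("`sequence` must be a single string")
  }
  if (!is_count(window, min = 4)) stop_input("`window` must be an integer >= 4")
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE)) {
    stop_input("`sequence` must be ungapped")
  }
  rx <- sprintf("(?=(%s))", LIPOBOX_PATTERNS[[pattern]])
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  starts <- as.integer(m[m != -1L])
  starts <- starts[starts + 3L <= min(window, nchar(sequence))]
  if (length(starts) == 0L) {
    return(tibble::tibble(start = integer(), motif = character(),
                          cys_position = integer(), canonical = logical()))
  }
  motif <- substring(sequence, starts, starts + 3L)
  tibble::tibble(start = starts, motif = motif,
                 cys_position = starts + 3L,
                 canonical = motif == "LGCC")
}

#' Scan every sequence of a family or FASTA file for lipoboxes
#'
#' @param x A [protein_family()], a named character vector of sequences, or
#'   a FASTA path. Gaps are stripped before scanning.
#' @inheritParams scan_lipobox
#' @return A tibble with columns `id`, `start`, `motif`, `cys_position`,
#'   `canonical` (zero rows when nothing matches).
#' @export
lipobox_scan <- function(x, window = 40, pattern = c("canonical", "extended")) {
  pattern <- match.arg(pattern)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- read_family(x, format = "fasta")
  }
  if (inherits(x, "protein_family")) {
    seqs <- stats::setNames(x$records$sequence, x$records$id)
  } else if (is.character(x)) {
    seqs <- if (is.null(names(x))) stats::setNames(x, paste0("seq", seq_along(x))) else x
  } else {
    stop_input("`x` must be a protein_family, character vector or FASTA path")
  }
  seqs <- gsub("-", "", seqs, fixed = TRUE)
  out <- lapply(names(seqs), function(id) {
    hits <- scan_lipobox(seqs[[id]], window = window, pattern = pattern)
    if (nrow(hits)) dplyr::mutate(hits, id = id, .before = 1) else NULL
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(id = character(), start = integer(),
                          motif = character(), cys_position = integer(),
                          canonical = logical())
  }
  out
}
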