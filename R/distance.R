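# Pairwise evolutionary distances from protein alignments.

#' Proportion-of-differences (p) distance matrix
#'
#' Computes, for every pair of sequences in an aligned family, the fraction
#' of differing columns among the comparable columns. A column is comparable
#' for a pair when neither sequence carries a gap (`-`) or an unknown residue
#' (`X`) there; `X` is treated as missing data, never as a mismatch.
#'
#' Two gap policies are offered. `complete_deletion` first drops every column
#' containing a gap or `X` in any sequence, so all pairs share the same
#' column set (the usual choice before consensus phylogenies).
#' `pairwise_deletion` drops columns per pair, retaining more signal for the
#' mirrortree path. The two agree exactly on gapless alignments.
#'
#' @param family An aligned [protein_family()] with at least two records.
#' @param gap_policy `"complete_deletion"` (default) or `"pairwise_deletion"`.
#' @return A symmetric numeric matrix with zero diagonal, organism labels as
#'   dimnames, entries in \[0, 1\].
#' @export
p_distance_matrix <- function(family,
                              gap_policy = c("complete_deletion",
                                             "pairwise_deletion")) {
  gap_policy <- match.arg(gap_policy)
  if (!inherits(family, "protein_family")) stop_input("not a protein_family")
  if (!family$aligned) stop_input("family '%s' is not aligned", family$name)
  if (nrow(family$records) < 2L) stop_input("need at least 2 sequences")

  m <- family_matrix(family)
  ok <- m != "-" & m != "X"
  orgs <- rownames(m)
  n <- nrow(m)

  if (gap_policy == "complete_deletion") {
    keep <- colSums(ok) == n
    if (!any(keep)) {
      stop_degenerate("no columns free of gaps/missing data in family '%s'",
                      family$name)
    }
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }

  D <- matrix(0, n, n, dimnames = list(orgs, orgs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L) {
        stop_degenerate("no comparable columns between '%s' and '%s'",
                        orgs[i], orgs[j])
      }
      p <- sum(m[i, comp] != m[j, comp]) / ncomp
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Poisson correction of p-distances
#'
#' Converts raw p-distances into expected substitutions per site under the
#' 20-state equal-rates (Poisson) amino-acid model:
#' `d = -(19/20) * log(1 - 20 p / 19)`. This is the inverse of the model used
#' by the family simulator, so simulated branch lengths are recoverable.
#'
#' @param D A p-distance matrix, all entries strictly below 19/20.
#' @return A matrix of corrected distances with the same dimnames.
#' @export
#' @examples
#' D <- matrix(c(0, 0.475, 0.475, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' poisson_correct(D) # off-diagonal ~ 0.6585
poisson_correct <- function(D) {
  check_distance_matrix(D)
  if (any(D > 1)) stop_input("p-distances must lie in [0, 1]")
  if (any(D >= 19 / 20)) {
    stop_degenerate("saturated distance (p >= 19/20) between '%s' and '%s'",
                    rownames(D)[which(D >= 19 / 20, arr.ind = TRUE)[1, 1]],
                    colnames(D)[which(D >= 19 / 20, arr.ind = TRUE)[1, 2]])
  }
  out <- -(19 / 20) * log1p(-(20 / 19) * D)
  diag(out) <- 0
  out
}

#' Write / read a labeled distance matrix
#'
#' `write_distance()` serializes a square matrix as TSV (header row and first
#' column of organism labels) or in PHYLIP square format; `read_distance()`
#' reads the TSV form back.
#'
#' @param D A labeled symmetric distance matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path` invisibly, or the matrix for `read_distance()`.
#' @export
write_distance <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  check_distance_matrix(D)
  if (format == "tsv") {
    tab <- cbind(organism = rownames(D), as.data.frame(D))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(c(format(rownames(D)[i], width = 10),
                         formatC(D[i, ], digits = 10, format = "g")),
                       collapse = "  "), con)
    }
  }
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = c(organism = "character"))
  D <- as.matrix(tab[, -1, drop = FALSE])
  rownames(D) <- tab$organism
  storage.mode(D) <- "double"
  check_distance_matrix(D, arg = path)
  D
}
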