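# Reading, writing and filtering organism-labeled protein families.

#' Construct a protein family
#'
#' A protein family is an ordered set of protein sequences, one per organism
#' after representative selection, optionally aligned. It is the unit every
#' downstream stage (distances, trees, mirrortree correlation) consumes.
#'
#' @param records A data frame (or tibble) with character columns `id`,
#'   `organism` and `sequence`. Sequences use the 20-letter amino-acid
#'   alphabet plus `-` (gap) and `X` (unknown).
#' @param name Family name (single string).
#' @param aligned Logical; if `NULL` (default) it is inferred: the family is
#'   flagged aligned iff all sequences have equal length.
#'
#' @return An object of class `protein_family`: a list with elements `name`,
#'   `records` (a tibble) and `aligned`.
#' @export
#' @examples
#' fam <- protein_family(
#'   tibble::tibble(
#'     id = c("a", "b"), organism = c("orgA", "orgB"),
#'     sequence = c("MKLV", "MKIV")
#'   ),
#'   name = "toy"
#' )
#' fam$aligned
protein_family <- function(records, name = "family", aligned = NULL) {
  records <- tibble::as_tibble(records)
  req <- c("id", "organism", "sequence")
  if (!all(req %in% names(records))) {
    stop_input("family records need columns %s", paste(req, collapse = ", "))
  }
  records <- records[, req]
  if (nrow(records) == 0L) stop_input("no records")
  if (any(!nzchar(records$sequence))) stop_input("empty sequence in family '%s'", name)
  if (any(is.na(records$organism) | !nzchar(records$organism))) {
    stop_input("empty organism label in family '%s'", name)
  }
  if (anyDuplicated(records$id)) {
    stop_input("duplicate sequence id '%s' in family '%s'",
               records$id[duplicated(records$id)][1], name)
  }
  bad <- grepl(sprintf("[^%sX-]", paste(AA20, collapse = "")), toupper(records$sequence))
  if (any(bad)) {
    stop_input("sequence '%s' contains characters outside the amino-acid alphabet",
               records$id[bad][1])
  }
  records$sequence <- toupper(records$sequence)
  lens <- nchar(records$sequence)
  if (is.null(aligned)) aligned <- length(unique(lens)) == 1L
  if (aligned && length(unique(lens)) != 1L) {
    stop_input("family '%s' flagged aligned but sequence lengths differ", name)
  }
  structure(list(name = name, records = records, aligned = aligned),
            class = "protein_family")
}

#' @export
print.protein_family <- function(x, ...) {
  cat(sprintf("<protein_family '%s': %d sequences, %s>\n", x$name,
              nrow(x$records),
              if (x$aligned) sprintf("aligned, %d columns", nchar(x$records$sequence[1]))
              else "unaligned"))
  invisible(x)
}

# organism tag: token after the last '|' in the header, or the whole header.
organism_from_header <- function(header) {
  sub(".*\\|", "", header)
}

#' Read a protein family from FASTA or Clustal
#'
#' The organism of each record defaults to the token after the last `|` of
#' its header (the whole header when no `|` is present); alternatively a
#' two-column tab-separated mapping file (`id<TAB>organism`, no header) or a
#' named character vector can assign organisms explicitly.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"clustal"`.
#' @param organisms `NULL` for the header rule, a path to a mapping TSV, or a
#'   named character vector `c(id = organism, ...)`.
#' @param name Family name; defaults to the file name.
#' @return A [protein_family()].
#' @export
read_family <- function(path, format = c("fasta", "clustal"), organisms = NULL,
                        name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))

  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    body <- which(nzchar(trimws(lines)))
    if (length(body) == 0L) stop_input("no records in %s", path)
    if (!startsWith(trimws(lines[body[1]]), ">")) {
      stop_input("malformed FASTA in %s: line %d does not start a record",
                 path, body[1])
    }
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0L) stop_input("no records in %s", path)
    ids <- sub("\\s.*$", "", names(aas))
    seqs <- as.character(aas)
  } else {
    aln <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                    error = function(e) stop_input("malformed clustal file %s: %s",
                                                   path, conditionMessage(e)))
    seqs <- Biostrings::unmasked(aln)
    ids <- names(seqs)
    seqs <- as.character(seqs)
  }
  if (anyDuplicated(ids)) {
    stop_input("duplicate sequence id '%s' in %s", ids[duplicated(ids)][1], path)
  }

  org <- organism_from_header(ids)
  if (!is.null(organisms)) {
    map <- if (is.character(organisms) && length(organisms) == 1L && file.exists(organisms)) {
      tab <- utils::read.delim(organisms, header = FALSE, colClasses = "character")
      stats::setNames(tab[[2]], tab[[1]])
    } else if (!is.null(names(organisms))) {
      organisms
    } else {
      stop_input("`organisms` must be a mapping file path or a named vector")
    }
    miss <- setdiff(ids, names(map))
    if (length(miss)) stop_input("no organism mapping for id '%s'", miss[1])
    org <- unname(map[ids])
  }

  protein_family(tibble::tibble(id = ids, organism = org,
                                sequence = unname(seqs)), name = name)
}

#' Write a protein family as FASTA
#'
#' Headers are the record ids; when the organism cannot be recovered from the
#' id by the default header rule, `|organism` is appended so that
#' `read_family()` round-trips ids, organisms and sequences exactly.
#'
#' @param family A [protein_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  stopifnot(inherits(family, "protein_family"))
  rec <- family$records
  hdr <- ifelse(organism_from_header(rec$id) == rec$organism,
                rec$id, paste(rec$id, rec$organism, sep = "|"))
  x <- Biostrings::AAStringSet(stats::setNames(rec$sequence, hdr))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a homolog-hit table
#'
#' Tab-separated with header columns `subject_id`, `organism`, `bitscore`
#' and `coverage` (query coverage as a fraction in \[0, 1\]).
#'
#' @param path Path to the TSV file.
#' @return A tibble of hits.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  hits <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "organism", "bitscore", "coverage")
  if (!all(req %in% names(hits))) {
    stop_input("hit table %s needs columns %s", path, paste(req, collapse = ", "))
  }
  validate_hits(hits[, req])
}

validate_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) > 0L) {
    if (any(hits$coverage < 0 | hits$coverage > 1)) {
      stop_input("hit coverage must lie in [0, 1]")
    }
    if (any(hits$bitscore < 0)) stop_input("hit bitscore must be non-negative")
  }
  hits
}

#' Filter homolog hits by query coverage
#'
#' Retains hits whose coverage is strictly greater than the threshold (a hit
#' at exactly the threshold is dropped); input order is preserved.
#'
#' @param hits A tibble of hits as returned by [read_hits()].
#' @param min_coverage Coverage threshold as a fraction; default `0.60`.
#' @return The retained hits, same columns and order.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   subject_id = c("s1", "s2", "s3"), organism = c("a", "b", "c"),
#'   bitscore = c(100, 90, 80), coverage = c(0.55, 0.60, 0.80)
#' )
#' filter_hits(hits) # keeps only s3
filter_hits <- function(hits, min_coverage = 0.60) {
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1) {
    stop_input("`min_coverage` must lie in [0, 1]")
  }
  hits <- validate_hits(hits)
  dplyr::filter(hits, .data$coverage > min_coverage)
}

#' Select one representative hit per organism
#'
#' Within each organism the hit with the highest bitscore wins; ties go to
#' the highest coverage, then to the lexicographically smallest subject id.
#' Organisms keep their order of first appearance.
#'
#' @param hits A tibble of hits.
#' @return One hit per organism.
#' @export
select_one_per_organism <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$coverage),
                   .data$subject_id) |>
    dplyr::distinct(.data$organism, .keep_all = TRUE) |>
    dplyr::arrange(match(.data$organism, unique(hits$organism)))
}

# Family as a character matrix, rows labeled by organism.
family_matrix <- function(family) {
  if (!inherits(family, "protein_family")) stop_input("not a protein_family")
  m <- do.call(rbind, strsplit(family$records$sequence, "", fixed = TRUE))
  rownames(m) <- family$records$organism
  m
}
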