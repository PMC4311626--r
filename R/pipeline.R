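# End-to-end orchestration: families in, trees/matrices/result out.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Defaults follow the package's
#' standard protocol: 100 bootstrap replicates, consensus collapse below 45
#' percent support, 999 permutations, coverage filter at 0.60.
#'
#' @param family1,family2 Paths to the two aligned family FASTA files, or
#'   [protein_family()] objects.
#' @param out_dir Directory for artifacts.
#' @param gap_policy,correction Distance-stage options.
#' @param bootstrap Bootstrap replicate count (default 100).
#' @param collapse Consensus collapse threshold in percent (default 45).
#' @param permutations Permutation count for the significance test
#'   (default 999).
#' @param min_coverage Coverage threshold for optional hit filtering
#'   (default 0.60).
#' @param min_n Minimum common organisms (default 4).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(family1, family2, out_dir = ".",
                            gap_policy = c("complete_deletion",
                                           "pairwise_deletion"),
                            correction = c("poisson", "none"),
                            bootstrap = 100, collapse = 45,
                            permutations = 999, min_coverage = 0.60,
                            min_n = 4, seed = NULL) {
  gap_policy <- match.arg(gap_policy)
  correction <- match.arg(correction)
  if (!is_count(bootstrap)) stop_input("`bootstrap` must be a positive integer")
  if (!is.numeric(collapse) || collapse < 0 || collapse > 100) {
    stop_input("`collapse` must lie in [0, 100]")
  }
  if (!is_count(permutations, min = 19)) {
    stop_input("`permutations` must be an integer >= 19")
  }
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1) {
    stop_input("`min_coverage` must lie in [0, 1]")
  }
  structure(list(family1 = family1, family2 = family2, out_dir = out_dir,
                 gap_policy = gap_policy, correction = correction,
                 bootstrap = as.integer(bootstrap), collapse = collapse,
                 permutations = as.integer(permutations),
                 min_coverage = min_coverage, min_n = min_n,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys are the
#' arguments of [pipeline_config()]; unknown keys are an error. Values given
#' on the command line override the file, which overrides the defaults.
#'
#' @param path Path to the config file.
#' @param ... Overrides, as named arguments to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_input("malformed config line: '%s'", lines[bad][1])
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[`, character(1), 1))
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) stop_input("unknown config key '%s'", unknown[1])
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full mirrortree pipeline
#'
#' For each family: distance matrix (written as TSV), NJ tree (newick),
#' bootstrap consensus with collapse (newick with supports), patristic
#' matrix (TSV). Then the two patristic matrices are matched on common
#' organisms and the correlation with its permutation p-value is computed
#' and written as JSON (`{r, N, n, p_value, B, seed}`). Any stage failure
#' aborts with the stage name, removing partial artifacts. With a fixed
#' seed a re-run reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The `mirrortree_result`, invisibly, with the artifact paths in
#'   attribute `"paths"`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_input("not a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = intersect(class(e), c("mirrortree_input_error",
                                        "mirrortree_degenerate_error",
                                        "mirrortree_error")),
          parent = e)
  }
  stage <- function(name, expr) {
    tryCatch(expr, mirrortree_error = function(e) on_fail(name, e),
             error = function(e) on_fail(name, e))
  }
  emit <- function(path) { written <<- c(written, path); path }

  message(sprintf(
    "pipeline settings: gap_policy=%s correction=%s bootstrap=%d collapse=%s permutations=%d min_n=%s seed=%s",
    config$gap_policy, config$correction, config$bootstrap, config$collapse,
    config$permutations, config$min_n,
    if (is.null(config$seed)) "none" else config$seed))

  fams <- list()
  mats <- list()
  for (k in 1:2) {
    fk <- config[[paste0("family", k)]]
    fam <- stage("read", {
      if (inherits(fk, "protein_family")) fk else read_family(fk)
    })
    if (!fam$aligned) stage("read", stop_input("family '%s' is not aligned", fam$name))
    D <- stage("distance", {
      D <- p_distance_matrix(fam, config$gap_policy)
      if (config$correction == "poisson") D <- poisson_correct(D)
      D
    })
    write_distance(D, emit(file.path(config$out_dir,
                                     sprintf("family%d_distance.tsv", k))))
    tree <- stage("nj", nj_tree(D))
    write_newick(tree, emit(file.path(config$out_dir,
                                      sprintf("family%d_nj.nwk", k))))
    cons <- stage("consensus", {
      bs <- bootstrap_trees(fam, B = config$bootstrap,
                            seed = derive_seed(config$seed, 10 + k),
                            gap_policy = config$gap_policy,
                            correction = config$correction)
      consensus_collapse(bs, threshold_pct = config$collapse)
    })
    write_newick(cons, emit(file.path(config$out_dir,
                                      sprintf("family%d_consensus.nwk", k))))
    P <- stage("patristic", patristic_matrix(tree))
    write_distance(P, emit(file.path(config$out_dir,
                                     sprintf("family%d_patristic.tsv", k))))
    fams[[k]] <- fam
    mats[[k]] <- P
  }

  res <- stage("mirror", {
    pair <- match_organisms(mats[[1]], mats[[2]], min_n = config$min_n)
    message(sprintf("common organisms (N=%d): %s", pair$N,
                    paste(pair$organisms, collapse = ", ")))
    permutation_pvalue(pair, B = config$permutations,
                       seed = derive_seed(config$seed, 13))
  })
  json_path <- emit(file.path(config$out_dir, "mirrortree_result.json"))
  jsonlite::write_json(
    list(r = res$r, N = res$N, n = res$n, p_value = res$p_value,
         B = res$B_permutations,
         seed = if (is.null(config$seed)) NA else config$seed),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")

  attr(res, "paths") <- written
  invisible(res)
}
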