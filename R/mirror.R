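# The mirrortree statistic: matching, correlation and permutation test.

#' Match two distance matrices on their common organisms
#'
#' Takes the intersection of the two label sets, sorts it lexicographically,
#' subsets both matrices to it, and flattens each upper triangle in the same
#' (i < j) order, so position k of both vectors refers to the same organism
#' pair.
#'
#' @param M1,M2 Labeled symmetric distance matrices (one row per organism),
#'   e.g. from [patristic_matrix()].
#' @param min_n Minimum number of common organisms (default 4); below this
#'   the correlation is near-degenerate.
#' @return An object of class `matched_pair` with elements `organisms`,
#'   `N` (common organisms), `n` (= N(N-1)/2 pairs), the flattened vectors
#'   `R` and `S`, and the subset matrices `M1`, `M2`.
#' @export
match_organisms <- function(M1, M2, min_n = 4) {
  check_distance_matrix(M1, "M1")
  check_distance_matrix(M2, "M2")
  common <- sort(intersect(rownames(M1), rownames(M2)))
  if (length(common) < min_n) {
    stop_input("insufficient common organisms: %d found, %d required",
               length(common), min_n)
  }
  A <- M1[common, common]
  B <- M2[common, common]
  N <- length(common)
  structure(list(organisms = common, N = N, n = N * (N - 1L) / 2L,
                 R = upper_tri_vec(A), S = upper_tri_vec(B),
                 M1 = A, M2 = B),
            class = "matched_pair")
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf("<matched_pair: N = %d common organisms, n = %d distance pairs>\n",
              x$N, x$n))
  invisible(x)
}

# Pearson correlation written out as the mirrortree similarity score.
pearson_r <- function(R, S) {
  Rc <- R - mean(R)
  Sc <- S - mean(S)
  den <- sqrt(sum(Rc^2) * sum(Sc^2))
  if (den == 0) stop_degenerate("degenerate distance matrix: zero variance")
  sum(Rc * Sc) / den
}

#' Mirrortree tree-similarity correlation
#'
#' The similarity between two families' trees is the Pearson correlation of
#' their matched distance matrices,
#' \deqn{r = \frac{\sum_i (R_i - \bar R)(S_i - \bar S)}
#'              {\sqrt{\sum_i (R_i - \bar R)^2 \sum_i (S_i - \bar S)^2}},}
#' where \eqn{R_i} and \eqn{S_i} run over the \eqn{n = (N^2 - N)/2} distinct
#' organism pairs of the two matrices.
#'
#' @param pair A [match_organisms()] result.
#' @return The correlation r, a number in \[-1, 1\].
#' @export
#' @examples
#' M <- matrix(c(0, .2, .4, .2, 0, .6, .4, .6, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' # self-comparison is perfectly correlated (needs >= 4 organisms normally)
tree_correlation <- function(pair) {
  if (!inherits(pair, "matched_pair")) stop_input("not a matched_pair")
  if (pair$n < 3) stop_input("need at least 3 distance pairs")
  pearson_r(pair$R, pair$S)
}

#' Permutation significance of the mirrortree correlation
#'
#' The null hypothesis is that the organism-to-organism correspondence
#' between the two matrices is arbitrary. It is simulated by permuting the
#' organism assignment of the second matrix as a whole (rows and columns
#' together, Mantel-style), which preserves the within-family distance
#' structure, and recomputing r each time. The p-value uses the add-one
#' correction \eqn{p = (1 + \#\{|r_b| \ge |r_{obs}|\}) / (1 + B)} (one-sided
#' on r itself with `alternative = "greater"`), so it is never zero and its
#' minimum is 1/(B+1).
#'
#' @param pair A [match_organisms()] result.
#' @param B Number of permutations (default 999, minimum 19).
#' @param seed Optional integer seed; the same seed reproduces the p-value.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return A `mirrortree_result` holding `r`, `N`, `n`, `p_value`,
#'   `B_permutations`, `seed`, the permutation distribution and the matched
#'   distance vectors.
#' @export
permutation_pvalue <- function(pair, B = 999, seed = NULL,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!inherits(pair, "matched_pair")) stop_input("not a matched_pair")
  if (!is_count(B, min = 19)) stop_input("`B` must be an integer >= 19")
  r_obs <- tree_correlation(pair)

  N <- pair$N
  Rc <- pair$R - mean(pair$R)
  ssR <- sum(Rc^2)
  ut <- upper.tri(pair$M2)
  r_perm <- with_seed_if(seed, vapply(seq_len(B), function(b) {
    perm <- sample.int(N)
    S <- pair$M2[perm, perm][ut]
    Sc <- S - mean(S)
    den <- sqrt(ssR * sum(Sc^2))
    if (den == 0) return(0)
    sum(Rc * Sc) / den
  }, numeric(1)))

  exceed <- if (alternative == "two.sided") {
    sum(abs(r_perm) >= abs(r_obs))
  } else {
    sum(r_perm >= r_obs)
  }
  structure(list(r = r_obs, N = N, n = pair$n,
                 p_value = (1 + exceed) / (1 + B),
                 B_permutations = B, seed = seed, alternative = alternative,
                 r_perm = r_perm, R = pair$R, S = pair$S,
                 organisms = pair$organisms),
            class = "mirrortree_result")
}

#' Full mirrortree comparison of two trees or matrices
#'
#' Convenience front end: computes patristic matrices when given trees,
#' matches organisms, and runs the correlation and its permutation test.
#'
#' @param x,y `ape::phylo` trees with organism tip labels, or labeled
#'   distance matrices.
#' @inheritParams permutation_pvalue
#' @inheritParams match_organisms
#' @return A `mirrortree_result`; see [permutation_pvalue()].
#' @export
mirror_trees <- function(x, y, B = 999, seed = NULL,
                         alternative = c("two.sided", "greater"), min_n = 4) {
  M1 <- if (inherits(x, "phylo")) patristic_matrix(x) else x
  M2 <- if (inherits(y, "phylo")) patristic_matrix(y) else y
  pair <- match_organisms(M1, M2, min_n = min_n)
  permutation_pvalue(pair, B = B, seed = seed, alternative = alternative)
}

#' @export
print.mirrortree_result <- function(x, ...) {
  cat("Mirrortree tree-similarity test\n")
  cat(sprintf("  common organisms N = %d (n = %d distance pairs)\n", x$N, x$n))
  cat(sprintf("  correlation r = %.4f\n", x$r))
  cat(sprintf("  permutation p-value = %.4g (%s, B = %d)\n",
              x$p_value, x$alternative, x$B_permutations))
  invisible(x)
}

#' Tidy a mirrortree result
#'
#' @param x A `mirrortree_result`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate` (r), `p.value`,
#'   `n_organisms`, `n_pairs`, `permutations` and `alternative`;
#'   `glance()` adds the seed.
#' @export
tidy.mirrortree_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_value,
                 n_organisms = x$N, n_pairs = x$n,
                 permutations = x$B_permutations,
                 alternative = x$alternative)
}

#' @rdname tidy.mirrortree_result
#' @method glance mirrortree_result
#' @export
glance.mirrortree_result <- function(x, ...) {
  out <- tidy.mirrortree_result(x)
  out$seed <- if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  out
}

#' Plot a mirrortree result
#'
#' `type = "scatter"` draws the inter-protein distance scatterplot (family 1
#' distances against family 2 distances for every organism pair), the usual
#' visual of the mirrortree signal; `type = "null"` shows the permutation
#' distribution of r with the observed value marked.
#'
#' @param object A `mirrortree_result`.
#' @param type `"scatter"` or `"null"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirrortree_result
#' @export
autoplot.mirrortree_result <- function(object, type = c("scatter", "null"),
                                       ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    df <- tibble::tibble(R = object$R, S = object$S)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$S)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.5, colour = "firebrick") +
      ggplot2::labs(
        x = "family 1 inter-protein distance",
        y = "family 2 inter-protein distance",
        title = sprintf("mirrortree r = %.3f (p = %.3g)",
                        object$r, object$p_value))
  } else {
    df <- tibble::tibble(r = object$r_perm)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
      ggplot2::geom_vline(xintercept = object$r, colour = "firebrick") +
      ggplot2::labs(x = "permutation r", y = "count",
                    title = sprintf("observed r = %.3f, p = %.3g",
                                    object$r, object$p_value))
  }
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
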