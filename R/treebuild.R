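# Neighbor-joining, patristic distances and newick I/O.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration on the Q-criterion. For reproducibility
#' ties in the Q minimum are broken by the smallest (row, column) index pair.
#' A negative estimated branch length is clamped to zero and its deficit is
#' transferred to the sister branch, so the length of the path joining the
#' two merged taxa is preserved (this is the usual practice and matters for
#' downstream patristic sums). NJ is exact on additive matrices: it recovers
#' the generating topology and branch lengths.
#'
#' @param D A labeled symmetric distance matrix with at least 3 rows.
#' @return An unrooted `ape::phylo` tree whose tip labels are the matrix
#'   labels.
#' @export
nj_tree <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop_input("neighbor-joining needs at least 3 taxa, got %d", n)

  frag <- newick_quote(rownames(D))
  d <- unname(D)

  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    merged <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li), frag[j], fmt_len(lj))
    du <- pmax((d[i, ] + d[j, ] - d[i, j]) / 2, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], merged)
    n <- n - 1L
  }

  a <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  b <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  c3 <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt_len(a), frag[2], fmt_len(b), frag[3], fmt_len(c3))
  ape::read.tree(text = nwk)
}

#' Patristic distance matrix of a tree
#'
#' The patristic distance between two leaves is the sum of the branch
#' lengths along the unique path joining them. Labels of the returned
#' matrix are sorted lexicographically.
#'
#' @param tree An `ape::phylo` tree with branch lengths and >= 2 leaves.
#' @return A labeled symmetric matrix of patristic distances.
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("not a phylo tree")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop_input("patristic distances need at least 2 leaves")
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop_input("missing branch length on edge %d -> %d",
               tree$edge[bad, 1], tree$edge[bad, 2])
  }

  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[p]] <- rbind(adj[[p]], c(ch, w))
    adj[[ch]] <- rbind(adj[[ch]], c(p, w))
  }

  D <- matrix(0, ntip, ntip)
  for (tip in seq_len(ntip)) {
    dist <- rep(NA_real_, nnode)
    dist[tip] <- 0
    queue <- tip
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        u <- nb[k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nb[k, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[tip, ] <- dist[seq_len(ntip)]
  }
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  ord <- order(tree$tip.label)
  D[ord, ord]
}

#' Read / write trees in newick format
#'
#' Thin validated wrappers around `ape::read.tree()` / `ape::write.tree()`.
#' Support values travel as internal node labels and branch lengths are
#' written with enough digits to round-trip.
#'
#' @param x A newick string or a file path containing one.
#' @param tree An `ape::phylo` tree.
#' @param path Output file, or `NULL` to return the newick string.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` the
#'   newick string (invisibly when written to a file).
#' @export
read_newick <- function(x) {
  text <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  bal <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
  if (length(bal) == 0L || any(bal < 0) || bal[length(bal)] != 0) {
    pos <- if (length(bal) && any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop_input("newick parse error: unbalanced parentheses at position %d", pos)
  }
  if (!grepl(";\\s*$", text)) stop_input("newick parse error: missing terminal ';'")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop_input("newick parse error in '%s'", substr(text, 1, 40))
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop_input("not a phylo tree")
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
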