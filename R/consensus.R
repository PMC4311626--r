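# Bootstrap resampling and support-thresholded consensus trees.

#' Bootstrap NJ trees from an aligned family
#'
#' Resamples alignment columns with replacement (keeping alignment length),
#' recomputes the distance matrix under the chosen gap policy and correction,
#' and rebuilds the NJ tree, `B` times. Given the same seed the replicate
#' list is identical.
#'
#' @param family An aligned [protein_family()].
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @param gap_policy,correction Passed to the distance stage;
#'   `correction = "poisson"` applies [poisson_correct()].
#' @return An object of class `bootstrap_set`: list with `trees`, `B`, `seed`.
#' @export
bootstrap_trees <- function(family, B = 100, seed = NULL,
                            gap_policy = c("complete_deletion",
                                           "pairwise_deletion"),
                            correction = c("poisson", "none")) {
  gap_policy <- match.arg(gap_policy)
  correction <- match.arg(correction)
  if (!is_count(B)) stop_input("`B` must be a positive integer")
  if (!inherits(family, "protein_family") || !family$aligned) {
    stop_input("bootstrap needs an aligned protein_family")
  }
  m <- family_matrix(family)
  L <- ncol(m)
  fam_b <- family
  trees <- with_seed_if(seed, lapply(seq_len(B), function(b) {
    idx <- sample.int(L, L, replace = TRUE)
    fam_b$records$sequence <- apply(m[, idx, drop = FALSE], 1L, paste,
                                    collapse = "")
    tryCatch({
      D <- p_distance_matrix(fam_b, gap_policy)
      if (correction == "poisson") D <- poisson_correct(D)
      nj_tree(D)
    }, mirrortree_error = function(e) {
      abort(sprintf("bootstrap replicate %d: %s", b, conditionMessage(e)),
            class = intersect(class(e),
                              c("mirrortree_input_error",
                                "mirrortree_degenerate_error",
                                "mirrortree_error")))
    })
  }))
  structure(list(trees = trees, B = B, seed = seed), class = "bootstrap_set")
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat(sprintf("<bootstrap_set: %d replicate trees, %d leaves>\n", x$B,
              length(x$trees[[1]]$tip.label)))
  invisible(x)
}

# Non-trivial splits of one tree as canonical leaf subsets (the side not
# containing the reference leaf), with the corresponding branch length.
# A rooted binary tree presents the root bipartition twice; the two root
# edges are merged and their lengths summed (the unrooted branch).
tree_splits <- function(tr, ref, all_labels) {
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  eo <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    below[[eo$edge[e, 1]]] <- c(below[[eo$edge[e, 1]]], below[[eo$edge[e, 2]]])
  }
  keys <- character(0); lens <- numeric(0); members <- list()
  internal <- which(tr$edge[, 2] > ntip)
  for (e in internal) {
    mem <- below[[tr$edge[e, 2]]]
    if (ref %in% mem) mem <- setdiff(all_labels, mem)
    if (length(mem) < 2L || length(mem) > length(all_labels) - 2L) next
    mem <- sort(mem)
    key <- paste(mem, collapse = "\x1f")
    len <- if (is.null(tr$edge.length)) 0 else tr$edge.length[e]
    at <- match(key, keys)
    if (is.na(at)) {
      keys <- c(keys, key); lens <- c(lens, len); members <- c(members, list(mem))
    } else {
      lens[at] <- lens[at] + len
    }
  }
  list(keys = keys, lens = lens, members = members)
}

#' Majority-rule-extended consensus with support collapse
#'
#' Counts the bipartitions of the replicate trees, greedily assembles the
#' extended majority-rule consensus (bipartitions admitted in order of
#' decreasing frequency when compatible with those already kept), and then
#' contracts every internal edge whose bootstrap support is below
#' `threshold_pct`. Supports (percent of replicates) annotate the remaining
#' internal edges as node labels; branch lengths are averaged over the
#' replicates containing each bipartition.
#'
#' @param bs A `bootstrap_set` or a plain list of `phylo` trees sharing one
#'   leaf set.
#' @param threshold_pct Collapse threshold in percent (default 45): edges
#'   supported by fewer than this percentage of replicates are removed.
#' @return An `ape::phylo` consensus tree with supports as node labels.
#' @export
consensus_collapse <- function(bs, threshold_pct = 45) {
  trees <- if (inherits(bs, "bootstrap_set")) bs$trees else bs
  if (!length(trees)) stop_input("need at least one replicate tree")
  if (!is.numeric(threshold_pct) || threshold_pct < 0 || threshold_pct > 100) {
    stop_input("`threshold_pct` must lie in [0, 100]")
  }
  B <- length(trees)
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labels)) {
      stop_input("replicate trees do not share one leaf label set")
    }
  }
  ref <- labels[1]

  keys <- character(0); count <- integer(0); lensum <- numeric(0)
  members <- list()
  leaf_len <- stats::setNames(numeric(length(labels)), labels)
  for (tr in trees) {
    sp <- tree_splits(tr, ref, labels)
    for (k in seq_along(sp$keys)) {
      at <- match(sp$keys[k], keys)
      if (is.na(at)) {
        keys <- c(keys, sp$keys[k]); count <- c(count, 1L)
        lensum <- c(lensum, sp$lens[k]); members <- c(members, list(sp$members[[k]]))
      } else {
        count[at] <- count[at] + 1L
        lensum[at] <- lensum[at] + sp$lens[k]
      }
    }
    if (!is.null(tr$edge.length)) {
      tip_edges <- tr$edge[, 2] <= length(tr$tip.label)
      leaf_len[tr$tip.label[tr$edge[tip_edges, 2]]] <-
        leaf_len[tr$tip.label[tr$edge[tip_edges, 2]]] +
        tr$edge.length[tip_edges]
    }
  }
  leaf_len <- leaf_len / B
  support <- 100 * count / B
  mean_len <- ifelse(count > 0, lensum / count, 0)

  # Greedy extended-majority assembly, then threshold filter.
  ord <- order(-count, keys)
  kept <- integer(0)
  for (i in ord) {
    compatible <- all(vapply(kept, function(j) {
      a <- members[[i]]; b <- members[[j]]
      length(intersect(a, b)) == 0L || all(a %in% b) || all(b %in% a)
    }, logical(1)))
    if (compatible) kept <- c(kept, i)
  }
  kept <- kept[support[kept] >= threshold_pct]

  build_split_tree(labels, ref, members[kept], support[kept], mean_len[kept],
                   leaf_len)
}

# Assemble a phylo tree from a laminar family of canonical splits.
build_split_tree <- function(labels, ref, mem, support, len, leaf_len) {
  ns <- length(mem)
  sizes <- vapply(mem, length, integer(1))
  parent <- rep(0L, ns)              # 0 = root
  for (i in seq_len(ns)) {
    containing <- which(sizes > sizes[i] &
                          vapply(seq_len(ns), function(j)
                            j != i && all(mem[[i]] %in% mem[[j]]), logical(1)))
    if (length(containing)) parent[i] <- containing[which.min(sizes[containing])]
  }
  leaf_parent <- vapply(labels, function(lb) {
    containing <- which(vapply(mem, function(m) lb %in% m, logical(1)))
    if (length(containing)) containing[which.min(sizes[containing])] else 0L
  }, integer(1))

  leaf_str <- function(lb) sprintf("%s:%s", newick_quote(lb), fmt_len(leaf_len[[lb]]))
  rec <- function(i) {
    parts <- c(vapply(labels[leaf_parent == i], leaf_str, character(1)),
               vapply(which(parent == i), rec, character(1)))
    sprintf("(%s)%s:%s", paste(parts, collapse = ","),
            formatC(support[i], digits = 6, format = "g"), fmt_len(len[i]))
  }
  root_parts <- c(vapply(labels[leaf_parent == 0L], leaf_str, character(1)),
                  vapply(which(parent == 0L), rec, character(1)))
  ape::read.tree(text = sprintf("(%s);", paste(root_parts, collapse = ",")))
}
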