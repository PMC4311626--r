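# Independent oracles used to check the implementation paths.

# Patristic distances via root depths and most-recent-common-ancestor lookup:
# d(i, j) = depth(i) + depth(j) - 2 * depth(mrca(i, j)). Independent of the
# graph-walk used by patristic_matrix().
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- rep(NA_integer_, nnode)
  plen <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  depth <- function(v) {
    d <- 0
    while (!is.na(parent[v])) { d <- d + plen[v]; v <- parent[v] }
    d
  }
  ancestors <- function(v) {
    out <- v
    while (!is.na(parent[v])) { v <- parent[v]; out <- c(out, v) }
    out
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  dep <- vapply(seq_len(nnode), depth, numeric(1))
  anc <- lapply(seq_len(ntip), ancestors)
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      mrca <- intersect(anc[[i]], anc[[j]])[1]
      D[i, j] <- D[j, i] <- dep[i] + dep[j] - 2 * dep[mrca]
    }
  }
  ord <- order(tree$tip.label)
  D[ord, ord]
}

# Naive quadratic lipobox scan: test every window of four residues.
oracle_lipobox <- function(sequence, window = 40) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(max(nchar(sequence) - 3L, 0L))) {
    if (chars[i] %in% c("V", "L") && chars[i + 3L] == "C" &&
        i + 3L <= window) {
      hits <- c(hits, i)
    }
  }
  hits
}

# A random unrooted tree with branch lengths U(0.05, 1); its patristic
# matrix is additive by construction.
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr$tip.label <- sprintf("org_%03d", sample(seq_len(n)))
  tr
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

toy_family <- function(seqs, orgs = NULL, ids = NULL, name = "toy") {
  if (is.null(orgs)) orgs <- sprintf("org%02d", seq_along(seqs))
  if (is.null(ids)) ids <- orgs
  protein_family(tibble::tibble(id = ids, organism = orgs, sequence = seqs),
                 name = name)
}

# Distance matrix from an upper-triangle vector, for correlation tests.
mat_from_upper <- function(v, labels) {
  n <- length(labels)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  M[upper.tri(M)] <- v
  M + t(M)
}

# A family of sequences diverged from one ancestor: realistic pairwise
# p-distances (roughly 2 * mut), well inside the Poisson-correction domain.
related_family <- function(n, len, mut = 0.15, name = "related") {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  anc <- sample(aa, len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    x <- anc
    hit <- stats::runif(len) < mut
    x[hit] <- sample(aa, sum(hit), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  toy_family(seqs, name = name)
}
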