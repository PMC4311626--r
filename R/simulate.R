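# Synthetic coevolving / independent protein family pairs.

#' Simulation configuration
#'
#' Bundles the parameters of the family-pair generator. The defaults define
#' the package's reference study condition: 20 organisms on a Yule species
#' tree with per-lineage birth rate 10 (mean root-to-tip depth about 0.26
#' substitutions per site, a typical within-family divergence that keeps
#' corrected distances well below saturation), alignments of 200 columns, and per-family
#' lognormal rate scalars with sdlog 0.3 — the realistic between-family rate
#' variation that makes correlation, not equality, the right similarity
#' statistic.
#'
#' @param n_organisms Number of organisms (>= 4).
#' @param birth_rate Per-lineage birth rate of the Yule species tree.
#' @param seq_length Alignment columns (>= 1).
#' @param mode `"coevolving"` (both families evolve along the same species
#'   tree) or `"independent"` (each family gets its own tree over the same
#'   organism labels).
#' @param rate_sigma sdlog of the lognormal per-family rate scalar (>= 0).
#' @param distant_clade If `TRUE`, a long-branch clade of extra organisms
#'   (20 percent of `n_organisms`, stem three times the tree height) is
#'   grafted onto the species tree(s), emulating the addition of distant
#'   homologs to both families.
#' @param gap_fraction Fraction of alignment cells gapped at random
#'   (in \[0, 0.5\]).
#' @param seed Optional master seed; all stage seeds derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_organisms = 20, birth_rate = 10,
                              seq_length = 200,
                              mode = c("coevolving", "independent"),
                              rate_sigma = 0.3, distant_clade = FALSE,
                              gap_fraction = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!is_count(n_organisms, min = 4)) stop_input("`n_organisms` must be an integer >= 4")
  if (!is.numeric(birth_rate) || birth_rate <= 0) stop_input("`birth_rate` must be positive")
  if (!is_count(seq_length, min = 1)) stop_input("`seq_length` must be an integer >= 1")
  if (!is.numeric(rate_sigma) || rate_sigma < 0) stop_input("`rate_sigma` must be >= 0")
  if (!is.numeric(gap_fraction) || gap_fraction < 0 || gap_fraction > 0.5) {
    stop_input("`gap_fraction` must lie in [0, 0.5]")
  }
  structure(list(n_organisms = as.integer(n_organisms),
                 birth_rate = birth_rate,
                 seq_length = as.integer(seq_length), mode = mode,
                 rate_sigma = rate_sigma,
                 distant_clade = isTRUE(distant_clade),
                 gap_fraction = gap_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Starts from two lineages at the root; while k lineages are alive the
#' waiting time to the next split is exponential with rate
#' `birth_rate * k`, and a uniformly chosen lineage splits. After the n-th
#' lineage appears a final exponential waiting time ends the simulation, so
#' the expected tree height is \eqn{\sum_{k=2}^{n} 1/(\lambda k)}. The tree
#' is ultrametric with leaves labeled `org_001`, `org_002`, ...
#'
#' @param n_organisms Number of leaves (>= 2).
#' @param birth_rate Per-lineage birth rate.
#' @param seed Optional integer seed.
#' @param labels Optional leaf label vector of length `n_organisms`.
#' @return An `ape::phylo` tree.
#' @export
simulate_species_tree <- function(n_organisms, birth_rate = 10, seed = NULL,
                                  labels = NULL) {
  if (!is_count(n_organisms, min = 2)) stop_input("`n_organisms` must be an integer >= 2")
  if (is.null(labels)) labels <- sprintf("org_%03d", seq_len(n_organisms))
  if (length(labels) != n_organisms) stop_input("need one label per organism")

  with_seed_if(seed, {
    parent <- c(0L, 0L)         # 0 = root
    birth <- c(0, 0)
    split_time <- c(NA_real_, NA_real_)
    active <- c(1L, 2L)
    t <- 0
    k <- 2L
    while (k < n_organisms) {
      t <- t + stats::rexp(1, birth_rate * k)
      pick <- active[sample.int(k, 1L)]
      ids <- length(parent) + 1:2
      parent <- c(parent, pick, pick)
      birth <- c(birth, t, t)
      split_time <- c(split_time, NA_real_, NA_real_)
      split_time[pick] <- t
      active <- c(setdiff(active, pick), ids)
      k <- k + 1L
    }
    t_end <- t + stats::rexp(1, birth_rate * n_organisms)

    children <- split(seq_along(parent), parent)
    # Labels are assigned to leaves in random order: lineage creation order
    # carries topological information, and organism labels must be
    # exchangeable for the permutation null to hold.
    leaf_label <- rep(NA_character_, length(parent))
    leaf_label[sort(active)] <- sample(labels)
    rec <- function(v) {
      len <- fmt_len((if (is.na(split_time[v])) t_end else split_time[v]) - birth[v])
      kids <- children[[as.character(v)]]
      if (is.null(kids)) {
        sprintf("%s:%s", newick_quote(leaf_label[v]), len)
      } else {
        sprintf("(%s,%s):%s", rec(kids[1]), rec(kids[2]), len)
      }
    }
    root_kids <- children[["0"]]
    ape::read.tree(text = sprintf("(%s,%s);", rec(root_kids[1]), rec(root_kids[2])))
  })
}

tree_height <- function(tree) max(ape::node.depth.edgelength(tree))

# Graft a long-branch clade of extra organisms onto `tree`: new root with
# the old tree on a zero-length edge and the clade on a stem of three times
# the base tree height.
graft_distant_clade <- function(tree, birth_rate, labels, seed = NULL) {
  clade <- simulate_species_tree(length(labels), birth_rate = birth_rate,
                                 seed = seed, labels = labels)
  stem <- 3 * tree_height(tree)
  base <- sub(";\\s*$", "", write_newick(tree))
  cl <- sub(";\\s*$", "", write_newick(clade))
  ape::read.tree(text = sprintf("(%s:0,%s:%s);", base, cl, fmt_len(stem)))
}

#' Evolve an aligned protein family along a tree
#'
#' The root sequence is uniform over the 20 amino acids. Along each branch
#' of length t every site substitutes, independently, with probability
#' \eqn{(19/20)(1 - e^{-20 t \rho / 19})} (the exact transition probability
#' of the 20-state equal-rates Poisson model at rate scalar \eqn{\rho}),
#' moving to a uniformly chosen different residue. Optionally a fraction of
#' alignment cells is replaced by gaps at random.
#'
#' @param tree Species tree whose tip labels are the organisms.
#' @param seq_length Number of alignment columns.
#' @param rate_scalar Positive per-family rate multiplier.
#' @param gap_fraction Fraction of cells gapped (in \[0, 0.5\]).
#' @param seed Optional integer seed.
#' @param name Family name.
#' @return An aligned [protein_family()] with one record per organism
#'   (id = organism = tip label).
#' @export
evolve_family <- function(tree, seq_length, rate_scalar = 1, gap_fraction = 0,
                          seed = NULL, name = "sim_family") {
  if (!inherits(tree, "phylo")) stop_input("not a phylo tree")
  if (!is.numeric(rate_scalar) || rate_scalar <= 0) {
    stop_input("`rate_scalar` must be positive")
  }
  if (!is_count(seq_length, min = 1)) stop_input("`seq_length` must be an integer >= 1")
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children

  with_seed_if(seed, {
    seqs <- vector("list", ntip + tr$Nnode)
    seqs[[ntip + 1L]] <- sample.int(20L, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      t_eff <- tr$edge.length[e] * rate_scalar
      psub <- (19 / 20) * (1 - exp(-20 * t_eff / 19))
      s <- seqs[[p]]
      change <- which(stats::runif(seq_length) < psub)
      if (length(change)) {
        s[change] <- (s[change] - 1L +
                        sample.int(19L, length(change), replace = TRUE)) %% 20L + 1L
      }
      seqs[[ch]] <- s
    }
    chars <- vapply(seq_len(ntip), function(i) {
      x <- AA20[seqs[[i]]]
      if (gap_fraction > 0) {
        x[stats::runif(seq_length) < gap_fraction] <- "-"
      }
      paste(x, collapse = "")
    }, character(1))
    protein_family(tibble::tibble(id = tr$tip.label, organism = tr$tip.label,
                                  sequence = chars),
                   name = name, aligned = TRUE)
  })
}

#' Generate a pair of protein families
#'
#' In `coevolving` mode both families evolve along the same species tree
#' with independent lognormal rate scalars, so their patristic structures
#' mirror each other up to rate scaling and sampling noise. In
#' `independent` mode each family evolves along its own independently drawn
#' Yule tree over the same organism labels — the null of the mirrortree
#' test. With `distant_clade = TRUE` a shared long-branch clade of extra
#' organisms is grafted on, mimicking the enlargement of both families with
#' distant homologs.
#'
#' @param config A [simulation_config()].
#' @return A list with `family1`, `family2` (aligned [protein_family()]s),
#'   `tree1`, `tree2` (identical in coevolving mode), `rate_scalars` and
#'   `config`.
#' @export
make_family_pair <- function(config) {
  if (!inherits(config, "simulation_config")) stop_input("not a simulation_config")
  n <- config$n_organisms
  seed <- config$seed
  extra <- if (config$distant_clade) {
    sprintf("org_%03d", n + seq_len(max(2L, ceiling(0.2 * n))))
  } else {
    character(0)
  }

  build_tree <- function(s_tree, s_clade) {
    tr <- simulate_species_tree(n, config$birth_rate, seed = s_tree)
    if (length(extra)) {
      tr <- graft_distant_clade(tr, config$birth_rate, extra, seed = s_clade)
    }
    tr
  }

  tree1 <- build_tree(derive_seed(seed, 1), derive_seed(seed, 6))
  tree2 <- if (config$mode == "coevolving") {
    tree1
  } else {
    build_tree(derive_seed(seed, 2), derive_seed(seed, 7))
  }

  rates <- if (config$rate_sigma == 0) {
    c(1, 1)
  } else {
    with_seed_if(derive_seed(seed, 3),
                 stats::rlnorm(2, meanlog = 0, sdlog = config$rate_sigma))
  }

  fam1 <- evolve_family(tree1, config$seq_length, rates[1],
                        config$gap_fraction, seed = derive_seed(seed, 4),
                        name = "family1")
  fam2 <- evolve_family(tree2, config$seq_length, rates[2],
                        config$gap_fraction, seed = derive_seed(seed, 5),
                        name = "family2")
  list(family1 = fam1, family2 = fam2, tree1 = tree1, tree2 = tree2,
       rate_scalars = rates, config = config)
}

#' Write a simulated pair to disk
#'
#' Writes the two aligned FASTA files, the true species tree(s) in newick,
#' and a JSON sidecar with the full configuration (including the seed).
#'
#' @param pair A [make_family_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_simulation <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    family1 = file.path(dir, "family1.fasta"),
    family2 = file.path(dir, "family2.fasta"),
    tree1 = file.path(dir, "species_tree1.nwk"),
    config = file.path(dir, "config.json")
  )
  write_family(pair$family1, paths[["family1"]])
  write_family(pair$family2, paths[["family2"]])
  write_newick(pair$tree1, paths[["tree1"]])
  if (!identical(pair$tree1, pair$tree2)) {
    paths[["tree2"]] <- file.path(dir, "species_tree2.nwk")
    write_newick(pair$tree2, paths[["tree2"]])
  }
  cfg <- pair$config
  cfg_list <- unclass(cfg)
  cfg_list$rate_scalars <- pair$rate_scalars
  jsonlite::write_json(cfg_list, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
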