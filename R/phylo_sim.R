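# Synthetic-data generator: Yule phylogeny + 20-state Jukes-Cantor-style
# substitution along branches, clade labels from a root-distance cut, and an
# optional smooth latent-linked fitness. Everything is a pure function of
# (configuration, seed), so all downstream modules are testable without any
# real family download.

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Pure-birth tree with exponential waiting times (unit birth rate), rooted,
#' with branch lengths in units of evolutionary time; Newick-serialisable
#' via [ape::write.tree()].
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Seed.
#' @param birth Birth rate (default 1).
#' @return An [ape::rphylo()] `phylo` object with leaf labels `t1..tN`.
#' @export
simulate_tree <- function(n_leaves, seed = 42L, birth = 1) {
  stopifnot(n_leaves >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = birth, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

#' Evolve aligned protein sequences along a tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch
#' of length t every site substitutes independently with probability
#' `1 - exp(-rate * t)`, drawing the new residue uniformly from the other
#' 19 states (a Jukes-Cantor-style model on 20 states). The result is a
#' gap-free alignment of length L, one row per leaf.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param L Alignment length (sites).
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Seed.
#' @return An `aligned_family` whose ids are the tree's leaf labels (rows in
#'   leaf-label order).
#' @export
evolve_sequences <- function(tree, L, rate = 0.3, seed = 42L) {
  stopifnot(inherits(tree, "phylo"), L >= 1, rate >= 0)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  seqs <- matrix(0L, n_tip + n_node, L)
  root <- n_tip + 1L
  seqs[root, ] <- sample.int(20L, L, replace = TRUE)
  # visit edges parent-before-child
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t_br <- ord$edge.length[e]
    s <- seqs[par, ]
    hit <- stats::runif(L) < (1 - exp(-rate * t_br))
    if (any(hit)) {
      # uniform over the 19 other residues
      shift <- sample.int(19L, sum(hit), replace = TRUE)
      s[hit] <- 1L + (s[hit] - 1L + shift) %% 20L
    }
    seqs[child, ] <- s
  }
  fam <- new_raw_family(tree$tip.label,
                        apply(seqs[seq_len(n_tip), , drop = FALSE], 1,
                              function(r) .codes_to_string(r)))
  as_aligned_family(fam)
}

#' Clade labels from a root-distance cut
#'
#' Cuts the tree at a fixed evolutionary distance from the root: each leaf
#' is labelled by the first ancestor (or itself) whose root distance reaches
#' the threshold, so each subtree hanging below the cut forms one group.
#' Sequences grouped this way share recent ancestry and cluster together in
#' a faithful latent embedding.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param threshold Cut distance from the root (> 0). A threshold beyond the
#'   tree height yields a single group, with a warning.
#' @return Integer vector of group labels, one per leaf, named by leaf label.
#' @export
clade_labels <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), threshold > 0)
  depth <- ape::node.depth.edgelength(tree)   # root distance per node
  n_tip <- length(tree$tip.label)
  if (threshold > max(depth[seq_len(n_tip)])) {
    warning("threshold exceeds tree height; single group", call. = FALSE)
    return(stats::setNames(rep(1L, n_tip), tree$tip.label))
  }
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  anchor <- integer(n_tip)
  for (leaf in seq_len(n_tip)) {
    node <- leaf
    # climb while the parent is still at or past the threshold
    while (node != root && parent[node] != root &&
           depth[parent[node]] >= threshold) {
      node <- parent[node]
    }
    # node is the shallowest ancestor with depth >= threshold (or the leaf)
    anchor[leaf] <- if (depth[node] >= threshold) node else leaf
  }
  stats::setNames(as.integer(factor(anchor, levels = unique(anchor))),
                  tree$tip.label)
}

#' Cut distance yielding a fixed number of clades
#'
#' For an ultrametric tree, the number of groups produced by a root-distance
#' cut equals the number of lineages alive at that distance. This returns
#' the midpoint between the (k-1)-th and k-th branching depths, so
#' [clade_labels()] at the returned threshold yields exactly `k` groups.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param k Desired number of clades (2 <= k <= leaves).
#' @return A cut distance from the root.
#' @export
clade_cut_for_groups <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  stopifnot(k >= 2, k <= n_tip)
  depth <- ape::node.depth.edgelength(tree)
  splits <- sort(depth[(n_tip + 1L):(n_tip + tree$Nnode)])  # root first (0)
  if (k - 1L >= length(splits)) return(max(depth) - 1e-9)
  (splits[k - 1L] + splits[k]) / 2
}

#' Attach a smooth fitness value to a simulated family
#'
#' Emulates a fitness landscape over the family: each clade receives an
#' effect drawn once from N(0, clade_sd), each leaf adds a linear term in
#' its root depth, plus Gaussian measurement noise. The noiseless values are
#' recorded in the `components` attribute for recovery tests. The default
#' baseline of 55 with clade_sd 5 puts values on a T50-like scale (degrees
#' C in the 40-70 range).
#'
#' @param tree The `phylo` the family was evolved on.
#' @param labels Clade labels from [clade_labels()].
#' @param seed Seed.
#' @param baseline Mean fitness level.
#' @param clade_sd SD of the per-clade effects.
#' @param depth_slope Fitness change per unit root depth.
#' @param noise_sd SD of the additive measurement noise (0 = noiseless).
#' @return Named numeric vector of fitness values (one per leaf) with a
#'   `components` attribute (data frame: clade effect, depth term, noise).
#' @export
attach_fitness <- function(tree, labels, seed = 42L, baseline = 55,
                           clade_sd = 5, depth_slope = 1.5, noise_sd = 0.5) {
  stopifnot(inherits(tree, "phylo"), noise_sd >= 0)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  stopifnot(length(labels) == n_tip)
  depth <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  eff <- stats::rnorm(length(unique(labels)), sd = clade_sd)
  smooth <- baseline + eff[labels] + depth_slope * (depth - mean(depth))
  noise <- if (noise_sd > 0) stats::rnorm(n_tip, sd = noise_sd) else numeric(n_tip)
  out <- stats::setNames(smooth + noise, tree$tip.label)
  attr(out, "components") <- data.frame(id = tree$tip.label, smooth = smooth,
                                        clade = as.integer(labels),
                                        depth = depth, noise = noise)
  out
}

#' Simulate a complete labelled family
#'
#' One-call wrapper: Yule tree, evolved alignment, clade labels at the given
#' cut distance, and fitness values. Sub-seeds for the tree, the sequences
#' and the fitness are derived deterministically from `seed`.
#'
#' @param n_leaves Leaves / sequences (desk-scale default 300; a full-scale
#'   simulation would use 10000 leaves with a cut distance of 2.4).
#' @param L Alignment length.
#' @param rate Substitution rate per site per unit branch length.
#' @param threshold Clade cut distance from the root; ignored when
#'   `n_clades` is given.
#' @param n_clades Optional exact clade count; the cut distance is then
#'   derived from the tree's branching depths via [clade_cut_for_groups()].
#' @param seed Seed.
#' @param noise_sd Fitness noise SD.
#' @return A `sim_family` list: `family` (aligned_family), `tree` (phylo),
#'   `labels`, `fitness`.
#' @export
simulate_family <- function(n_leaves = 300L, L = 60L, rate = 0.3,
                            threshold = 1.2, n_clades = NULL, seed = 42L,
                            noise_sd = 0.5) {
  tree <- simulate_tree(n_leaves, seed = seed)
  fam <- evolve_sequences(tree, L, rate, seed = seed + 1L)
  if (!is.null(n_clades)) threshold <- clade_cut_for_groups(tree, n_clades)
  labels <- clade_labels(tree, threshold)
  fitness <- attach_fitness(tree, labels, seed = seed + 2L, noise_sd = noise_sd)
  structure(list(family = fam, tree = tree, labels = labels,
                 fitness = fitness),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("sim_family: %d leaves, L=%d, %d clades\n",
              length(x$labels), x$family$L, length(unique(x$labels))))
  invisible(x)
}

#' Mean silhouette of an embedding against labels
#'
#' Mean silhouette coefficient (Euclidean distance) of the latent embedding
#' with respect to clade labels: positive when same-clade sequences sit
#' closer to each other than to other clades, about zero for arbitrary
#' labels, nonpositive for coincident clusters.
#'
#' @param embeddings N x d numeric matrix.
#' @param labels Integer/factor labels; at least 2 distinct labels, each
#'   with at least 2 members.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
latent_separation_score <- function(embeddings, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for a single label")
  if (min(table(labels)) < 2)
    stop("each label needs at least 2 members")
  sil <- cluster::silhouette(labels, stats::dist(embeddings))
  mean(sil[, "sil_width"])
}

#' Write simulated-family artifacts
#'
#' @param sim A `sim_family`.
#' @param dir Output directory (created if needed): `family.fasta`,
#'   `tree.nwk`, `labels.tsv`, `fitness.tsv`.
#' @return The directory, invisibly.
#' @export
write_sim_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aligned_fasta(sim$family, file.path(dir, "family.fasta"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(data.frame(id = names(sim$labels), clade = sim$labels),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(id = names(sim$fitness),
                                fitness = as.numeric(sim$fitness)),
                     file.path(dir, "fitness.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
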