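test_that("Yule simulation returns seeded trees of the right size", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_s3_class(tr2, "phylo")
  expect_equal(length(tr2$tip.label), 2)

  t1 <- simulate_tree(100, seed = 9)
  t2 <- simulate_tree(100, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  set.seed(33)
  for (n in sample(2:80, 10))
    expect_equal(length(simulate_tree(n, seed = n)$tip.label), n)
})

test_that("sequence evolution respects the rate limits", {
  tree <- simulate_tree(20, seed = 3)
  # rate 0: all leaves identical to the root (and to each other)
  frozen <- evolve_sequences(tree, L = 30, rate = 0, seed = 4)
  expect_equal(nrow(unique(frozen$matrix)), 1)

  # saturation: enormous rate drives pairwise identity to ~1/20
  hot <- evolve_sequences(tree, L = 1000, rate = 50, seed = 5)
  pairs <- combn(nrow(hot$matrix), 2)
  ident <- apply(pairs, 2, function(p)
    mean(hot$matrix[p[1], ] == hot$matrix[p[2], ]))
  expect_lt(abs(mean(ident) - 0.05), 0.01)
  # gap-free alignment over the 20 amino acids
  expect_true(all(hot$matrix >= 1 & hot$matrix <= 20))
})

test_that("tree structure leaves a similarity signal in the sequences", {
  tree <- simulate_tree(100, seed = 6)
  fam <- evolve_sequences(tree, L = 200, rate = 0.3, seed = 7)
  D <- ape::cophenetic.phylo(tree)[fam$ids, fam$ids]
  set.seed(8)
  pairs <- t(combn(100, 2))
  pairs <- pairs[sample(nrow(pairs), 400), ]
  ident <- apply(pairs, 1, function(p)
    mean(fam$matrix[p[1], ] == fam$matrix[p[2], ]))
  patristic <- D[pairs]
  # identity decays with patristic distance
  expect_lt(cor(ident, patristic, method = "spearman"), 0)

  # sister leaves beat random pairs on average
  sisters <- which(tree$edge[, 2] <= 100)
  sis_pairs <- split(tree$edge[sisters, 2], tree$edge[sisters, 1])
  sis_pairs <- Filter(function(x) length(x) == 2, sis_pairs)
  sis_id <- vapply(sis_pairs, function(p)
    mean(fam$matrix[p[1], ] == fam$matrix[p[2], ]), numeric(1))
  expect_gt(mean(sis_id), mean(ident))
})

test_that("clade labelling cuts behave at both extremes and in between", {
  tree <- simulate_tree(50, seed = 10)
  # shallow cut: one group per child of the root
  shallow <- clade_labels(tree, 1e-9)
  expect_equal(length(unique(shallow)), 2)
  # cut beyond the height: single group with a warning
  h <- max(ape::node.depth.edgelength(tree))
  expect_warning(deep <- clade_labels(tree, h + 1), "single group")
  expect_equal(unique(unname(deep)), 1L)

  # constructed balanced tree: root children at depth 1, four inner nodes
  # at depth 2, tips at depth 4; a cut between 1 and 2 isolates 4 clades
  txt <- "(((a:2,b:2):1,(c:2,d:2):1):1,((e:2,f:2):1,(g:2,h:2):1):1);"
  bal <- ape::read.tree(text = txt)
  expect_equal(length(unique(clade_labels(bal, 1.5))), 4)
  expect_equal(length(unique(clade_labels(bal, 0.5))), 2)

  # derived cut distance yields the requested group count
  for (k in c(3, 4, 6)) {
    thr <- clade_cut_for_groups(tree, k)
    expect_equal(length(unique(clade_labels(tree, thr))), k)
  }
})

test_that("fitness attachment is seeded, smooth plus recorded noise", {
  tree <- simulate_tree(60, seed = 12)
  labels <- clade_labels(tree, clade_cut_for_groups(tree, 4))
  f1 <- attach_fitness(tree, labels, seed = 13)
  f2 <- attach_fitness(tree, labels, seed = 13)
  expect_identical(f1, f2)

  noiseless <- attach_fitness(tree, labels, seed = 13, noise_sd = 0)
  comp <- attr(noiseless, "components")
  expect_equal(as.numeric(noiseless), comp$smooth)

  # clade effects dominate: between-clade variance exceeds within-clade
  strong <- attach_fitness(tree, labels, seed = 14, clade_sd = 8,
                           depth_slope = 0, noise_sd = 0.3)
  fit <- stats::aov(y ~ g, data.frame(y = as.numeric(strong),
                                      g = factor(labels)))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_gt(ss[1] / length(unique(labels)), ss[2] / length(labels))
})

test_that("silhouette separates constructed clusters and nulls permutations", {
  set.seed(15)
  a <- matrix(rnorm(60, mean = 0, sd = 0.3), 30, 2)
  b <- matrix(rnorm(60, mean = 5, sd = 0.3), 30, 2)
  emb <- rbind(a, b)
  lab <- rep(1:2, each = 30)
  expect_gt(latent_separation_score(emb, lab), 0.5)

  perm <- replicate(20, latent_separation_score(emb, sample(lab)))
  expect_lt(abs(mean(perm)), 0.05)

  # coincident clusters with distinct labels score nonpositive
  co <- rbind(a, a)
  expect_lte(latent_separation_score(co, lab), 0)
  expect_error(latent_separation_score(emb, rep(1, 60)), "single label")
})

test_that("simulated family artifacts round trip through disk", {
  sim <- simulate_family(n_leaves = 12, L = 15, seed = 16)
  dir <- tempfile("sim_")
  write_sim_family(sim, dir)
  fam <- read_aligned_fasta(file.path(dir, "family.fasta"))
  expect_equal(length(fam), 12)
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_equal(sort(tree$tip.label), sort(sim$tree$tip.label))
  lab <- read.delim(file.path(dir, "labels.tsv"))
  expect_equal(nrow(lab), 12)
  fit <- read.delim(file.path(dir, "fitness.tsv"))
  expect_equal(fit$fitness, as.numeric(sim$fitness))
})
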