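test_that("allele-sharing distance follows the multiset rule", {
  # identical genotypes
  gm <- make_gm(cbind(c(100L, 100L), c(120L, 120L)),
                cbind(c(104L, 104L), c(124L, 124L)))
  d <- genetic_distance_matrix(gm)
  expect_equal(unname(d[1, 2]), 0)
  expect_equal(diag(d), c(I01 = 0, I02 = 0))

  # A/A vs A/B at a single locus: one of two copies shared
  gm2 <- make_gm(cbind(c(100L, 100L)), cbind(c(100L, 104L)))
  expect_equal(unname(genetic_distance_matrix(gm2)[1, 2]), 0.5)

  # fully disjoint alleles
  gm3 <- make_gm(cbind(c(100L, 108L), c(120L, 128L)),
                 cbind(c(104L, 112L), c(124L, 132L)))
  expect_equal(unname(genetic_distance_matrix(gm3)[1, 2]), 1)

  # bounded, symmetric, pairwise deletion over missing loci
  a1 <- cbind(c(100L, 100L, NA), c(120L, 124L, 120L))
  a2 <- cbind(c(104L, 104L, NA), c(120L, 124L, 128L))
  gm4 <- make_gm(a1, a2)
  d4 <- genetic_distance_matrix(gm4)
  expect_equal(d4, t(d4))
  expect_true(all(d4 >= 0 & d4 <= 1))
  # I03 compared with I01 over locus 2 only: {120,128} vs {100?...}
  expect_equal(unname(d4[1, 3]), 0.5)

  # no overlapping typed locus is an error
  gm5 <- make_gm(cbind(c(100L, NA), c(NA, 120L)),
                 cbind(c(100L, NA), c(NA, 120L)))
  expect_error(genetic_distance_matrix(gm5), "share no typed locus")
})

test_that("Nei individual distance is zero for identical homozygotes", {
  gm <- make_gm(cbind(c(100L, 100L), c(120L, 120L)),
                cbind(c(100L, 100L), c(120L, 120L)))
  d <- genetic_distance_matrix(gm, method = "nei_individual")
  expect_equal(unname(d[1, 2]), 0, tolerance = 1e-12)
  # hand-computed case: A/A vs A/B at one locus
  gm2 <- make_gm(cbind(c(100L, 100L)), cbind(c(100L, 104L)))
  # Jxy = 0.5, Jx = 1, Jy = 0.5 -> D = -ln(0.5/sqrt(0.5))
  expect_equal(unname(genetic_distance_matrix(gm2, "nei_individual")[1, 2]),
               -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
})

test_that("trait distances equal a brute-force pairwise oracle", {
  sim <- simulate_traits(n_accessions = 10L, seed = 23)
  d <- trait_distance_matrix(sim$table)
  X <- standardize_traits(sim$table)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(unname(d[i, j]), sqrt(sum((X[i, ] - X[j, ])^2)),
                   tolerance = 1e-9)
    }
  }
  expect_equal(unname(diag(d)), rep(0, 10))
})

test_that("UPGMA reproduces the hand-computed 3-leaf tree", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(dm)
  expect_equal(write_newick(tree), "((A:1,B:1):1,C:2);")
  expect_equal(tree$height, c(1, 2))

  # two leaves at distance d: both branches d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  expect_equal(write_newick(upgma(d2)), "(x:1.5,y:1.5);")

  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "incomplete")
})

test_that("UPGMA is ultrametric and matches average-linkage hclust", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
    tree <- upgma(d)
    # ultrametric: root-to-leaf path lengths all equal
    ph <- ape::read.tree(text = write_newick(tree))
    depths <- ape::node.depth.edgelength(ph)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
    # cophenetic distances equal twice hclust(average) merge heights
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(as.matrix(cophenetic(tree))[hc$labels, hc$labels],
                 as.matrix(cophenetic(hc))[hc$labels, hc$labels] / 2,
                 tolerance = 1e-9)
  }
})

test_that("UPGMA output does not depend on input row order", {
  set.seed(91)
  pts <- matrix(rnorm(8 * 2), 8)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  t1 <- write_newick(upgma(d))
  perm <- sample(8)
  t2 <- write_newick(upgma(d[perm, perm]))
  expect_equal(t1, t2)
})

test_that("Newick serialization quotes labels and round-trips", {
  skip_if_not_installed("ape")
  # single leaf
  solo <- upgma(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(write_newick(solo), "A;")
  # metacharacter labels are quoted
  dm <- matrix(c(0, 2, 2, 0), 2, 2,
               dimnames = list(c("a b", "c:d"), c("a b", "c:d")))
  nwk <- write_newick(upgma(dm))
  expect_match(nwk, "'a b'", fixed = TRUE)
  expect_match(nwk, "'c:d'", fixed = TRUE)
  # heights survive a parse round-trip
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(d) <- list(sprintf("L%d", 1:n), sprintf("L%d", 1:n))
    tree <- upgma(d)
    ph <- ape::read.tree(text = write_newick(tree))
    coph <- as.matrix(cophenetic(tree))
    expect_equal(as.matrix(ape::cophenetic.phylo(ph))[rownames(coph),
                                                      colnames(coph)],
                 2 * coph, tolerance = 1e-6)
  }
})

test_that("cluster cutting renumbers by decreasing size", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(dm)
  expect_equal(sort(unique(cut_clusters(tree, 1))), 1L)
  expect_equal(unname(cut_clusters(tree, 3)), c(1L, 2L, 3L))
  cl2 <- cut_clusters(tree, 2)
  expect_equal(cl2[c("A", "B")], c(A = 1L, B = 1L))  # larger cluster first
  expect_equal(unname(cl2["C"]), 2L)
})

test_that("duplicate detection finds planted clone groups", {
  # three mutual clones: one group, two redundant
  a <- cbind(c(100L, 100L, 100L, 108L), c(120L, 120L, 120L, 124L))
  gm <- make_gm(a, a)
  dup <- find_duplicates(genetic_distance_matrix(gm))
  expect_length(dup$groups, 1L)
  expect_equal(sort(dup$groups[[1]]), c("I01", "I02", "I03"))
  expect_equal(dup$n_redundant, 2L)
  expect_equal(dup$n_distinct, 2L)
  expect_error(find_duplicates(genetic_distance_matrix(gm), -1),
               "non-negative")

  # planted clones in the simulator
  sim <- simulate_populations(group_sizes = c(30L, 30L), clone_pairs = 2L,
                              seed = 17)
  d <- genetic_distance_matrix(sim$gm)
  dup2 <- find_duplicates(d)
  expect_length(dup2$groups, 2L)
  expect_equal(lapply(dup2$groups, sort),
               lapply(sim$truth$clone_groups, sort))

  # threshold-0 grouping equals exact genotype-string matching
  keys <- genotype_strings(sim$gm)
  expect_equal(dup2$n_distinct, length(unique(keys)))
  expect_equal(dup2$n_distinct + dup2$n_redundant,
               length(sim$gm$accessions))
})

test_that("homonym flagging distinguishes clones from distinct genotypes", {
  a1 <- cbind(c(100L, 100L, 100L, 108L), c(120L, 120L, 124L, 124L))
  gm <- make_gm(a1, a1)
  d <- genetic_distance_matrix(gm)
  nm <- c(I01 = "Alpha", I02 = "Alpha",   # clones sharing a name
          I03 = "Beta", I04 = "Beta")     # distinct sharing a name
  hom <- find_homonyms(nm, d)
  expect_length(hom$name_groups, 2L)
  expect_equal(names(hom$flagged), "Beta")
  expect_error(find_homonyms(c(ZZ = "x", ZZ2 = "x"), d), "missing")

  # planted homonym groups in the simulator
  sim <- simulate_populations(group_sizes = c(40L, 40L),
                              homonym_groups = 3L, seed = 29)
  hom2 <- find_homonyms(sim$names, genetic_distance_matrix(sim$gm))
  expect_length(hom2$flagged, 3L)
})

test_that("principal coordinates reproduce Euclidean configurations", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  pc3 <- suppressWarnings(genotype_pca(d3))
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # coordinates reproduce a Euclidean distance matrix
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  d6 <- as.matrix(dist(pts))
  dimnames(d6) <- list(sprintf("p%d", 1:6), sprintf("p%d", 1:6))
  pc6 <- genotype_pca(d6, k = 2)
  rec <- as.matrix(dist(pc6$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d6), tolerance = 1e-9)

  # planted groups separate on the first axes
  sim <- simulate_populations(group_sizes = c(25L, 25L, 25L), fst = 0.32,
                              seed = 41)
  d <- genetic_distance_matrix(sim$gm)
  pc <- suppressWarnings(genotype_pca(d, k = 2))
  sil <- mean_silhouette(dist(pc$coordinates[, 1:2]),
                         sim$groups[rownames(pc$coordinates)])
  expect_gt(sil, 0.5)
})
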