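test_that("gower dissimilarity matches forced mismatch counts", {
  a <- trait_profile(c("x", "y", "z", "w"),
                     c("small", "giant", "small", "small"),
                     c("current", "mixed", "active_ambush", "current"),
                     c("omnivore_herbivore", "carnivore",
                       "omnivore_herbivore", "omnivore_herbivore"),
                     c("free_spawner", "egg_brooding", "free_spawner",
                       "free_spawner"))
  tm <- encode_traits(a)
  dcat <- gower_dissimilarity(tm, "categorical_traits")
  dbin <- gower_dissimilarity(tm, "binary_columns")
  expect_equal(dcat["x", "w"], 0)              # identical profiles
  expect_equal(dcat["x", "y"], 1)              # differ in all 4 traits
  expect_equal(dbin["x", "y"], 8 / 17)
  expect_equal(dcat["x", "z"], 0.25)           # feeding type only
  expect_equal(dbin["x", "z"], 2 / 17)
})

test_that("gower modes are proportional and match brute force / daisy", {
  fx <- table3_fixture()
  tm <- fx$trait_matrix
  dcat <- gower_dissimilarity(tm, "categorical_traits")
  dbin <- gower_dissimilarity(tm, "binary_columns")
  expect_true(all(dcat >= 0 & dcat <= 1))
  expect_equal(unclass(dbin), unclass(dcat) * 8 / 17, tolerance = 1e-12)
  expect_equal(unclass(dcat), t(unclass(dcat)))
  expect_true(all(diag(dcat) == 0))

  # brute-force mismatch counting on a subsample
  dec <- decode_traits(tm)
  idx <- seq(1, 98, by = 7)
  for (i in idx) for (j in idx) {
    m <- sum(dec[i, -1] != dec[j, -1])
    expect_equal(dcat[i, j], m / 4)
    expect_equal(dbin[i, j], 2 * m / 17)
  }

  skip_if_not_installed("cluster")
  fac <- dec[-1]
  fac[] <- lapply(fac, factor)
  ref <- as.matrix(cluster::daisy(fac, metric = "gower"))
  expect_equal(unname(unclass(dcat)), unname(ref), tolerance = 1e-12)
})

test_that("ward base cases behave as forced by geometry", {
  d <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  dend <- ward_cluster(d)
  expect_equal(nrow(dend$merge), 1)
  expect_equal(dend$height, 0.6)   # ward.D2 height of a singleton pair
  expect_error(ward_cluster(d[1, 1, drop = FALSE]), "at least 2")

  # two zero-distance pairs far apart: first two merges are the pairs
  d4 <- matrix(0.9, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0
  d4[3, 4] <- d4[4, 3] <- 0
  diag(d4) <- 0
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  dend4 <- ward_cluster(d4)
  expect_equal(dend4$height[1:2], c(0, 0))
  expect_equal(dend4$merge[1, ], c(-1, -2))
  expect_equal(dend4$merge[2, ], c(-3, -4))
})

test_that("ward merge sequence equals the from-scratch cost oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    d <- random_dissimilarity(n)
    dend <- ward_cluster(d)
    oracle <- ward_oracle(d)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-9)
    for (m in seq_len(n - 2)) {
      mine <- cut_tree(dend, n - m)$group
      expect_equal(adjusted_rand_index(mine, oracle$partitions[[m]]), 1)
    }
  }
})

test_that("ward agrees with stats::hclust for both variants", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    d <- random_dissimilarity(n)
    for (variant in c("ward.D2", "ward.D")) {
      mine <- ward_cluster(d, variant)
      ref <- stats::hclust(stats::as.dist(d), method = variant)
      expect_equal(mine$height, ref$height, tolerance = 1e-9)
      for (k in 2:(n - 1)) {
        expect_equal(adjusted_rand_index(cut_tree(mine, k)$group,
                                         stats::cutree(ref, k)), 1)
      }
    }
  }
})

test_that("ward topology is invariant to uniform rescaling", {
  set.seed(5)
  d <- random_dissimilarity(9)
  a <- ward_cluster(d)
  b <- ward_cluster(d * 0.37)
  expect_equal(a$merge, b$merge)
  expect_equal(a$height, b$height / 0.37, tolerance = 1e-9)
  # hence both gower modes give the same tree
  tm <- table3_fixture()$trait_matrix
  t_cat <- ward_cluster(gower_dissimilarity(tm, "categorical_traits"))
  t_bin <- ward_cluster(gower_dissimilarity(tm, "binary_columns"))
  expect_equal(t_cat$merge, t_bin$merge)
})

test_that("ward heights are monotone non-decreasing", {
  set.seed(31)
  for (rep in 1:10) {
    dend <- ward_cluster(random_dissimilarity(sample(5:15, 1)))
    expect_true(all(diff(dend$height) >= -1e-10))
  }
})

test_that("cut_tree covers the trivial cuts and errors out of range", {
  dend <- ward_cluster(random_dissimilarity(6))
  expect_equal(unique(cut_tree(dend, 1)$group), 1)
  expect_equal(sort(cut_tree(dend, 6)$group), 1:6)
  expect_error(cut_tree(dend, 0), "k must be")
  expect_error(cut_tree(dend, 7), "k must be")
})

test_that("cut_tree partitions are nested across k and numbered by size", {
  set.seed(47)
  d <- random_dissimilarity(12)
  dend <- ward_cluster(d)
  for (k in 2:11) {
    coarse <- cut_tree(dend, k)$group
    fine <- cut_tree(dend, k + 1)$group
    # each fine group maps into exactly one coarse group
    expect_true(all(tapply(coarse, fine, function(g) length(unique(g))) == 1))
    sizes <- as.integer(table(coarse))   # indexed by group id 1..k
    expect_true(all(diff(sizes) <= 0))
    expect_equal(sort(unique(coarse)), seq_len(k))
  }
})

test_that("planted Table-3 profiles are recovered exactly at k = 8", {
  fx <- table3_fixture(coverage = "modal")
  d <- gower_dissimilarity(fx$trait_matrix)
  dend <- ward_cluster(d)
  cl <- cut_tree(dend, 8)
  expect_equal(adjusted_rand_index(cl$group, fx$groups$group), 1)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$group, fx$groups$group), 1)
})

test_that("elbow selects the zero-dispersion floor for planted profiles", {
  # 4 groups of identical items: wss(4) = 0 and k = 4 selected
  tm <- encode_traits(trait_profile(
    paste0("s", 1:8),
    rep(c("small", "giant", "medium", "large"), each = 2),
    rep(c("current", "mixed", "active_ambush", "passive_ambush"), each = 2),
    rep(c("omnivore_herbivore", "carnivore", "omnivore", "omnivore_detritivore"),
        each = 2),
    rep(c("free_spawner", "egg_brooding", "parthenogenesis",
          "alternation_of_generations"), each = 2)))
  d <- gower_dissimilarity(tm)
  dend <- ward_cluster(d)
  el <- elbow_select(d, dend, k_max = 7)
  expect_equal(el$selected_k, 4)
  expect_equal(el$rule, "zero_floor")
  expect_equal(el$wss[el$k_values == 4], 0)
})

test_that("elbow finds a constructed sharp kink by maximum curvature", {
  # five equidistant tight clusters (regular simplex): the wss curve
  # declines near-linearly down to k = 5, then hits a sharp kink
  centers <- 10 * diag(5)
  pts <- rbind(centers - 0.3, centers + 0.3)
  d <- as.matrix(stats::dist(pts)) / max(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", seq_len(nrow(pts)))
  dend <- ward_cluster(d)
  el <- elbow_select(d, dend, k_max = 9)
  expect_true(all(el$wss > 0))
  expect_equal(el$rule, "max_curvature")
  expect_equal(el$selected_k, 5)
})

test_that("wss is non-increasing in k", {
  set.seed(61)
  for (rep in 1:5) {
    d <- random_dissimilarity(14)
    dend <- ward_cluster(d)
    el <- elbow_select(d, dend, k_max = 13)
    expect_true(all(diff(el$wss) <= 1e-10))
  }
  expect_error(elbow_select(d, dend, k_max = 14), "k_max")
})

test_that("dendrogram export/import round-trips", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), NULL))
  two <- ward_cluster(d)
  nwk <- export_dendrogram(two, "newick")
  expect_match(nwk, "^\\(A:0\\.4,B:0\\.4\\)m1;$")
  expect_error(export_dendrogram(two, "nexus"))

  set.seed(77)
  dend <- ward_cluster(random_dissimilarity(10))
  for (fmt in c("newick", "merge_json")) {
    back <- import_dendrogram(export_dendrogram(dend, fmt), fmt,
                              labels = dend$labels)
    expect_equal(back$merge, dend$merge)
    expect_equal(back$height, dend$height, tolerance = 1e-8)
    expect_equal(back$labels, dend$labels)
  }

  # 98-leaf fixture: identical cuts for every k after newick round trip
  fx <- table3_fixture()
  big <- ward_cluster(gower_dissimilarity(fx$trait_matrix))
  back <- import_dendrogram(export_dendrogram(big, "newick"), "newick",
                            labels = big$labels)
  expect_equal(back$merge, big$merge)
  for (k in 2:98) {
    expect_identical(cut_tree(back, k)$group, cut_tree(big, k)$group)
  }
})
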