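test_that("dominance follows Y = share x occurrence frequency", {
  # hand case: sp1 = (10, 5, 0), sp2 = (0, 5, 10) -> Y(sp1) = (15/30)(2/3)
  ab <- tiny_abundance(rbind(c(10, 0), c(5, 5), c(0, 10)))
  dom <- dominance(ab, "spring")
  expect_equal(dom$dominance[dom$species == "sp1"], 1 / 3)
  expect_equal(dom$share, c(0.5, 0.5))
  expect_equal(dom$occurrence_frequency, c(2 / 3, 2 / 3))

  # a species holding all abundance at every station: Y = 1
  ab1 <- tiny_abundance(rbind(c(10, 0), c(20, 0), c(5, 0)))
  dom1 <- dominance(ab1, "spring")
  expect_equal(dom1$dominance, c(1, 0))
  expect_equal(dom1$dominant, c(TRUE, FALSE))

  expect_error(dominance(ab, "summer"), "no stations")
})

test_that("dominance is scale invariant and order invariant", {
  set.seed(3)
  v <- matrix(rexp(5 * 6), 5, 6)
  v[v < 0.4] <- 0
  ab <- abundance_table(tiny_stations(5), paste0("sp", 1:6), v)
  base <- dominance(ab, "spring")
  scaled <- dominance(abundance_table(tiny_stations(5), paste0("sp", 1:6),
                                      v * 13.7), "spring")
  expect_equal(scaled$dominance, base$dominance)
  perm <- sample(5)
  st <- tiny_stations(5)[perm, ]
  reord <- dominance(abundance_table(st, paste0("sp", 1:6),
                                     v[perm, ]), "spring")
  expect_equal(reord$occurrence_frequency, base$occurrence_frequency)
  expect_equal(reord$dominance, base$dominance)
})

test_that("dominant-taxon counting is threshold-inclusive across seasons", {
  none <- data.frame(species = c("a", "b"), dominance = c(0.01, 0.019))
  expect_equal(count_dominant_taxa(none), 0)
  edge <- data.frame(species = "a", dominance = 0.02)
  expect_equal(count_dominant_taxa(edge), 1)
  two_seasons <- list(data.frame(species = c("a", "b"), dominance = c(0.5, 0.001)),
                      data.frame(species = c("a", "b"), dominance = c(0.4, NA)))
  expect_equal(count_dominant_taxa(two_seasons), 1)
})

test_that("published dominance table yields the twelve dominant taxa", {
  pub <- published_dominance()
  per_season <- split(pub, pub$season)
  expect_equal(count_dominant_taxa(per_season), 12)
  # no taxon crosses the threshold only via a below-detection midpoint
  expect_true(all(pub$dominance[pub$below_detection] < 0.02, na.rm = TRUE))
})

test_that("composition shares are normalized per stratum", {
  ab <- tiny_abundance(rbind(c(10, 0), c(5, 5), c(0, 10)))
  one_key <- composition(ab, c(sp1 = "all", sp2 = "all"), "season")
  expect_equal(one_key$share, 1)
  two_keys <- composition(ab, c(sp1 = "k1", sp2 = "k2"), "season")
  expect_equal(two_keys$share, c(0.5, 0.5))

  by_station <- composition(ab, c(sp1 = "k1", sp2 = "k2"), "station")
  sums <- tapply(by_station$share, by_station$station, sum)
  expect_equal(as.numeric(sums), rep(1, 3))

  expect_error(composition(ab, c(sp1 = "k1")), "sp2")
  # excluded species leave numerator and denominator
  excl <- composition(ab, c(sp1 = "k1"), "season", exclude = "sp2")
  expect_equal(excl$share, 1)
})

test_that("published seasonal means reproduce the printed share structure", {
  ab <- published_abundance_table()
  shares <- composition(ab, stats::setNames(ab$species, ab$species), "season")
  cop <- shares[shares$key == "Copepods", ]
  expect_true(all(cop$share > 0.5))
  expect_gt(cop$share[cop$season == "autumn"], 0.8)
  # printed-total arithmetic of the source table
  pub <- published_seasonal_abundance()
  expect_equal(pub$mean_abundance[pub$taxon_group == "Copepods" &
                                    pub$season == "autumn"] /
                 pub$mean_abundance[pub$taxon_group == "Total" &
                                      pub$season == "autumn"],
               0.947, tolerance = 1e-3)
})

test_that("functional richness counts groups with presence", {
  v <- rbind(c(0, 0, 0), c(1, 0, 2), c(3, 4, 5))
  ab <- abundance_table(tiny_stations(3), c("s1", "s2", "s3"), v)
  groups <- data.frame(species = c("s1", "s2", "s3"), group = c(1, 2, 1))
  rich <- functional_richness(ab, groups)
  expect_equal(rich$richness, c(0, 1, 2))

  # brute-force recount on a simulated cruise
  cfg <- simulation_config(seed = 4)
  com <- generate_community(cfg, generate_env(cfg))
  rich2 <- functional_richness(com$abundance, com$truth$groups)
  v2 <- com$abundance$values
  for (i in seq_len(nrow(v2))) {
    present <- names(which(v2[i, ] > 0))
    expect_equal(rich2$richness[i],
                 length(unique(com$truth$groups[present])))
  }
})

test_that("group abundance aggregation preserves totals", {
  cfg <- simulation_config(seed = 8)
  com <- generate_community(cfg, generate_env(cfg))
  ga <- group_abundance(com$abundance, com$truth$groups)
  expect_equal(colnames(ga), as.character(1:8))
  expect_equal(rowSums(ga), rowSums(com$abundance$values))
})
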