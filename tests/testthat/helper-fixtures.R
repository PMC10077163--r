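# Shared in-code fixtures for the test suite.

tiny_stations <- function(n = 3, season = "spring") {
  data.frame(station_id = paste0("S", seq_len(n)),
             season = rep_len(season, n),
             latitude = 34 + seq_len(n) / 10,
             longitude = 121 + seq_len(n) / 10,
             tow_depth = 10 * seq_len(n),
             stringsAsFactors = FALSE)
}

tiny_abundance <- function(values = rbind(c(10, 0), c(5, 5), c(0, 10)),
                           species = c("sp1", "sp2"),
                           season = "spring") {
  abundance_table(tiny_stations(nrow(values), season), species, values)
}

random_dissimilarity <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  m
}

# From-scratch Ward oracle: at every step recompute the merge cost
# 2 * [ESS(A u B) - ESS(A) - ESS(B)] from the raw pairwise squared
# dissimilarities, ESS(C) = sum_{i,j in C} d2_ij / (2 |C|).
ward_oracle <- function(d) {
  d2 <- d^2
  n <- nrow(d)
  ess <- function(idx) sum(d2[idx, idx]) / (2 * length(idx))
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- list()
  for (m in seq_len(n - 1)) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cost <- 2 * (ess(c(clusters[[i]], clusters[[j]])) -
                       ess(clusters[[i]]) - ess(clusters[[j]]))
        if (cost < best - 1e-12) { best <- cost; bi <- i; bj <- j }
      }
    }
    heights[m] <- sqrt(max(best, 0))
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    part <- integer(n)
    for (c in seq_along(clusters)) part[clusters[[c]]] <- c
    partitions[[m]] <- part
  }
  list(heights = heights, partitions = partitions)
}

trait_profile <- function(species, bl, ft, tg, rm) {
  data.frame(species = species, body_length_class = bl, feeding_type = ft,
             trophic_group = tg, reproductive_mode = rm,
             stringsAsFactors = FALSE)
}
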