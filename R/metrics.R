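# Dominance screening, composition by season/station, functional richness.

#' Dominance index of each taxon within one season
#'
#' The dominance of species i over a season's stations is
#' `Y = (n_i / N) * f_i`, where `n_i / N` is the species' share of the
#' summed abundance of all species at those stations and `f_i` is its
#' occurrence frequency (fraction of stations with abundance > 0). Taxa
#' with `Y >= threshold` (default 0.02) are flagged dominant.
#'
#' @param abundance An [abundance_table()].
#' @param season Season label to screen.
#' @param threshold Dominance cutoff, default 0.02 (inclusive).
#' @return Data frame (one row per species): `species`, `mean_abundance`,
#'   `sd_abundance`, `share`, `occurrence_frequency`, `dominance`,
#'   `dominant`.
#' @export
dominance <- function(abundance, season, threshold = 0.02) {
  sub <- season_subset(abundance, season)
  v <- sub$values
  total <- sum(v)
  n_i <- colSums(v)
  share <- if (total > 0) n_i / total else rep(0, ncol(v))
  f_i <- colMeans(v > 0)
  y <- share * f_i
  data.frame(species = sub$species,
             season = season,
             mean_abundance = colMeans(v),
             sd_abundance = apply(v, 2, stats::sd),
             share = share,
             occurrence_frequency = f_i,
             dominance = y,
             dominant = y >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count taxa dominant in at least one season
#'
#' @param tables List of per-season dominance tables (from [dominance()]
#'   or any data frame with `species` and `dominance` columns, e.g.
#'   printed literature values).
#' @param threshold Dominance cutoff, default 0.02 (inclusive); `NA`
#'   dominance values never count.
#' @return Integer: number of distinct taxa with `dominance >= threshold`
#'   in at least one table.
#' @export
count_dominant_taxa <- function(tables, threshold = 0.02) {
  if (is.data.frame(tables)) tables <- list(tables)
  hits <- unlist(lapply(tables, function(t) {
    stopifnot(all(c("species", "dominance") %in% names(t)))
    t$species[!is.na(t$dominance) & t$dominance >= threshold]
  }))
  length(unique(hits))
}

#' Relative-abundance composition by a species grouping
#'
#' Sums abundance over species sharing a key (higher taxon, trait
#' modality, or functional group) and normalizes within each season or
#' each station. Excluded species (e.g. planktonic larvae for trait keys)
#' are removed from both numerator and denominator; any other unmapped
#' species with nonzero abundance is an error.
#'
#' @param abundance An [abundance_table()].
#' @param mapping Named character/integer vector: species -> key.
#' @param by `"season"` or `"station"`.
#' @param exclude Character vector of species excluded from the analysis.
#' @return Data frame with columns `key`, `season` or `station`, `share`;
#'   shares sum to 1 within each season/station with nonzero mapped
#'   abundance.
#' @export
composition <- function(abundance, mapping, by = c("season", "station"),
                        exclude = character()) {
  stopifnot(inherits(abundance, "abundance_table"))
  by <- match.arg(by)
  sp <- abundance$species
  unmapped <- setdiff(sp, c(names(mapping), exclude))
  if (length(unmapped)) {
    active <- unmapped[colSums(abundance$values[, unmapped, drop = FALSE]) > 0]
    if (length(active)) {
      stop("species with abundance but no composition key: ",
           paste(active, collapse = ", "))
    }
  }
  keep <- setdiff(intersect(sp, names(mapping)), exclude)
  v <- abundance$values[, keep, drop = FALSE]
  key <- as.character(mapping[keep])
  strata <- if (by == "season") abundance$stations$season else
    abundance$stations$station_id
  out <- do.call(rbind, lapply(unique(strata), function(s) {
    tot <- colSums(v[strata == s, , drop = FALSE])
    per_key <- tapply(tot, key, sum)
    denom <- sum(per_key)
    share <- if (denom > 0) per_key / denom else per_key * NA_real_
    data.frame(key = names(per_key), stratum = s, share = as.numeric(share),
               stringsAsFactors = FALSE)
  }))
  names(out)[names(out) == "stratum"] <- by
  rownames(out) <- NULL
  out
}

#' Functional richness per station
#'
#' Number of functional groups with nonzero summed abundance at each
#' station.
#'
#' @param abundance An [abundance_table()].
#' @param groups Data frame `species`/`group` (from [cut_tree()]) or a
#'   named vector species -> group. Species without a group (e.g.
#'   larvae) are ignored.
#' @return Data frame `station`, `season`, `richness`.
#' @export
functional_richness <- function(abundance, groups) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$species)
  }
  keep <- intersect(abundance$species, names(groups))
  v <- abundance$values[, keep, drop = FALSE]
  g <- as.character(groups[keep])
  rich <- apply(v, 1, function(row) {
    length(unique(g[row > 0]))
  })
  data.frame(station = abundance$stations$station_id,
             season = abundance$stations$season,
             richness = as.integer(rich),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sum abundance into a station x group matrix
#'
#' @param abundance An [abundance_table()].
#' @param groups As in [functional_richness()].
#' @return Numeric matrix, stations x groups (column order = sorted group
#'   labels; numeric-like labels sort numerically).
#' @export
group_abundance <- function(abundance, groups) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$species)
  }
  keep <- intersect(abundance$species, names(groups))
  v <- abundance$values[, keep, drop = FALSE]
  g <- as.character(groups[keep])
  lev <- unique(g)
  ord <- suppressWarnings(as.numeric(lev))
  lev <- if (!anyNA(ord)) lev[order(ord)] else sort(lev)
  m <- sapply(lev, function(x) rowSums(v[, g == x, drop = FALSE]))
  m <- matrix(m, nrow = nrow(v), dimnames = list(rownames(v), lev))
  m
}
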