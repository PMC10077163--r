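# Accessors for the packaged seasonal summary tables transcribed from
# the South Yellow Sea survey (seasonal mean abundances by taxon group,
# dominance of the twelve recurrent dominant taxa, and the eight-group
# functional summary). Values printed as "< 0.1" (abundance) or
# "< 0.01" (dominance) are stored as midpoints (0.05 / 0.005) and
# flagged `below_detection`; such entries never drive threshold checks.

.extdata <- function(name) {
  system.file("extdata", name, package = "planktraits", mustWork = TRUE)
}

#' Published seasonal abundance summary by taxon group
#'
#' @return Data frame: `taxon_group`, `season`, `n_species`,
#'   `mean_abundance` (ind/m^3), `sd_abundance`, `below_detection`.
#'   Includes a `Total` row per season as printed; component means do
#'   not exactly sum to it in autumn (source inconsistency).
#' @export
published_seasonal_abundance <- function() {
  utils::read.csv(.extdata("sys_table1_seasonal_abundance.csv"),
                  stringsAsFactors = FALSE)
}

#' Seasonal mean abundances as a pseudo abundance table
#'
#' Wraps the published per-season mean abundances (taxon groups as
#' "species", one pseudo-station per season) so that [composition()] and
#' friends can be applied to the printed summary directly. The `Total`
#' row is dropped; undetected groups get 0.
#'
#' @return An [abundance_table()] with 3 pseudo-stations and 16 taxon
#'   groups.
#' @export
published_abundance_table <- function() {
  df <- published_seasonal_abundance()
  df <- df[df$taxon_group != "Total", ]
  groups <- unique(df$taxon_group)
  values <- matrix(0, nrow = 3, ncol = length(groups),
                   dimnames = list(.seasons, groups))
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$mean_abundance[i])) {
      values[df$season[i], df$taxon_group[i]] <- df$mean_abundance[i]
    }
  }
  stations <- data.frame(station_id = paste0("mean_", .seasons),
                         season = .seasons, latitude = 34.5, longitude = 122,
                         tow_depth = 1, stringsAsFactors = FALSE)
  abundance_table(stations, groups, values)
}

#' Published dominance of the recurrent dominant taxa
#'
#' Seasonal mean abundance and dominance index Y of the twelve taxa that
#' were dominant (Y >= 0.02) in at least one season, as printed. `NA`
#' marks seasons where a taxon was not detected.
#'
#' @return Data frame: `species`, `season`, `mean_abundance`,
#'   `sd_abundance`, `dominance`, `below_detection`.
#' @export
published_dominance <- function() {
  utils::read.csv(.extdata("sys_table2_dominance.csv"),
                  stringsAsFactors = FALSE)
}

#' Published functional-group summary
#'
#' The eight functional groups with sizes, higher taxa, and the distinct
#' trait modalities present in each, as `"; "`-joined lists (taxa
#' alphabetical, modalities in vocabulary order) matching the layout of
#' [summarize_groups()].
#'
#' @return Data frame with columns `group`, `size`, `taxa`, and one
#'   column per trait.
#' @export
published_group_summary <- function() {
  utils::read.csv(.extdata("sys_table3_groups.csv"),
                  stringsAsFactors = FALSE)
}
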