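# Station-indexed abundance and environment tables, CSV I/O, and the
# net-haul abundance standardization.

.station_columns <- c("station_id", "season", "latitude", "longitude", "tow_depth")

.validate_stations <- function(stations) {
  missing <- setdiff(.station_columns, names(stations))
  if (length(missing)) {
    stop("station metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  stations$station_id <- as.character(stations$station_id)
  if (anyDuplicated(stations$station_id)) stop("station ids must be unique")
  bad <- !stations$season %in% .seasons
  if (any(bad)) {
    stop(sprintf("unknown season label '%s' for station '%s'",
                 stations$season[bad][1], stations$station_id[bad][1]))
  }
  if (any(!is.finite(stations$tow_depth)) || any(stations$tow_depth <= 0)) {
    stop("tow_depth must be finite and > 0")
  }
  stations
}

#' Construct a station x species abundance table
#'
#' @param stations Data frame of station metadata with columns
#'   `station_id`, `season` (one of spring/summer/autumn), `latitude`,
#'   `longitude`, `tow_depth` (m).
#' @param species Character vector of unique taxon labels.
#' @param values Numeric matrix, stations x species, abundance in ind/m^3.
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(stations, species, values) {
  stations <- .validate_stations(stations)
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species labels must be unique")
  values <- as.matrix(values)
  if (nrow(values) != nrow(stations) || ncol(values) != length(species)) {
    stop("abundance matrix shape does not match station/species metadata")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid abundance at station '%s', species '%s'",
                 stations$station_id[bad[1, 1]], species[bad[1, 2]]))
  }
  dimnames(values) <- list(stations$station_id, species)
  structure(list(stations = stations, species = species, values = values),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d stations x %d species (ind/m^3)\n",
              nrow(x$values), ncol(x$values)))
  cat("seasons:", paste(sprintf("%s (%d)", .seasons,
                                tabulate(factor(x$stations$season, .seasons), 3)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Construct a station x environment table
#'
#' @param stations Station metadata, as in [abundance_table()].
#' @param variables Character vector, subset of
#'   `c("SST","SBT","SSS","SBS","SChla","BChla")` in order.
#' @param values Numeric matrix, stations x variables.
#' @return Object of class `env_table`.
#' @export
env_table <- function(stations, variables, values) {
  stations <- .validate_stations(stations)
  known <- c("SST", "SBT", "SSS", "SBS", "SChla", "BChla")
  variables <- as.character(variables)
  if (!all(variables %in% known)) {
    stop("unknown environment variable(s): ",
         paste(setdiff(variables, known), collapse = ", "))
  }
  values <- as.matrix(values)
  if (nrow(values) != nrow(stations) || ncol(values) != length(variables)) {
    stop("environment matrix shape does not match metadata")
  }
  chl <- which(variables %in% c("SChla", "BChla"))
  if (length(chl) && any(values[, chl, drop = FALSE] < 0, na.rm = TRUE)) {
    stop("chlorophyll a values must be >= 0")
  }
  dimnames(values) <- list(stations$station_id, variables)
  structure(list(stations = stations, variables = variables, values = values),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d stations x %d variables (%s)\n",
              nrow(x$values), ncol(x$values), paste(x$variables, collapse = ", ")))
  invisible(x)
}

.table_to_df <- function(tab) {
  cbind(tab$stations[.station_columns], as.data.frame(tab$values))
}

.df_to_parts <- function(df, path) {
  missing <- setdiff(.station_columns, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' lacks metadata column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  list(stations = df[.station_columns],
       value_cols = setdiff(names(df), .station_columns))
}

#' Read / write abundance tables as CSV
#'
#' One row per station; metadata columns `station_id`, `season`,
#' `latitude`, `longitude`, `tow_depth` followed by one column per
#' species. Comma-separated, UTF-8, `.` decimal.
#'
#' @param path File path.
#' @return `read_abundance_csv`: a validated [abundance_table()].
#' @export
read_abundance_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  parts <- .df_to_parts(df, path)
  abundance_table(parts$stations, parts$value_cols,
                  as.matrix(df[parts$value_cols]))
}

#' @param table An `abundance_table`.
#' @rdname read_abundance_csv
#' @export
write_abundance_csv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  utils::write.csv(.table_to_df(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write environment tables as CSV
#'
#' Same layout as [read_abundance_csv()] with environment variables as
#' value columns.
#'
#' @param path File path.
#' @return `read_env_csv`: a validated [env_table()].
#' @export
read_env_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  parts <- .df_to_parts(df, path)
  env_table(parts$stations, parts$value_cols, as.matrix(df[parts$value_cols]))
}

#' @param table An `env_table`.
#' @rdname read_env_csv
#' @export
write_env_csv <- function(table, path) {
  stopifnot(inherits(table, "env_table"))
  utils::write.csv(.table_to_df(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write trait assignment tables as CSV
#'
#' Columns `species`, `body_length_class`, `feeding_type`,
#' `trophic_group`, `reproductive_mode`; extra columns (e.g.
#' `higher_taxon`, `group`) are carried through unchanged.
#'
#' @param path File path.
#' @return `read_trait_csv`: validated trait assignment data frame.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_assignments(df)
}

#' @param assignments Trait assignment data frame.
#' @rdname read_trait_csv
#' @export
write_trait_csv <- function(assignments, path) {
  utils::write.csv(validate_trait_assignments(assignments), path,
                   row.names = FALSE)
  invisible(path)
}

#' Standardize a net-haul count to abundance per cubic meter
#'
#' Converts a raw count from a vertical plankton-net tow to ind/m^3 by
#' dividing by the filtered volume `mouth_area * tow_depth`. The default
#' mouth area is that of a WP2 net (0.25 m^2).
#'
#' @param count Number of individuals counted (>= 0); vectorized.
#' @param tow_depth Haul length in meters (> 0).
#' @param mouth_area Net mouth area in m^2 (> 0), default 0.25.
#' @return Abundance in ind/m^3.
#' @export
#' @examples
#' standardize_abundance(100, tow_depth = 20) # 20 ind/m^3
standardize_abundance <- function(count, tow_depth, mouth_area = 0.25) {
  if (any(!is.finite(count)) || any(count < 0)) stop("count must be >= 0")
  if (any(!is.finite(tow_depth)) || any(tow_depth <= 0)) {
    stop("tow_depth must be > 0")
  }
  if (any(!is.finite(mouth_area)) || any(mouth_area <= 0)) {
    stop("mouth_area must be > 0")
  }
  count / (mouth_area * tow_depth)
}

#' Subset an abundance table to the stations of one season
#'
#' @param table An `abundance_table`.
#' @param season One of `"spring"`, `"summer"`, `"autumn"`.
#' @return An `abundance_table` restricted to that season's stations.
#' @export
season_subset <- function(table, season) {
  stopifnot(inherits(table, "abundance_table"))
  if (!season %in% .seasons) stop("unknown season: ", season)
  keep <- table$stations$season == season
  if (!any(keep)) stop("no stations in season: ", season)
  abundance_table(table$stations[keep, , drop = FALSE], table$species,
                  table$values[keep, , drop = FALSE])
}
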