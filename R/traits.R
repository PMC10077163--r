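# Categorical trait vocabulary and one-hot (binary) trait coding.

.trait_vocabulary <- list(
  body_length_class = c("small", "medium", "large", "giant"),
  feeding_type      = c("active_ambush", "passive_ambush", "current", "mixed"),
  trophic_group     = c("carnivore", "omnivore", "omnivore_carnivore",
                        "omnivore_herbivore", "omnivore_detritivore"),
  reproductive_mode = c("free_spawner", "egg_brooding", "parthenogenesis",
                        "alternation_of_generations")
)

.seasons <- c("spring", "summer", "autumn")

.trait_columns <- function() {
  unlist(lapply(names(.trait_vocabulary), function(tr) {
    paste(tr, .trait_vocabulary[[tr]], sep = ".")
  }), use.names = FALSE)
}

#' Trait vocabulary
#'
#' The closed vocabulary of the four categorical functional traits used
#' throughout the package: body length class (`small` < 1 mm, `medium`
#' 1--2 mm, `large` 2--5 mm, `giant` > 5 mm), feeding type, trophic group
#' and reproductive mode.
#'
#' @return Named list of character vectors, one per trait, giving the
#'   modalities in their fixed column order.
#' @export
#' @examples
#' trait_vocabulary()
trait_vocabulary <- function() .trait_vocabulary

#' Classify adult body length into a length class
#'
#' Class boundaries are half-open and lower-inclusive: `[0, 1)` mm is
#' `small`, `[1, 2)` `medium`, `[2, 5)` `large`, and `[5, Inf)` `giant`.
#'
#' @param length_mm Numeric vector of average adult body lengths in mm.
#' @return Character vector of body length classes.
#' @export
#' @examples
#' classify_body_length(c(0.4, 1, 3.2, 12))
classify_body_length <- function(length_mm) {
  stopifnot(is.numeric(length_mm))
  if (any(!is.finite(length_mm)) || any(length_mm < 0)) {
    stop("body lengths must be finite and >= 0")
  }
  cls <- cut(length_mm, breaks = c(0, 1, 2, 5, Inf), right = FALSE,
             labels = .trait_vocabulary$body_length_class,
             include.lowest = TRUE)
  as.character(cls)
}

#' Validate a trait assignment table
#'
#' Checks that a data frame assigns each species exactly one modality per
#' trait from the closed vocabulary, and that species labels are unique.
#'
#' @param assignments Data frame with columns `species`,
#'   `body_length_class`, `feeding_type`, `trophic_group`,
#'   `reproductive_mode`.
#' @return The validated data frame, invisibly coerced to character columns.
#' @export
validate_trait_assignments <- function(assignments) {
  required <- c("species", names(.trait_vocabulary))
  missing <- setdiff(required, names(assignments))
  if (length(missing)) {
    stop("trait assignment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  assignments$species <- as.character(assignments$species)
  dup <- assignments$species[duplicated(assignments$species)]
  if (length(dup)) {
    stop("duplicate species label(s): ", paste(unique(dup), collapse = ", "))
  }
  for (tr in names(.trait_vocabulary)) {
    vals <- as.character(assignments[[tr]])
    bad <- !vals %in% .trait_vocabulary[[tr]]
    if (any(bad)) {
      stop(sprintf("unknown %s modality '%s' for species '%s'",
                   tr, vals[bad][1], assignments$species[bad][1]))
    }
    assignments[[tr]] <- vals
  }
  assignments
}

#' One-hot encode trait assignments into a species x trait matrix
#'
#' Builds the binary species x trait-modality matrix used for Gower
#' dissimilarity and clustering: 17 columns in fixed order (4 body length
#' + 4 feeding + 5 trophic + 4 reproductive), with exactly one `1` per
#' trait block per species.
#'
#' @param assignments Data frame as accepted by
#'   [validate_trait_assignments()].
#' @return Integer matrix of class `trait_matrix` with species row names.
#' @export
#' @examples
#' a <- data.frame(species = "Oithona similis",
#'                 body_length_class = "small", feeding_type = "active_ambush",
#'                 trophic_group = "omnivore_herbivore",
#'                 reproductive_mode = "egg_brooding")
#' encode_traits(a)
encode_traits <- function(assignments) {
  assignments <- validate_trait_assignments(assignments)
  cols <- .trait_columns()
  m <- matrix(0L, nrow = nrow(assignments), ncol = length(cols),
              dimnames = list(assignments$species, cols))
  for (tr in names(.trait_vocabulary)) {
    j <- match(paste(tr, assignments[[tr]], sep = "."), cols)
    m[cbind(seq_len(nrow(m)), j)] <- 1L
  }
  class(m) <- c("trait_matrix", class(m))
  m
}

#' Validate a one-hot trait matrix
#'
#' @param x Matrix with the 17 fixed trait-modality columns.
#' @return The matrix, invisibly, after checking the one-hot block
#'   structure (each row sums to 1 within every trait block).
#' @export
validate_trait_matrix <- function(x) {
  cols <- .trait_columns()
  if (is.null(colnames(x)) || !identical(colnames(x), cols)) {
    stop("trait matrix must have the 17 fixed modality columns in order")
  }
  if (!all(x %in% c(0L, 1L))) stop("trait matrix values must be 0/1")
  offset <- 0L
  for (tr in names(.trait_vocabulary)) {
    w <- offset + seq_along(.trait_vocabulary[[tr]])
    rs <- rowSums(x[, w, drop = FALSE])
    if (any(rs != 1)) {
      bad <- which(rs != 1)[1]
      stop(sprintf("row '%s' is not one-hot in trait block '%s'",
                   rownames(x)[bad], tr))
    }
    offset <- offset + length(w)
  }
  invisible(x)
}

#' Decode a one-hot trait matrix back to modality labels
#'
#' @param x Validated `trait_matrix`.
#' @return Data frame with `species` and one modality column per trait;
#'   the inverse of [encode_traits()].
#' @export
decode_traits <- function(x) {
  validate_trait_matrix(x)
  out <- data.frame(species = rownames(x), stringsAsFactors = FALSE)
  offset <- 0L
  for (tr in names(.trait_vocabulary)) {
    mods <- .trait_vocabulary[[tr]]
    block <- x[, offset + seq_along(mods), drop = FALSE]
    out[[tr]] <- mods[max.col(block, ties.method = "first")]
    offset <- offset + length(mods)
  }
  out
}
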