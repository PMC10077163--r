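# End-to-end orchestration: encode -> cluster -> dominance ->
# composition -> seasonal tests -> RDA, from a config list or YAML file.

#' Summarize functional groups in the style of a published group table
#'
#' @param groups Data frame `species`/`group` (e.g. from [cut_tree()]).
#' @param assignments Trait assignment data frame covering the grouped
#'   species, optionally with a `higher_taxon` column.
#' @return Data frame, one row per group: `group`, `size`,
#'   `taxa` and one column per trait, each a `"; "`-joined list of the
#'   distinct modalities present, in vocabulary order.
#' @export
summarize_groups <- function(groups, assignments) {
  assignments <- validate_trait_assignments(assignments)
  missing <- setdiff(groups$species, assignments$species)
  if (length(missing)) {
    stop("no trait assignment for grouped species: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(groups$species, assignments$species)
  out <- lapply(sort(unique(groups$group)), function(g) {
    rows <- idx[groups$group == g]
    row <- data.frame(group = g, size = length(rows))
    row$taxa <- if ("higher_taxon" %in% names(assignments)) {
      paste(sort(unique(assignments$higher_taxon[rows])), collapse = "; ")
    } else NA_character_
    for (tr in names(.trait_vocabulary)) {
      present <- unique(assignments[[tr]][rows])
      ordered <- .trait_vocabulary[[tr]][.trait_vocabulary[[tr]] %in% present]
      row[[tr]] <- paste(ordered, collapse = "; ")
    }
    row
  })
  do.call(rbind, out)
}

.pipeline_defaults <- list(
  gower_mode = "categorical_traits",
  ward_variant = "ward.D2",
  k_max = NULL, k = NULL,
  dominance_threshold = 0.02,
  exclude = character(),
  rda_permutations = 999,
  fixture_coverage = "full",
  seed = 1)

#' Run the full trait-based community analysis
#'
#' Executes encoding, Gower + Ward clustering with elbow selection (or a
#' `k` override), dominance screening per season, composition by higher
#' taxon / trait modality / functional group, per-station functional
#' richness, seasonal Wilcoxon tests on trait modalities, and seasonal +
#' pooled RDA. Inputs are either CSV paths (`abundance`, `env`, `traits`)
#' or `simulate = TRUE`, in which case a seeded synthetic cruise set is
#' generated.
#'
#' @param config Named list, or path to a YAML file with the same keys:
#'   `abundance`, `env`, `traits` (CSV paths) or `simulate`; optional
#'   `gower_mode`, `ward_variant`, `k_max`, `k`, `dominance_threshold`,
#'   `exclude` (species kept out of trait/group analyses, e.g. larvae),
#'   `rda_permutations`, `seed`.
#' @param out_dir Optional directory; when given, per-stage CSV/JSON
#'   artifacts and a `report.json` are written there.
#' @return List of class `run_report` with the per-stage results, the
#'   echoed config, and the package version.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)

  if (isTRUE(cfg$simulate)) {
    sim_cfg <- simulation_config(seed = cfg$seed)
    env <- generate_env(sim_cfg)
    traits_fx <- table3_fixture(coverage = cfg$fixture_coverage)
    community <- generate_community(sim_cfg, env, traits_fx)
    abundance <- community$abundance
    assignments <- traits_fx$assignments
  } else {
    for (key in c("abundance", "env", "traits")) {
      if (is.null(cfg[[key]])) stop("config lacks input path: ", key)
    }
    abundance <- read_abundance_csv(cfg$abundance)
    env <- read_env_csv(cfg$env)
    assignments <- read_trait_csv(cfg$traits)
  }

  analyzed <- setdiff(abundance$species, cfg$exclude)
  missing <- setdiff(analyzed, assignments$species)
  if (length(missing)) {
    stop("trait stage: no trait assignment for species: ",
         paste(missing, collapse = ", "))
  }
  assignments <- assignments[assignments$species %in% analyzed, , drop = FALSE]
  tm <- encode_traits(assignments)

  d <- gower_dissimilarity(tm, mode = cfg$gower_mode)
  dend <- ward_cluster(d, variant = cfg$ward_variant)
  elbow <- if (nrow(tm) >= 3) elbow_select(d, dend, k_max = cfg$k_max) else NULL
  k <- if (!is.null(cfg$k)) as.integer(cfg$k) else if (!is.null(elbow)) {
    elbow$selected_k
  } else stop("too few species for elbow selection; set k explicitly")
  groups <- cut_tree(dend, k)
  group_map <- stats::setNames(groups$group, groups$species)

  seasons_present <- intersect(.seasons, unique(abundance$stations$season))
  dom <- lapply(seasons_present, function(s) dominance(abundance, s,
                                                       cfg$dominance_threshold))
  names(dom) <- seasons_present

  taxon_map <- if ("higher_taxon" %in% names(assignments)) {
    stats::setNames(assignments$higher_taxon, assignments$species)
  } else NULL
  comp <- list(
    functional_group = composition(abundance, group_map, "season",
                                   exclude = cfg$exclude))
  if (!is.null(taxon_map)) {
    comp$higher_taxon <- composition(abundance, taxon_map, "season",
                                     exclude = cfg$exclude)
  }
  for (tr in names(.trait_vocabulary)) {
    comp[[tr]] <- composition(abundance,
                              stats::setNames(assignments[[tr]],
                                              assignments$species),
                              "season", exclude = cfg$exclude)
  }

  richness <- functional_richness(abundance, group_map)

  # seasonal Wilcoxon tests on per-station abundance of each trait modality
  wilcoxon <- NULL
  if (length(seasons_present) >= 2) {
    pairs <- utils::combn(seasons_present, 2, simplify = FALSE)
    rows <- list()
    for (tr in names(.trait_vocabulary)) {
      mod_map <- stats::setNames(assignments[[tr]], assignments$species)
      ga <- group_abundance(abundance, mod_map)
      for (mod in colnames(ga)) {
        for (pr in pairs) {
          sel1 <- abundance$stations$season == pr[1]
          sel2 <- abundance$stations$season == pr[2]
          w <- wilcoxon_rank_sum(ga[sel1, mod], ga[sel2, mod])
          rows[[length(rows) + 1]] <- data.frame(
            trait = tr, modality = mod, season_a = pr[1], season_b = pr[2],
            statistic = w$statistic, p_value = w$p_value,
            stringsAsFactors = FALSE)
        }
      }
    }
    wilcoxon <- do.call(rbind, rows)
  }

  ga_groups <- group_abundance(abundance, group_map)
  env_vals <- env$values
  if (!identical(rownames(env_vals), rownames(ga_groups))) {
    stop("rda stage: environment and abundance station sets differ")
  }
  rda <- list(pooled = rda_fit(ga_groups, env_vals))
  rda_p <- rda_permutation_test(ga_groups, env_vals,
                                n_perm = cfg$rda_permutations,
                                seed = cfg$seed)
  for (s in seasons_present) {
    sel <- abundance$stations$season == s
    if (sum(sel) >= 3) {
      rda[[s]] <- suppressWarnings(
        rda_fit(ga_groups[sel, , drop = FALSE], env_vals[sel, , drop = FALSE]))
    }
  }

  report <- structure(list(
    config = cfg,
    selected_k = k,
    elbow = elbow,
    groups = groups,
    group_summary = summarize_groups(groups, assignments),
    dominance = dom,
    dominant_taxa = count_dominant_taxa(dom, cfg$dominance_threshold),
    composition = comp,
    richness = richness,
    wilcoxon = wilcoxon,
    rda = rda,
    rda_permutation = rda_p,
    version = as.character(utils::packageVersion("planktraits"))),
    class = "run_report")

  if (!is.null(out_dir)) .write_report(report, dend, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("planktraits run_report\n")
  cat(sprintf("  functional groups: k = %d (%s)\n", x$selected_k,
              if (is.null(x$elbow)) "override" else x$elbow$rule))
  cat(sprintf("  dominant taxa: %d\n", x$dominant_taxa))
  cat(sprintf("  pooled RDA explained: %.1f%% (perm p = %.4g)\n",
              100 * x$rda$pooled$explained_fraction,
              x$rda_permutation$p_value))
  invisible(x)
}

.write_report <- function(report, dend, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  w(report$groups, "groups.csv")
  w(report$group_summary, "group_summary.csv")
  for (s in names(report$dominance)) w(report$dominance[[s]],
                                       paste0("dominance_", s, ".csv"))
  for (k in names(report$composition)) w(report$composition[[k]],
                                         paste0("composition_", k, ".csv"))
  w(report$richness, "richness.csv")
  if (!is.null(report$wilcoxon)) w(report$wilcoxon, "wilcoxon.csv")
  writeLines(export_dendrogram(dend, "newick"),
             file.path(out_dir, "dendrogram.nwk"))
  jsonlite::write_json(list(
    config = report$config,
    selected_k = report$selected_k,
    elbow = if (is.null(report$elbow)) NULL else
      list(k_values = report$elbow$k_values, wss = report$elbow$wss,
           selected_k = report$elbow$selected_k, rule = report$elbow$rule),
    dominant_taxa = report$dominant_taxa,
    rda_explained_fraction = lapply(report$rda,
                                    function(r) r$explained_fraction),
    rda_permutation_p = report$rda_permutation$p_value,
    version = report$version),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
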