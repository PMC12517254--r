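#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Paths may point at PDB or
#' mmCIF files; `l_max` defaults to the query length at run time.
#'
#' @param query,target structure file paths.
#' @param query_chains,target_chains optional chain filters.
#' @param anm an [anm_params()].
#' @param l_min,l_max tile-length bounds.
#' @param r_min,r_max cysteine SG - iron distance bounds (Angstrom).
#' @param n_random,n_guided weight-optimizer budgets.
#' @param seed integer seed for the stochastic stage (weight optimizer).
#' @param gap_opening,gap_extension Smith-Waterman gap penalties.
#' @param fe_cluster_names hetero-group names treated as iron cofactors.
#' @param out_dir output directory (`NULL` = no files written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(query, target, query_chains = NULL,
                            target_chains = NULL, anm = anm_params(),
                            l_min = 6L, l_max = NULL,
                            r_min = 2.18, r_max = 2.35,
                            n_random = 15L, n_guided = 100L, seed = 1L,
                            gap_opening = 0, gap_extension = 0,
                            fe_cluster_names = c("SF4", "FES", "F3S", "FE"),
                            out_dir = NULL) {
  structure(list(query = query, target = target,
                 query_chains = query_chains, target_chains = target_chains,
                 anm = anm, l_min = as.integer(l_min),
                 l_max = if (is.null(l_max)) NULL else as.integer(l_max),
                 r_min = r_min, r_max = r_max,
                 n_random = as.integer(n_random),
                 n_guided = as.integer(n_guided), seed = as.integer(seed),
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 fe_cluster_names = fe_cluster_names, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full comparative-dynamics pipeline
#'
#' Executes every stage in order: load structures, extract iron sites,
#' compute elastic-network cross-correlations, score all query-target tile
#' pairs on the three metrics, choose metric weights by Bayesian
#' optimization, build the length-by-center weighted-similarity landscape,
#' apply the cysteine-iron coordination filter, segment islands, trace the
#' optimal tile path through each island, pick each path's converged tile
#' length, and assemble the final match records. With `out_dir` set, the
#' score table, optimization trace, islands, paths, matches, the paired
#' structure-vs-dynamics export and a PyMOL highlight script are written
#' there together with a manifest. Re-running with the same config and
#' seed reproduces all numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with elements `query`, `target`,
#'   `fe_sites`, `scores`, `weights` (a `weight_opt`), `landscape`,
#'   `islands`, `paths`, `convergence`, `matches`,
#'   `dynamics_vs_structure`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  query <- stage("load_query",
                 load_structure(config$query, chains = config$query_chains))
  target <- stage("load_target",
                  load_structure(config$target, chains = config$target_chains))
  fe_sites <- stage("fe_sites",
                    extract_fe_sites(config$target,
                                     cluster_names = config$fe_cluster_names))
  corr_q <- stage("anm_query", anm_cross_correlation(query, config$anm))
  corr_t <- stage("anm_target", anm_cross_correlation(target, config$anm))
  l_max <- if (is.null(config$l_max)) n_residues(query) else
    min(config$l_max, n_residues(query), n_residues(target))
  scores <- stage("tile_scores",
                  score_all_lengths(corr_q, corr_t, query, target,
                                    l_min = config$l_min, l_max = l_max,
                                    gap_opening = config$gap_opening,
                                    gap_extension = config$gap_extension))
  wopt <- stage("weights",
                optimize_weights(scores, n_random = config$n_random,
                                 n_guided = config$n_guided,
                                 seed = config$seed))
  landscape <- stage("landscape",
                     build_tile_matrix(scores, wopt$weights,
                                       target_n = n_residues(target)))
  filtered <- stage("cys_fe_filter",
                    cys_fe_filter(landscape, target, fe_sites,
                                  r_min = config$r_min, r_max = config$r_max))
  islands <- stage("islands", segment_islands(filtered))
  paths <- list(); convergence <- list()
  for (k in seq_len(nrow(islands))) {
    id <- islands$island_id[k]
    paths[[id]] <- stage(paste0("path_", id),
                         island_optimal_path(filtered, islands[k, ]))
    st <- paths[[id]]$steps
    convergence[[id]] <- if (nrow(st) >= 5)
      convergence_length(st$row_length, st$value)
    else list(l_opt = st$row_length[which.max(st$value)], converged = FALSE)
  }
  matches <- stage("matches",
                   assemble_matches(paths, islands, target,
                                    convergence = convergence))
  dvs <- if (any(scores$length == min(30L, l_max)))
    export_dynamics_vs_structure(scores, L = min(30L, l_max),
                                 target_id = attr(target, "source_id"))
  else NULL
  result <- structure(list(query = query, target = target,
                           fe_sites = fe_sites, scores = scores,
                           weights = wopt, landscape = filtered,
                           islands = islands, paths = paths,
                           convergence = convergence, matches = matches,
                           dynamics_vs_structure = dvs,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: query %s (N=%d) vs target %s (N=%d)\n",
                     "  %d scored tile pairs, %d iron sites, %d island(s)\n"),
              attr(x$query, "source_id"), n_residues(x$query),
              attr(x$target, "source_id"), n_residues(x$target),
              nrow(x$scores), nrow(x$fe_sites), nrow(x$islands)))
  if (nrow(x$matches) > 0) {
    cat("  matches:\n")
    print(x$matches[, c("island_id", "length", "center", "auth_start",
                        "auth_end", "s_weighted", "converged")])
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(as.data.frame(result$scores), "score_table.tsv")
  tsv(result$weights$trace, "weight_trace.tsv")
  tsv(result$islands, "islands.tsv")
  for (id in names(result$paths))
    tsv(result$paths[[id]]$steps, sprintf("path_%s.tsv", id))
  write_match_table(result$matches, file.path(out_dir, "matches.tsv"))
  if (!is.null(result$dynamics_vs_structure))
    tsv(result$dynamics_vs_structure, "dynamics_vs_structure.tsv")
  if (nrow(result$matches) > 0)
    write_pymol_script(result$matches, file.path(out_dir, "matches.pml"),
                       object = attr(result$target, "source_id"))
  cfg <- result$config
  manifest <- c(
    sprintf("dynatile_version: %s",
            as.character(utils::packageVersion("dynatile"))),
    sprintf("query: %s", cfg$query),
    sprintf("target: %s", cfg$target),
    sprintf("seed: %d", cfg$seed),
    sprintf("gamma: %g", cfg$anm$gamma),
    sprintf("cutoff: %g", cfg$anm$cutoff),
    sprintf("n_modes: %d", cfg$anm$n_modes),
    sprintf("l_min: %d", cfg$l_min),
    sprintf("r_min: %g", cfg$r_min),
    sprintf("r_max: %g", cfg$r_max),
    sprintf("n_random: %d", cfg$n_random),
    sprintf("n_guided: %d", cfg$n_guided))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
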