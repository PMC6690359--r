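#' Pipeline configuration
#'
#' Collects every tunable of the six-step workflow in one serializable
#' list: the fold-ratio threshold, the interaction-confidence cutoff, the
#' relevance and penalty strengths, the outer-gene flag, terrain grid and
#' kernel width, the single-cell detection threshold, and the seeds. Either
#' supply input paths (\code{inputs}) or let the pipeline simulate its own
#' inputs (\code{simulate = TRUE}, the default) from \code{sim}.
#'
#' @param out_dir Directory the run writes into (created if needed).
#' @param threshold Heavy/light ratio threshold, strict (default 1.2).
#' @param mode Ratio-filter database mode, \code{"any_db"} or
#'   \code{"primary_db"}.
#' @param min_confidence Minimum interaction confidence (default 0.7).
#' @param alpha Relevance network-boost strength (default 1).
#' @param beta Penalty strength (default 0.5; 0 disables penalties).
#' @param outer Add the one-layer outer-gene extension (default FALSE).
#' @param grid_size,sigma Terrain raster resolution and kernel width.
#' @param height_var Terrain peak height variable: \code{"final"} (combined
#'   score) or \code{"log2ratio"}.
#' @param theta Single-cell detection-fraction threshold (default 0.1).
#' @param combine_method Cross-experiment combination, \code{"geometric"}
#'   or \code{"arithmetic"}.
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param sim A [sim_config()] used when \code{simulate} is TRUE.
#' @param layout_seed Seed for the terrain layout.
#' @param inputs Named list of paths used when \code{simulate} is FALSE:
#'   \code{training}, \code{validation} (ratio TSVs), \code{exclusion},
#'   \code{penalty} (GMTs, optional), \code{ppi} (edge TSV),
#'   \code{ppi_dialect} (\code{"unit"}/\code{"string_1000"}), and
#'   optionally \code{sc_mtx}, \code{sc_genes}, \code{sc_cells}.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir = tempfile("gvtsig_run_"),
                            threshold = 1.2,
                            mode = "any_db",
                            min_confidence = 0.7,
                            alpha = 1,
                            beta = 0.5,
                            outer = FALSE,
                            grid_size = 256L,
                            sigma = 0.05,
                            height_var = c("final", "log2ratio"),
                            theta = 0.1,
                            combine_method = c("geometric", "arithmetic"),
                            simulate = TRUE,
                            sim = sim_config(),
                            layout_seed = 1L,
                            inputs = NULL) {
  structure(list(out_dir = out_dir, threshold = threshold, mode = mode,
                 min_confidence = min_confidence, alpha = alpha, beta = beta,
                 outer = isTRUE(outer), grid_size = as.integer(grid_size),
                 sigma = sigma, height_var = match.arg(height_var),
                 theta = theta, combine_method = match.arg(combine_method),
                 simulate = isTRUE(simulate), sim = sim,
                 layout_seed = as.integer(layout_seed), inputs = inputs),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full six-step signature pipeline
#'
#' Executes, in order: (1) input acquisition — simulation of paired
#' labeling experiments or loading from files; (2) strict fold-ratio
#' filtering of each experiment; (3) exclusion-set removal of
#' disease-confounded proteins; (4) candidate subnetwork construction
#' (optionally with outer genes) and network-weighted relevance plus
#' other-disease penalty scoring per experiment; (5) cross-experiment
#' combination into the signature; (6) terrain rendering of the scored
#' network and, when single-cell input is available, expression-category
#' overlap. All stage outputs and a JSON manifest with every parameter and
#' seed are written under \code{config$out_dir}; rerunning with the same
#' configuration reproduces the numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results:
#'   \code{bundle} (when simulated), \code{candidates}, \code{subnetworks},
#'   \code{scores}, \code{signature}, \code{terrain}, \code{overlap} (NULL
#'   without single-cell input), \code{manifest}, \code{paths}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  acquired <- run_stage("inputs", {
    if (config$simulate) {
      bundle <- generate_experiments(config$sim)
      list(bundle = bundle,
           tables = bundle$ratio_tables,
           exclusions = bundle$exclusion_sets,
           penalties = bundle$penalty_library,
           network = bundle$network)
    } else {
      inp <- config$inputs
      for (role in c("training", "validation", "ppi"))
        if (is.null(inp[[role]]) || !file.exists(inp[[role]]))
          stop("required input '", role, "' missing or not found: ",
               if (is.null(inp[[role]])) "(no path given)" else inp[[role]])
      list(bundle = NULL,
           tables = list(
             training = read_ratio_table(inp$training, "training"),
             validation = read_ratio_table(inp$validation, "validation")),
           exclusions = if (!is.null(inp$exclusion)) read_gmt(inp$exclusion)
                        else list(),
           penalties = if (!is.null(inp$penalty)) read_gmt(inp$penalty)
                       else list(),
           network = read_ppi_edges(inp$ppi,
                                    score_dialect = inp$ppi_dialect %||% "unit"))
    }
  })

  candidates <- run_stage("filter", lapply(acquired$tables, function(tab)
    exclude_genesets(filter_by_ratio(tab, config$threshold, config$mode),
                     acquired$exclusions)))

  scored <- run_stage("score", lapply(candidates, function(cand) {
    sub <- build_subnetwork(acquired$network, cand, config$min_confidence)
    if (config$outer) sub <- extend_outer(acquired$network, sub)
    weights <- if (length(cand$genes)) connectivity_weights(sub)
               else stats::setNames(numeric(0), character(0))
    scores <- final_scores(cand, weights,
                           penalty_factors(cand$genes, acquired$penalties,
                                           config$beta),
                           alpha = config$alpha, beta = config$beta)
    list(subnetwork = sub, scores = scores)
  }))

  signature <- run_stage("combine", combine_experiments(
    scored$training$scores, scored$validation$scores,
    method = config$combine_method))
  paths$signature <- file.path(config$out_dir, "signature.tsv")
  write_signature(signature, paths$signature)

  terrain <- run_stage("terrain", {
    sub_all <- build_subnetwork(acquired$network, signature$gene,
                                config$min_confidence)
    coords <- layout_network(sub_all, seed = config$layout_seed)
    heights <- if (config$height_var == "final")
      stats::setNames(signature$combined_score, signature$gene)
    else {
      r <- ifelse(is.na(signature$final_training), signature$final_validation,
                  signature$final_training)
      stats::setNames(log2(pmax(r, .Machine$double.eps)), signature$gene)
    }
    render_terrain(coords, heights, config$grid_size, config$sigma)
  })
  paths$terrain <- file.path(config$out_dir, "terrain.tsv")
  write_terrain(terrain, paths$terrain)

  overlap <- NULL
  assignment <- NULL
  sc_available <- config$simulate ||
    all(c("sc_mtx", "sc_genes", "sc_cells") %in% names(config$inputs))
  if (sc_available) {
    sc_stage <- run_stage("sc-overlap", {
      sc <- if (config$simulate)
        generate_singlecell(config$sim, signature$gene)$matrix
      else read_singlecell(config$inputs$sc_mtx, config$inputs$sc_genes,
                           config$inputs$sc_cells)
      asg <- classify_genes(detection_fractions(sc), config$theta)
      list(assignment = asg, overlap = overlap_summary(signature, asg))
    })
    assignment <- sc_stage$assignment
    overlap <- sc_stage$overlap
    paths$assignment <- file.path(config$out_dir, "sc_assignment.tsv")
    utils::write.table(as.data.frame(assignment), paths$assignment,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$overlap <- file.path(config$out_dir, "sc_overlap.json")
    jsonlite::write_json(overlap, paths$overlap, auto_unbox = TRUE,
                         digits = NA)
  }

  manifest <- list(
    package = "gvtsig",
    version = as.character(utils::packageVersion("gvtsig")),
    parameters = list(threshold = config$threshold, mode = config$mode,
                      min_confidence = config$min_confidence,
                      alpha = config$alpha, beta = config$beta,
                      outer = config$outer, grid_size = config$grid_size,
                      sigma = config$sigma, height_var = config$height_var,
                      theta = config$theta,
                      combine_method = config$combine_method),
    seeds = list(simulation = if (config$simulate) config$sim$seed else NULL,
                 layout = config$layout_seed),
    simulate = config$simulate,
    inputs = if (!config$simulate) config$inputs else NULL,
    sim = if (config$simulate)
      config$sim[setdiff(names(config$sim), "sc_category_probs")] else NULL,
    stage_counts = list(
      candidates_training = length(candidates$training$genes),
      candidates_validation = length(candidates$validation$genes),
      signature_size = nrow(signature),
      strata = as.list(signature_strata(signature))))
  paths$manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(bundle = acquired$bundle,
                 candidates = candidates,
                 subnetworks = lapply(scored, `[[`, "subnetwork"),
                 scores = lapply(scored, `[[`, "scores"),
                 signature = signature,
                 terrain = terrain,
                 assignment = assignment,
                 overlap = overlap,
                 manifest = manifest,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
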