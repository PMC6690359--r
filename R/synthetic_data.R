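#' Simulation configuration for paired synthetic labeling experiments
#'
#' Bundles every parameter of the synthetic-data generator: sizes of the
#' four ground-truth gene classes, the log-normal ratio model, per-experiment
#' identification dropout, the scale-free interaction network with a planted
#' signature module, the other-disease penalty library, and the reduced-scale
#' single-cell experiment.
#'
#' The defaults define the simulated study conditions: a signature protein's
#' heavy/light ratio is log-normal around 1.6 and truncated above the 1.2
#' selection threshold so that planted signal always passes the fold filter
#' (recovery tests then measure specificity, not luck); background and
#' contaminant proteins fluctuate around ratio 1 with log-sd 0.15; disease
#' confounders mimic signature-sized ratios in the training contrast only.
#'
#' @param n_background Number of background (null) proteins.
#' @param n_signature Number of planted signature proteins.
#' @param n_gvhd Number of GVHD-confounded proteins (always covered by at
#'   least one exclusion set).
#' @param n_contaminant Number of unspecific contaminant proteins (recurrent
#'   members of the other-disease penalty library).
#' @param signature_ratio_logmean,signature_ratio_logsd Log-scale mean/sd of
#'   the signature ratio distribution (left-truncated at 1.2).
#' @param background_ratio_logsd Log-scale sd of the background ratio
#'   distribution (log-mean 0).
#' @param dropout_prob Per-experiment probability that a protein is not
#'   identified at all.
#' @param ppi_attach Preferential-attachment edges added per node when
#'   growing the interaction network.
#' @param planted_extra_edges Extra high-confidence edges planted uniformly
#'   among signature gene pairs (confidence ~ Uniform(0.7, 0.99)).
#' @param n_penalty_sets Number of other-disease gene sets in the penalty
#'   library.
#' @param penalty_decoy_frac Fraction of background genes drawn at random
#'   into each penalty set.
#' @param contaminated_penalty If TRUE, penalty sets may also contain
#'   signature genes (robustness testing); the default FALSE keeps planted
#'   truth recoverable.
#' @param sc_cells_per_condition Cells simulated per stimulation condition
#'   (reduced desk scale; the profiled study averaged 1,436 per condition).
#' @param sc_mu_on,sc_mu_off Negative-binomial mean count where a gene's
#'   truth category says expressed / silent.
#' @param sc_nb_size Negative-binomial size (dispersion) parameter.
#' @param sc_category_probs Named probabilities over the four single-cell
#'   truth categories; the default mirrors the 11/32/18-of-61 partition of
#'   the profiled signature (no CMV-only genes were reported, so that class
#'   defaults to prevalence 0 but remains legal).
#' @param seed Integer seed; a fixed seed makes every generated object
#'   reproducible.
#'
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_background = 700L,
                       n_signature = 60L,
                       n_gvhd = 80L,
                       n_contaminant = 50L,
                       signature_ratio_logmean = log(1.6),
                       signature_ratio_logsd = 0.25,
                       background_ratio_logsd = 0.15,
                       dropout_prob = 0.15,
                       ppi_attach = 2L,
                       planted_extra_edges = 120L,
                       n_penalty_sets = 20L,
                       penalty_decoy_frac = 0.05,
                       contaminated_penalty = FALSE,
                       sc_cells_per_condition = 200L,
                       sc_mu_on = 2.0,
                       sc_mu_off = 0.02,
                       sc_nb_size = 2.0,
                       sc_category_probs = c(prame_specific = 11,
                                             general_activation = 32,
                                             cmv_specific = 0,
                                             not_expressed = 18) / 61,
                       seed = 1L) {
  cfg <- list(n_background = as.integer(n_background),
              n_signature = as.integer(n_signature),
              n_gvhd = as.integer(n_gvhd),
              n_contaminant = as.integer(n_contaminant),
              signature_ratio_logmean = signature_ratio_logmean,
              signature_ratio_logsd = signature_ratio_logsd,
              background_ratio_logsd = background_ratio_logsd,
              dropout_prob = dropout_prob,
              ppi_attach = as.integer(ppi_attach),
              planted_extra_edges = as.integer(planted_extra_edges),
              n_penalty_sets = as.integer(n_penalty_sets),
              penalty_decoy_frac = penalty_decoy_frac,
              contaminated_penalty = isTRUE(contaminated_penalty),
              sc_cells_per_condition = as.integer(sc_cells_per_condition),
              sc_mu_on = sc_mu_on, sc_mu_off = sc_mu_off,
              sc_nb_size = sc_nb_size,
              sc_category_probs = sc_category_probs,
              seed = as.integer(seed))
  with(cfg, stopifnot(
    n_background >= 0, n_signature >= 0, n_gvhd >= 0, n_contaminant >= 0,
    signature_ratio_logsd > 0, background_ratio_logsd > 0,
    dropout_prob >= 0, dropout_prob < 1,
    ppi_attach >= 1, planted_extra_edges >= 0,
    n_penalty_sets >= 0, penalty_decoy_frac >= 0, penalty_decoy_frac < 1,
    sc_cells_per_condition >= 1, sc_mu_on > 0, sc_mu_off >= 0,
    sc_nb_size > 0,
    setequal(names(sc_category_probs),
             c("prame_specific", "general_activation", "cmv_specific",
               "not_expressed")),
    all(sc_category_probs >= 0), sum(sc_category_probs) > 0))
  structure(cfg, class = "sim_config")
}

# Exact inverse-CDF draw from a left-truncated log-normal.
rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a pair of synthetic labeling experiments with ground truth
#'
#' Simulates the full input bundle for the pipeline: two protein ratio
#' tables (training and validation), GVHD exclusion gene sets, an
#' other-disease penalty library, a scale-free interaction network with a
#' dense planted module among the signature genes, and per-gene truth
#' labels.
#'
#' The gene universe is partitioned into four classes. Signature genes draw
#' ratios from a left-truncated log-normal (always above 1.2) in both
#' tables. GVHD genes draw signature-like ratios in the training table —
#' the contrast in which GVHD confounds — and background ratios in the
#' validation table, and every GVHD gene belongs to at least one exclusion
#' set. Background and contaminant genes draw ratios around 1. Each protein
#' independently drops out of each table with probability
#' \code{dropout_prob} (not identified in that experiment).
#'
#' @param config A [sim_config()].
#' @return A \code{synthetic_bundle}: list with \code{ratio_tables}
#'   (\code{$training}, \code{$validation}), \code{exclusion_sets},
#'   \code{penalty_library}, \code{network} (a \code{ppi_network} over the
#'   full universe), \code{truth} (data frame gene, class) and
#'   \code{config}.
#' @export
generate_experiments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tot <- config$n_background + config$n_signature + config$n_gvhd +
    config$n_contaminant
  if (n_tot == 0L) stop("empty gene universe: all class counts are zero")
  genes <- sprintf("GENE%05d", seq_len(n_tot))
  cls <- sample(rep(c("signature", "gvhd", "background", "contaminant"),
                    times = c(config$n_signature, config$n_gvhd,
                              config$n_background, config$n_contaminant)))
  truth <- data.frame(gene = genes, class = cls, stringsAsFactors = FALSE)
  accession <- sprintf("P%05d", seq_len(n_tot))

  draw_ratios <- function(confound_gvhd) {
    r <- numeric(n_tot)
    is_sig <- cls == "signature"
    is_gvhd <- cls == "gvhd"
    sig_like <- is_sig | (is_gvhd & confound_gvhd)
    r[sig_like] <- rlnorm_trunc(sum(sig_like),
                                config$signature_ratio_logmean,
                                config$signature_ratio_logsd, 1.2)
    r[!sig_like] <- stats::rlnorm(sum(!sig_like), 0,
                                  config$background_ratio_logsd)
    r
  }
  make_table <- function(experiment_id, confound_gvhd) {
    ratio <- draw_ratios(confound_gvhd)
    peptide_count <- 1L + stats::rpois(n_tot, 4)
    keep <- stats::runif(n_tot) >= config$dropout_prob
    rec <- data.frame(accession = accession[keep],
                      gene_symbol = genes[keep],
                      ratio = ratio[keep],
                      peptide_count = peptide_count[keep],
                      search_db = "swissprot",
                      stringsAsFactors = FALSE)
    ratio_table(experiment_id, rec)
  }
  tab_train <- make_table("IPAS-01", confound_gvhd = TRUE)
  tab_valid <- make_table("IPAS-02", confound_gvhd = FALSE)

  gvhd_genes <- genes[cls == "gvhd"]
  exclusion_sets <- list()
  if (length(gvhd_genes) > 0L) {
    gshuf <- sample(gvhd_genes)
    k <- max(1L, ceiling(0.6 * length(gshuf)))
    exclusion_sets <- list(
      gene_set("GVHD_PRIOR_UP", "proteins upregulated in prior GVHD contrasts",
               gshuf[seq_len(k)]),
      gene_set("GVHD_COMMON_PLASMA", "recurrent GVHD-associated plasma proteins",
               gshuf[seq(length(gshuf) - k + 1L, length(gshuf))]))
  }

  cont_genes <- genes[cls == "contaminant"]
  bg_genes <- genes[cls == "background"]
  sig_genes <- genes[cls == "signature"]
  penalty_library <- vector("list", config$n_penalty_sets)
  n_decoy <- floor(config$penalty_decoy_frac * length(bg_genes))
  for (i in seq_len(config$n_penalty_sets)) {
    members <- character(0)
    if (length(cont_genes) > 0L)
      members <- sample(cont_genes, max(1L, ceiling(length(cont_genes) / 2)))
    if (n_decoy > 0L)
      members <- c(members, sample(bg_genes, n_decoy))
    if (config$contaminated_penalty && length(sig_genes) > 0L)
      members <- c(members, sample(sig_genes,
                                   max(1L, ceiling(0.05 * length(sig_genes)))))
    penalty_library[[i]] <- gene_set(sprintf("OTHER_DISEASE_%02d", i),
                                     "unspecific proteins seen in another disease",
                                     members)
  }
  penalty_library <- Filter(Negate(is.null), penalty_library)

  pa <- igraph::sample_pa(n_tot, power = 1, m = config$ppi_attach,
                          directed = FALSE)
  el <- igraph::as_edgelist(pa, names = FALSE)
  perm <- sample(n_tot)   # detach attachment order from gene identity
  edges <- data.frame(gene_a = genes[perm[el[, 1]]],
                      gene_b = genes[perm[el[, 2]]],
                      confidence = stats::runif(nrow(el), 0.15, 0.95),
                      stringsAsFactors = FALSE)
  if (config$planted_extra_edges > 0L && length(sig_genes) >= 2L) {
    pairs <- t(utils::combn(sig_genes, 2L))
    take <- sample(nrow(pairs), min(config$planted_extra_edges, nrow(pairs)))
    edges <- rbind(edges,
                   data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                              confidence = stats::runif(length(take), 0.7, 0.99),
                              stringsAsFactors = FALSE))
  }
  network <- ppi_network(edges, nodes = genes)

  structure(list(ratio_tables = list(training = tab_train,
                                     validation = tab_valid),
                 exclusion_sets = exclusion_sets,
                 penalty_library = penalty_library,
                 network = network,
                 truth = truth,
                 config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle: ", nrow(x$truth), " genes (",
      paste(sprintf("%s=%d", names(table(x$truth$class)),
                    as.integer(table(x$truth$class))), collapse = ", "),
      ")\n  tables: ", x$ratio_tables$training$experiment_id, " (",
      nrow(x$ratio_tables$training$records), "), ",
      x$ratio_tables$validation$experiment_id, " (",
      nrow(x$ratio_tables$validation$records), ")\n  network: ",
      length(x$network$nodes), " nodes / ", nrow(x$network$edges),
      " edges; ", length(x$penalty_library), " penalty sets\n", sep = "")
  invisible(x)
}

#' Generate a labeled synthetic single-cell count matrix
#'
#' Simulates antigen-stimulated T-cell populations at reduced scale: five
#' conditions (CMVpp65+/-, PRAME+/-, nonreactive) with
#' \code{sc_cells_per_condition} cells each. Every input gene is assigned a
#' truth category; counts are negative-binomial with mean \code{sc_mu_on}
#' in conditions where the category says expressed (PRAME+ for
#' prame_specific, CMVpp65+ for cmv_specific, both for general_activation)
#' and \code{sc_mu_off} everywhere else.
#'
#' @param config A [sim_config()].
#' @param signature_genes Non-empty character vector of gene symbols to
#'   simulate (typically the combined signature).
#' @param conditions Condition tags to simulate; at least two of the five
#'   recognized tags, and the positives needed by the sampled categories.
#' @return List with \code{matrix} (a \code{singlecell_matrix}) and
#'   \code{truth} (data frame gene, category).
#' @export
generate_singlecell <- function(config, signature_genes,
                                conditions = c("cmv_pos", "cmv_neg",
                                               "prame_pos", "prame_neg",
                                               "nonreactive")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(signature_genes) == 0L)
    stop("signature_genes must be non-empty")
  if (length(conditions) < 2L)
    stop("at least 2 cell conditions must be configured")
  signature_genes <- toupper(signature_genes)
  set.seed(config$seed + 7919L)

  cats <- names(config$sc_category_probs)
  category <- sample(cats, length(signature_genes), replace = TRUE,
                     prob = config$sc_category_probs)
  on_conditions <- list(prame_specific = "prame_pos",
                        cmv_specific = "cmv_pos",
                        general_activation = c("cmv_pos", "prame_pos"),
                        not_expressed = character(0))

  n_cond <- length(conditions)
  n_cells <- config$sc_cells_per_condition
  condition_of <- rep(conditions, each = n_cells)
  cell_ids <- sprintf("%s_c%03d", condition_of, rep(seq_len(n_cells), n_cond))
  counts <- matrix(0L, nrow = length(signature_genes),
                   ncol = length(cell_ids),
                   dimnames = list(signature_genes, cell_ids))
  for (i in seq_along(signature_genes)) {
    mu <- ifelse(condition_of %in% on_conditions[[category[i]]],
                 config$sc_mu_on, config$sc_mu_off)
    counts[i, ] <- stats::rnbinom(length(mu), mu = mu,
                                  size = config$sc_nb_size)
  }
  sc <- singlecell_matrix(Matrix::Matrix(counts, sparse = TRUE),
                          stats::setNames(condition_of, cell_ids))
  list(matrix = sc,
       truth = data.frame(gene = signature_genes, category = category,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits the exact formats the readers consume: two ratio TSVs, exclusion
#' and penalty GMTs, and a STRING-style edge TSV, plus the truth labels.
#'
#' @param bundle A \code{synthetic_bundle}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    training = file.path(dir, "ratios_training.tsv"),
    validation = file.path(dir, "ratios_validation.tsv"),
    exclusion = file.path(dir, "exclusion.gmt"),
    penalty = file.path(dir, "penalty.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_ratio_table(bundle$ratio_tables$training, paths$training)
  write_ratio_table(bundle$ratio_tables$validation, paths$validation)
  if (length(bundle$exclusion_sets)) write_gmt(bundle$exclusion_sets, paths$exclusion)
  if (length(bundle$penalty_library)) write_gmt(bundle$penalty_library, paths$penalty)
  write_ppi_edges(bundle$network, paths$ppi)
  utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Precision and recall of planted signature genes in a recovered signature
#'
#' Ranks the combined signature by descending combined score (ties broken
#' alphabetically), takes the top \code{n_top} genes as the recovered set,
#' and scores it against the planted truth: precision is the fraction of
#' recovered genes that are planted signature genes, recall the fraction of
#' all planted signature genes recovered. By default \code{n_top} equals
#' the number of planted signature genes, the standard planted-module
#' evaluation size.
#'
#' @param signature A \code{combined_signature}.
#' @param truth Truth data frame (gene, class) from
#'   [generate_experiments()].
#' @param n_top Size of the recovered set (default: number of planted
#'   signature genes).
#' @return List with \code{precision}, \code{recall}, \code{n_top},
#'   \code{n_planted}, \code{true_positives}.
#' @export
evaluate_recovery <- function(signature, truth, n_top = NULL) {
  stopifnot(inherits(signature, "combined_signature"))
  planted <- truth$gene[truth$class == "signature"]
  if (length(planted) == 0L)
    stop("recovery evaluation requested but the truth labels contain no ",
         "planted signature genes (n_signature = 0)")
  df <- as.data.frame(signature)
  df <- df[order(-df$combined_score, df$gene), , drop = FALSE]
  if (is.null(n_top)) n_top <- length(planted)
  top <- utils::head(df$gene, n_top)
  tp <- sum(top %in% planted)
  list(precision = tp / length(top),
       recall = tp / length(planted),
       n_top = length(top),
       n_planted = length(planted),
       true_positives = tp)
}
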