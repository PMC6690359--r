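#' Normalized network connectivity weights for core genes
#'
#' For every core gene g, the raw network support is the sum of confidences
#' of retained subnetwork edges from g to any other retained node (core or
#' outer). Weights are normalized by the maximum raw support over core
#' genes, giving a connectivity weight in [0, 1]; if every core gene is
#' isolated all weights are 0. Outer genes receive no weight — they lend
#' support but are not themselves scored.
#'
#' @param sub A \code{subnetwork} with at least one core gene.
#' @return Named numeric vector over core genes, values in [0, 1].
#' @export
connectivity_weights <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"), length(sub$core_genes) > 0L)
  raw <- stats::setNames(numeric(length(sub$core_genes)), sub$core_genes)
  if (nrow(sub$edges) > 0L) {
    for (side in c("gene_a", "gene_b")) {
      s <- tapply(sub$edges$confidence, sub$edges[[side]], sum)
      s <- s[names(s) %in% sub$core_genes]
      raw[names(s)] <- raw[names(s)] + as.numeric(s)
    }
  }
  mx <- max(raw)
  if (mx > 0) raw / mx else raw
}

#' Network-weighted relevance scores
#'
#' relevance(g) = ratio(g) * (1 + alpha * c(g)), where c(g) is the
#' normalized connectivity weight. The ratio stays the primary datum: a
#' gene with no network support keeps its raw ratio, and alpha = 0 turns
#' the network weighting off entirely.
#'
#' @param candidates A \code{candidate_set}.
#' @param weights Named connectivity weights from [connectivity_weights()];
#'   candidates missing from it get weight 0.
#' @param alpha Non-negative strength of the network boost (default 1).
#' @return Named numeric vector of relevance scores over the candidates.
#' @export
relevance_scores <- function(candidates, weights, alpha = 1) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (alpha < 0) stop("alpha must be non-negative")
  w <- weights[candidates$genes]
  w[is.na(w)] <- 0
  stats::setNames(candidates$ratio_of * (1 + alpha * as.numeric(w)),
                  candidates$genes)
}

#' Other-disease penalty factors
#'
#' Counts, for each gene, the number k of penalty-library sets containing
#' it and converts the count to a multiplicative factor
#' 1 / (1 + beta * k) in (0, 1]. beta = 0 switches penalties off (every
#' factor 1). With the default beta = 0.5, membership in two other-disease
#' sets already halves a final score — a more-than-two-fold modification of
#' the kind penalty scoring is meant to produce for recurrently unspecific
#' proteins.
#'
#' @param genes Character vector of gene symbols.
#' @param penalty_library List of \code{gene_set} objects.
#' @param beta Non-negative penalty strength (default 0.5).
#' @return Data frame with columns \code{gene}, \code{penalty_hits},
#'   \code{penalty_factor}.
#' @export
penalty_factors <- function(genes, penalty_library = list(), beta = 0.5) {
  if (beta < 0) stop("beta must be non-negative")
  hits <- stats::setNames(integer(length(genes)), genes)
  for (s in penalty_library) {
    stopifnot(inherits(s, "gene_set"))
    inset <- genes %in% s$members
    hits[inset] <- hits[inset] + 1L
  }
  data.frame(gene = genes,
             penalty_hits = as.integer(hits),
             penalty_factor = 1 / (1 + beta * as.integer(hits)),
             stringsAsFactors = FALSE)
}

#' Per-experiment final candidate scores
#'
#' Chains the scoring formulas for one experiment:
#' relevance = ratio * (1 + alpha * connectivity), then
#' final = relevance / (1 + beta * penalty_hits). Both the penalized final
#' score and the penalty-free score (beta = 0 column,
#' \code{score_nopenalty}) are reported, and penalization never removes a
#' gene — it reorders without altering the primary data, so final scores
#' below 1 are legal and retained. Output is sorted by descending final
#' score, ties broken alphabetically.
#'
#' @param candidates A \code{candidate_set}.
#' @param weights Connectivity weights from [connectivity_weights()].
#' @param penalties Data frame from [penalty_factors()] (computed with the
#'   same \code{beta}); missing genes are treated as unpenalized.
#' @param alpha Network boost strength (default 1).
#' @param beta Penalty strength the factors were computed with (default
#'   0.5); recorded and used to recompute factors if \code{penalties} is
#'   NULL.
#' @param penalty_library Used only when \code{penalties} is NULL.
#' @return A \code{candidate_scores} data frame: gene, experiment_id,
#'   ratio, connectivity, relevance, penalty_hits, penalty_factor,
#'   final_score, score_nopenalty.
#' @export
final_scores <- function(candidates, weights, penalties = NULL,
                         alpha = 1, beta = 0.5, penalty_library = list()) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (alpha < 0) stop("alpha must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (is.null(penalties))
    penalties <- penalty_factors(candidates$genes, penalty_library, beta)
  w <- weights[candidates$genes]
  w[is.na(w)] <- 0
  w <- as.numeric(w)
  rel <- relevance_scores(candidates, weights, alpha)
  idx <- match(candidates$genes, penalties$gene)
  hits <- ifelse(is.na(idx), 0L, penalties$penalty_hits[idx])
  fac <- 1 / (1 + beta * hits)
  df <- data.frame(gene = candidates$genes,
                   experiment_id = candidates$experiment_id,
                   ratio = as.numeric(candidates$ratio_of),
                   connectivity = w,
                   relevance = as.numeric(rel),
                   penalty_hits = as.integer(hits),
                   penalty_factor = fac,
                   final_score = as.numeric(rel) * fac,
                   score_nopenalty = as.numeric(rel),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$final_score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("candidate_scores", "data.frame")
  df
}

#' Combine two experiments into one signature
#'
#' Takes the per-experiment score lists of the training and validation
#' experiments and combines them over the union of their genes. A gene
#' present in both experiments gets the geometric mean of its two final
#' scores (scale-respecting for ratio-like scores; arithmetic mean
#' available); a gene seen in only one experiment carries that experiment's
#' final score. No score cutoff is applied — sub-1 combined scores remain
#' members. The attached \code{strata} attribute counts genes with combined
#' score above 1, below 1, and exactly 1.
#'
#' @param a,b \code{candidate_scores} from two distinct experiments
#'   (training first by convention).
#' @param method \code{"geometric"} (default) or \code{"arithmetic"} mean
#'   for genes present in both.
#' @return A \code{combined_signature} data frame: gene, combined_score,
#'   provenance (training_only / validation_only / both), final_training,
#'   final_validation; sorted by descending combined score then gene.
#' @export
combine_experiments <- function(a, b, method = c("geometric", "arithmetic")) {
  stopifnot(inherits(a, "candidate_scores"), inherits(b, "candidate_scores"))
  method <- match.arg(method)
  id_a <- unique(a$experiment_id)
  id_b <- unique(b$experiment_id)
  if (identical(id_a, id_b))
    stop("the two score lists come from the same experiment: ", id_a)
  genes <- sort(union(a$gene, b$gene))
  fa <- a$final_score[match(genes, a$gene)]
  fb <- b$final_score[match(genes, b$gene)]
  provenance <- ifelse(!is.na(fa) & !is.na(fb), "both",
                       ifelse(!is.na(fa), "training_only", "validation_only"))
  combined <- ifelse(provenance == "both",
                     if (method == "geometric") sqrt(fa * fb)
                     else (fa + fb) / 2,
                     ifelse(is.na(fa), fb, fa))
  df <- data.frame(gene = genes,
                   combined_score = combined,
                   provenance = provenance,
                   final_training = fa,
                   final_validation = fb,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$combined_score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("combined_signature", "data.frame")
  attr(df, "experiments") <- c(training = id_a, validation = id_b)
  attr(df, "strata") <- c(gt1 = sum(df$combined_score > 1),
                          lt1 = sum(df$combined_score < 1),
                          eq1 = sum(df$combined_score == 1))
  df
}

#' Count the combined-score strata of a signature
#'
#' Tallies signature genes with combined score above 1, below 1, and
#' exactly 1 (the last flagged separately rather than folded into either
#' stratum), plus the total — the summary by which a combined signature is
#' usually reported.
#'
#' @param signature A \code{combined_signature}.
#' @return Named integer vector: \code{gt1}, \code{lt1}, \code{eq1},
#'   \code{total}.
#' @export
signature_strata <- function(signature) {
  stopifnot(inherits(signature, "combined_signature"))
  c(gt1 = sum(signature$combined_score > 1),
    lt1 = sum(signature$combined_score < 1),
    eq1 = sum(signature$combined_score == 1),
    total = nrow(signature))
}
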