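#' Per-condition detection fractions
#'
#' For every gene and stimulation condition, the fraction of that
#' condition's cells in which the gene is detected (count > 0).
#'
#' @param sc A \code{singlecell_matrix}.
#' @return Numeric matrix, genes x conditions, values in [0, 1].
#' @export
detection_fractions <- function(sc) {
  stopifnot(inherits(sc, "singlecell_matrix"))
  conditions <- if (is.factor(sc$condition_of)) levels(sc$condition_of)
                else sort(unique(as.character(sc$condition_of)))
  out <- matrix(NA_real_, nrow = nrow(sc$counts), ncol = length(conditions),
                dimnames = list(rownames(sc$counts), conditions))
  for (cond in conditions) {
    cells <- names(sc$condition_of)[sc$condition_of == cond]
    if (length(cells) == 0L)
      stop("condition '", cond, "' has zero cells")
    out[, cond] <- Matrix::rowSums(sc$counts[, cells, drop = FALSE] > 0) /
      length(cells)
  }
  out
}

#' Classify genes by expression pattern across stimulated T-cell populations
#'
#' A gene counts as expressed in a condition when its detection fraction
#' reaches \code{theta}. Categories follow the activation semantics:
#' \describe{
#'   \item{not_expressed}{below threshold in every condition (genes
#'     expressed only in negative or nonreactive populations are also
#'     mapped here and flagged in the \code{off_target} attribute).}
#'   \item{general_activation}{expressed in both the CMV-stimulated and the
#'     tumor-antigen-stimulated positive populations — a general T-cell
#'     activation marker.}
#'   \item{prame_specific}{expressed in the tumor-antigen-positive but not
#'     the CMV-positive population.}
#'   \item{cmv_specific}{the reverse — retained as a legal category so
#'     partitions on other data are not silently distorted.}
#' }
#'
#' @param fractions Gene x condition detection-fraction matrix from
#'   [detection_fractions()]; must contain columns \code{cmv_pos} and
#'   \code{prame_pos}.
#' @param theta Detection-fraction threshold in (0, 1), default 0.1.
#' @return A \code{category_assignment} data frame (gene, category) with
#'   the fraction matrix as attribute \code{fractions} and the flagged
#'   genes as attribute \code{off_target}.
#' @export
classify_genes <- function(fractions, theta = 0.1) {
  if (theta <= 0 || theta >= 1) stop("theta must lie strictly in (0, 1)")
  need <- c("cmv_pos", "prame_pos")
  miss <- setdiff(need, colnames(fractions))
  if (length(miss))
    stop("fractions lack required condition(s): ", paste(miss, collapse = ", "))
  expressed <- fractions >= theta
  cmv <- expressed[, "cmv_pos"]
  prame <- expressed[, "prame_pos"]
  category <- ifelse(cmv & prame, "general_activation",
                     ifelse(prame, "prame_specific",
                            ifelse(cmv, "cmv_specific", "not_expressed")))
  off_cols <- setdiff(colnames(fractions), need)
  off_target <- rownames(fractions)[category == "not_expressed" &
                                      rowSums(expressed[, off_cols, drop = FALSE]) > 0]
  out <- data.frame(gene = rownames(fractions),
                    category = unname(category),
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- fractions
  attr(out, "off_target") <- off_target
  attr(out, "theta") <- theta
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' Overlap of a signature with single-cell expression categories
#'
#' Partitions the signature genes by their expression category and reports
#' the per-category counts, the number expressed in activated T cells
#' (signature size minus the not-expressed count) and its percentage of the
#' signature, rounded to the nearest integer. Signature genes missing from
#' the assignment are counted as not_expressed with a warning.
#'
#' @param signature A \code{combined_signature} (or character vector of
#'   gene symbols).
#' @param assignment A \code{category_assignment} from [classify_genes()].
#' @return List with \code{counts} (named integer vector over the four
#'   categories), \code{n_signature}, \code{total_expressed} and
#'   \code{percent_expressed}.
#' @export
overlap_summary <- function(signature, assignment) {
  genes <- if (inherits(signature, "combined_signature")) signature$gene
           else as.character(signature)
  genes <- unique(toupper(genes))
  if (length(genes) == 0L) stop("signature is empty")
  stopifnot(inherits(assignment, "category_assignment"))
  cat_of <- stats::setNames(assignment$category, toupper(assignment$gene))
  miss <- setdiff(genes, names(cat_of))
  if (length(miss)) {
    warning(length(miss), " signature gene(s) missing from the assignment; ",
            "counted as not_expressed")
    cat_of[miss] <- "not_expressed"
  }
  levels <- c("prame_specific", "general_activation", "cmv_specific",
              "not_expressed")
  counts <- table(factor(cat_of[genes], levels = levels))
  counts <- stats::setNames(as.integer(counts), levels)
  total_expressed <- length(genes) - counts[["not_expressed"]]
  list(counts = counts,
       n_signature = length(genes),
       total_expressed = total_expressed,
       percent_expressed = round(100 * total_expressed / length(genes)))
}
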