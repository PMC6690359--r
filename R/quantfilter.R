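#' Select upregulated proteins by the heavy/light ratio rule
#'
#' Keeps the proteins whose heavy/light abundance ratio is strictly greater
#' than \code{threshold} (a ratio exactly at the threshold fails: upregulated
#' means more abundant in the heavy-labeled pool, and the comparison group is
#' defined by "1.2 or less"). With \code{mode = "any_db"} a gene passes if at
#' least one search database's record passes, and the databases in which it
#' passed are recorded; \code{mode = "primary_db"} considers only
#' swissprot-tagged records.
#'
#' @param table A \code{ratio_table} (or a list of them for the same
#'   experiment, one per search database).
#' @param threshold Positive ratio threshold (default 1.2).
#' @param mode \code{"any_db"} (default) or \code{"primary_db"}.
#' @return A \code{candidate_set}: list with \code{experiment_id},
#'   \code{genes} (ordered by descending selection ratio, ties
#'   alphabetical), \code{ratio_of} (named numeric, the maximum passing
#'   ratio per gene) and \code{provenance} (named list of search_db tags).
#' @export
filter_by_ratio <- function(table, threshold = 1.2,
                            mode = c("any_db", "primary_db")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  tables <- if (inherits(table, "ratio_table")) list(table) else table
  stopifnot(all(vapply(tables, inherits, logical(1), "ratio_table")))
  ids <- unique(vapply(tables, `[[`, character(1), "experiment_id"))
  if (length(ids) != 1L)
    stop("all ratio tables must come from the same experiment")
  rec <- do.call(rbind, lapply(tables, `[[`, "records"))
  if (mode == "primary_db")
    rec <- rec[rec$search_db == "swissprot", , drop = FALSE]
  rec <- rec[rec$ratio > threshold, , drop = FALSE]

  if (nrow(rec) == 0L) {
    return(structure(list(experiment_id = ids, genes = character(0),
                          ratio_of = stats::setNames(numeric(0), character(0)),
                          provenance = stats::setNames(list(), character(0))),
                     class = "candidate_set"))
  }
  ratio_of <- tapply(rec$ratio, rec$gene_symbol, max)
  provenance <- lapply(split(rec$search_db, rec$gene_symbol),
                       function(x) sort(unique(x)))
  genes <- names(ratio_of)[order(-ratio_of, names(ratio_of))]
  structure(list(experiment_id = ids,
                 genes = genes,
                 ratio_of = stats::setNames(as.numeric(ratio_of[genes]), genes),
                 provenance = provenance[genes]),
            class = "candidate_set")
}

#' Remove candidates belonging to exclusion gene sets
#'
#' Drops every candidate found in the union of the exclusion sets (e.g.
#' proteins identified as GVHD-specific in prior contrasts, or common
#' plasma proteins). The per-set removal counts are attached as the
#' \code{removal_report} attribute. An empty exclusion list is the
#' identity.
#'
#' @param candidates A \code{candidate_set}.
#' @param exclusions List of \code{gene_set} objects.
#' @return The filtered \code{candidate_set}, order preserved.
#' @export
exclude_genesets <- function(candidates, exclusions = list()) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (length(exclusions) == 0L) return(candidates)
  stopifnot(all(vapply(exclusions, inherits, logical(1), "gene_set")))
  report <- vapply(exclusions, function(s)
    sum(candidates$genes %in% s$members), integer(1))
  names(report) <- vapply(exclusions, `[[`, character(1), "name")
  excluded <- unique(unlist(lapply(exclusions, `[[`, "members")))
  keep <- !(candidates$genes %in% excluded)
  out <- structure(list(experiment_id = candidates$experiment_id,
                        genes = candidates$genes[keep],
                        ratio_of = candidates$ratio_of[candidates$genes[keep]],
                        provenance = candidates$provenance[candidates$genes[keep]]),
                   class = "candidate_set")
  attr(out, "removal_report") <- report
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set '", x$experiment_id, "': ", length(x$genes),
      " genes\n", sep = "")
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 6L)
    cat("  top: ", paste(sprintf("%s (%.2f)", shown, x$ratio_of[shown]),
                         collapse = ", "),
        if (length(x$genes) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.candidate_set <- function(x) length(x$genes)
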