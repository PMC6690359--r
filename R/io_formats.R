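#' Read a protein quantification ratio table
#'
#' Parses a tab-separated protein quantification table (accession, gene
#' symbol, heavy/light abundance ratio, optional peptide count) into a
#' \code{ratio_table}. Rows with a non-positive or unparsable ratio are
#' dropped and counted in the attached load report; duplicate gene symbols
#' within one search database are resolved in favour of the record with the
#' larger peptide count (ties: larger ratio). Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a TSV file (plain or gzip).
#' @param experiment_id Identifier of the labeling experiment the table
#'   belongs to (e.g. \code{"IPAS-01"}).
#' @param search_db Tag of the protein database the identifications came
#'   from: \code{"swissprot"}, \code{"uniprot"} or \code{"other"}.
#' @param columns Named character vector mapping the canonical column roles
#'   \code{accession}, \code{gene_symbol}, \code{ratio} and (optionally)
#'   \code{peptide_count} to the header names used in the file.
#' @param accession_map Optional 2-column data frame (accession, gene symbol)
#'   used to fill in gene symbols for rows whose symbol column is empty;
#'   rows that remain unmapped are dropped and counted.
#'
#' @return A \code{ratio_table}: list with \code{experiment_id} and
#'   \code{records} (data frame with columns \code{accession},
#'   \code{gene_symbol}, \code{ratio}, \code{peptide_count},
#'   \code{search_db}), with a \code{load_report} attribute counting dropped
#'   rows by reason.
#' @export
read_ratio_table <- function(path, experiment_id, search_db = "swissprot",
                             columns = c(accession = "accession",
                                         gene_symbol = "gene_symbol",
                                         ratio = "ratio",
                                         peptide_count = "peptide_count"),
                             accession_map = NULL) {
  if (!file.exists(path)) stop("ratio table not found: ", path)
  search_db <- match.arg(search_db, c("swissprot", "uniprot", "other"))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  for (role in c("accession", "gene_symbol", "ratio")) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop("ratio table is missing mandatory column '",
           if (is.null(col)) role else col, "'")
  }
  n_in <- nrow(raw)
  rec <- data.frame(
    accession = raw[[columns[["accession"]]]],
    gene_symbol = toupper(trimws(raw[[columns[["gene_symbol"]]]])),
    ratio = suppressWarnings(as.numeric(raw[[columns[["ratio"]]]])),
    stringsAsFactors = FALSE)
  pc_col <- columns[["peptide_count"]]
  rec$peptide_count <- if (!is.na(pc_col) && !is.null(pc_col) && pc_col %in% names(raw)) {
    pc <- suppressWarnings(as.integer(raw[[pc_col]]))
    ifelse(is.na(pc), 0L, pc)
  } else 0L

  n_unmapped <- 0L
  if (!is.null(accession_map)) {
    map <- stats::setNames(toupper(accession_map[[2]]), accession_map[[1]])
    blank <- !nzchar(rec$gene_symbol)
    rec$gene_symbol[blank] <- unname(map[rec$accession[blank]])
    rec$gene_symbol[is.na(rec$gene_symbol)] <- ""
  }
  bad_sym <- !nzchar(rec$gene_symbol)
  n_unmapped <- sum(bad_sym)
  bad_ratio <- is.na(rec$ratio) | rec$ratio <= 0
  n_bad_ratio <- sum(bad_ratio & !bad_sym)
  rec <- rec[!bad_sym & !bad_ratio, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("ratio table '", path, "' contains no usable rows after parsing")

  # dedup: keep the best-supported record per gene (peptides, then ratio)
  ord <- order(rec$gene_symbol, -rec$peptide_count, -rec$ratio)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[!duplicated(rec$gene_symbol), , drop = FALSE]
  rec$search_db <- search_db
  rownames(rec) <- NULL

  out <- structure(list(experiment_id = experiment_id, records = rec),
                   class = "ratio_table")
  attr(out, "load_report") <- list(rows_read = n_in,
                                   dropped_bad_ratio = n_bad_ratio,
                                   dropped_unmapped = n_unmapped,
                                   kept = nrow(rec))
  out
}

#' Write a ratio table to TSV
#'
#' Inverse of [read_ratio_table()]; the written file round-trips.
#'
#' @param table A \code{ratio_table}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ratio_table <- function(table, path) {
  stopifnot(inherits(table, "ratio_table"))
  utils::write.table(table$records[, c("accession", "gene_symbol", "ratio",
                                       "peptide_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a ratio table from a records data frame
#'
#' @param experiment_id Experiment identifier.
#' @param records Data frame with columns \code{accession},
#'   \code{gene_symbol}, \code{ratio}, \code{peptide_count},
#'   \code{search_db}.
#' @return A \code{ratio_table}.
#' @export
ratio_table <- function(experiment_id, records) {
  stopifnot(all(c("accession", "gene_symbol", "ratio", "peptide_count",
                  "search_db") %in% names(records)),
            all(records$ratio > 0),
            !anyDuplicated(records[, c("gene_symbol", "search_db")]))
  structure(list(experiment_id = experiment_id,
                 records = as.data.frame(records)),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("ratio_table '", x$experiment_id, "': ", nrow(x$records),
      " proteins (", paste(unique(x$records$search_db), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated (Broad GMT dialect). Member symbols are uppercased and
#' deduplicated within a line; set order is preserved.
#'
#' @param path Path to a GMT file (plain or gzip).
#' @return A list of \code{gene_set} objects (name, description, members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    out[[i]] <- gene_set(fields[[1]], fields[[2]], members)
  }
  out
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param description Free-text description.
#' @param members Character vector of gene symbols (uppercased, deduplicated).
#' @return A \code{gene_set}.
#' @export
gene_set <- function(name, description = "", members) {
  members <- unique(toupper(members))
  stopifnot(length(members) > 0L)
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' Write gene sets to a GMT file
#'
#' @param sets List of \code{gene_set} objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style protein-protein interaction edge table
#'
#' Reads a TSV of gene pairs with confidence scores into an undirected
#' \code{ppi_network}. The \code{string_1000} dialect divides scores by 1000
#' (STRING file exports use 0-1000 integer scores); \code{unit} stores them
#' as-is. Self-loops are silently dropped; duplicate unordered pairs are
#' collapsed keeping the maximum confidence. The dialect is explicit
#' configuration, never guessed from score magnitude.
#'
#' @param path TSV path (plain or gzip) with columns gene_a, gene_b, score
#'   (header names configurable via `columns`).
#' @param score_dialect \code{"unit"} (scores already in [0,1]) or
#'   \code{"string_1000"} (0-1000, divided by 1000 on load).
#' @param columns Named vector mapping roles \code{gene_a}, \code{gene_b},
#'   \code{score} to header names.
#' @return A \code{ppi_network}: list with \code{nodes} (character) and
#'   \code{edges} (data frame gene_a, gene_b, confidence; gene_a < gene_b).
#' @export
read_ppi_edges <- function(path, score_dialect = c("unit", "string_1000"),
                           columns = c(gene_a = "gene_a", gene_b = "gene_b",
                                       score = "score")) {
  if (!file.exists(path)) stop("PPI edge table not found: ", path)
  score_dialect <- match.arg(score_dialect)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  for (role in c("gene_a", "gene_b", "score")) {
    if (!columns[[role]] %in% names(raw))
      stop("PPI table is missing mandatory column '", columns[[role]], "'")
  }
  conf <- suppressWarnings(as.numeric(raw[[columns[["score"]]]]))
  if (score_dialect == "string_1000") conf <- conf / 1000
  if (any(is.na(conf) | conf < 0 | conf > 1))
    stop("PPI confidence outside [0, 1] after '", score_dialect,
         "' normalization")
  ppi_network(data.frame(gene_a = toupper(as.character(raw[[columns[["gene_a"]]]])),
                         gene_b = toupper(as.character(raw[[columns[["gene_b"]]]])),
                         confidence = conf, stringsAsFactors = FALSE))
}

#' Construct an undirected confidence-weighted PPI network
#'
#' Canonicalizes edges (endpoints sorted within each pair), drops self-loops,
#' collapses duplicate unordered pairs keeping the maximum confidence.
#'
#' @param edges Data frame with columns gene_a, gene_b, confidence.
#' @param nodes Optional character vector of nodes; defaults to (and is
#'   always extended by) the union of edge endpoints.
#' @return A \code{ppi_network}.
#' @export
ppi_network <- function(edges, nodes = character(0)) {
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)),
            all(edges$confidence >= 0 & edges$confidence <= 1))
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  if (nrow(edges) > 0L) {
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    edges <- edges[order(key, -edges$confidence), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")),
                   , drop = FALSE]
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  }
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes,
                 edges = edges[, c("gene_a", "gene_b", "confidence")]),
            class = "ppi_network")
}

#' Write a PPI network as a STRING-style edge TSV
#'
#' @param network A \code{ppi_network}.
#' @param path Output path.
#' @param score_dialect \code{"unit"} writes confidences as-is;
#'   \code{"string_1000"} multiplies by 1000 and rounds.
#' @return Invisibly, `path`.
#' @export
write_ppi_edges <- function(network, path,
                            score_dialect = c("unit", "string_1000")) {
  stopifnot(inherits(network, "ppi_network"))
  score_dialect <- match.arg(score_dialect)
  out <- data.frame(gene_a = network$edges$gene_a,
                    gene_b = network$edges$gene_b,
                    score = if (score_dialect == "string_1000")
                      round(network$edges$confidence * 1000)
                    else network$edges$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Write a combined signature report to TSV
#'
#' Serializes a \code{combined_signature} (gene, per-experiment final
#' scores, combined score, provenance) sorted by descending combined score,
#' ties broken alphabetically. Round-trips through [read_signature()].
#'
#' @param signature A \code{combined_signature} (see
#'   [combine_experiments()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "combined_signature"),
            nrow(signature) > 0L)
  df <- as.data.frame(signature)
  df <- df[order(-df$combined_score, df$gene), , drop = FALSE]
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a combined signature report written by [write_signature()]
#'
#' @param path TSV path.
#' @return A \code{combined_signature} data frame.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  needed <- c("gene", "combined_score", "provenance", "final_training",
              "final_validation")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("signature file is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("combined_score", "final_training", "final_validation"))
    df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("combined_signature", "data.frame")
  df
}

#' Read a sparse single-cell count matrix (MatrixMarket trio)
#'
#' Reads a 10x-style trio: an MTX triplet file of counts (genes x cells),
#' a one-column gene label file, and a cell label TSV that also carries each
#' cell's stimulation condition.
#'
#' @param mtx_path MatrixMarket triplet file of non-negative counts.
#' @param genes_path Text file, one gene symbol per line.
#' @param cells_path TSV with columns \code{cell} and \code{condition}
#'   (condition in cmv_pos, cmv_neg, prame_pos, prame_neg, nonreactive).
#' @return A \code{singlecell_matrix}: list with \code{counts} (sparse
#'   Matrix, genes x cells) and \code{condition_of} (named character).
#' @export
read_singlecell <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) stop("single-cell input not found: ", p)
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- toupper(readLines(genes_path))
  cells <- utils::read.delim(cells_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("cell", "condition") %in% names(cells)))
    stop("cell label file must have columns 'cell' and 'condition'")
  if (nrow(counts) != length(genes))
    stop("gene label count does not match matrix rows")
  if (ncol(counts) != nrow(cells))
    stop("cell label count does not match matrix columns")
  dimnames(counts) <- list(genes, cells$cell)
  singlecell_matrix(counts, stats::setNames(cells$condition, cells$cell))
}

#' Construct a single-cell count matrix container
#'
#' @param counts Sparse or dense non-negative integer matrix, genes x cells,
#'   with dimnames.
#' @param condition_of Named character vector mapping each cell to one
#'   condition tag.
#' @return A \code{singlecell_matrix}.
#' @export
singlecell_matrix <- function(counts, condition_of) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(colnames(counts) %in% names(condition_of)))
  condition_of <- condition_of[colnames(counts)]
  ok <- c("cmv_pos", "cmv_neg", "prame_pos", "prame_neg", "nonreactive")
  if (!all(condition_of %in% ok))
    stop("unknown cell condition(s): ",
         paste(setdiff(unique(condition_of), ok), collapse = ", "))
  structure(list(counts = counts, condition_of = condition_of),
            class = "singlecell_matrix")
}

#' Write a single-cell matrix as an MTX trio
#'
#' @param sc A \code{singlecell_matrix}.
#' @param mtx_path,genes_path,cells_path Output paths for the triplet
#'   matrix, gene labels and cell/condition labels.
#' @return Invisibly, `mtx_path`.
#' @export
write_singlecell <- function(sc, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(sc, "singlecell_matrix"))
  Matrix::writeMM(sc$counts, mtx_path)
  writeLines(rownames(sc$counts), genes_path)
  utils::write.table(data.frame(cell = colnames(sc$counts),
                                condition = unname(sc$condition_of)),
                     cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx_path)
}
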