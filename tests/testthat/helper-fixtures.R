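# In-code fixtures shared across test files.

make_records <- function(genes, ratios, peptides = NULL, db = "swissprot",
                         accession = NULL) {
  data.frame(accession = accession %||% paste0("ACC", seq_along(genes)),
             gene_symbol = genes,
             ratio = ratios,
             peptide_count = peptides %||% rep(1L, length(genes)),
             search_db = db,
             stringsAsFactors = FALSE)
}

make_table <- function(genes, ratios, id = "EXP", ...) {
  ratio_table(id, make_records(genes, ratios, ...))
}

# candidate_set through the public path: a threshold below every ratio
make_candidates <- function(genes, ratios, id = "EXP") {
  filter_by_ratio(make_table(genes, ratios, id), threshold = min(ratios) / 2)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_network <- function(n_nodes, edge_prob = 0.15) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  take <- stats::runif(nrow(pairs)) < edge_prob
  ppi_network(data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                         confidence = stats::runif(sum(take)),
                         stringsAsFactors = FALSE),
              nodes = nodes)
}

# detection-fraction matrix with prescribed per-category row patterns
make_fraction_matrix <- function(n_prame, n_general, n_not, n_cmv = 0,
                                 on = 0.6, off = 0.0) {
  conds <- c("cmv_pos", "cmv_neg", "prame_pos", "prame_neg", "nonreactive")
  n <- n_prame + n_general + n_not + n_cmv
  m <- matrix(off, nrow = n, ncol = length(conds),
              dimnames = list(sprintf("G%03d", seq_len(n)), conds))
  rows <- split(seq_len(n), rep(c("prame", "general", "cmv", "not"),
                                c(n_prame, n_general, n_cmv, n_not)))
  m[rows$prame, "prame_pos"] <- on
  m[rows$general, c("cmv_pos", "prame_pos")] <- on
  if (n_cmv > 0) m[rows$cmv, "cmv_pos"] <- on
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
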