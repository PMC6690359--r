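test_that("connectivity weights normalize summed edge confidences", {
  # symmetric triangle: all three share the maximum
  tri <- ppi_network(data.frame(gene_a = c("A", "B", "A"),
                                gene_b = c("B", "C", "C"),
                                confidence = 0.8))
  w <- connectivity_weights(build_subnetwork(tri, c("A", "B", "C"), 0.5))
  expect_equal(unname(w[c("A", "B", "C")]), c(1, 1, 1))

  # all isolated: all zero
  iso <- build_subnetwork(tri, c("X", "Y"), 0.5)
  expect_equal(unname(connectivity_weights(iso)), c(0, 0))

  # 4-node weighted toy graph vs hand-summed sums
  toy <- ppi_network(data.frame(gene_a = c("A", "A", "B", "C"),
                                gene_b = c("B", "C", "C", "D"),
                                confidence = c(0.9, 0.8, 0.7, 0.6)))
  w4 <- connectivity_weights(build_subnetwork(toy, c("A", "B", "C", "D"), 0))
  raw <- c(A = 0.9 + 0.8, B = 0.9 + 0.7, C = 0.8 + 0.7 + 0.6, D = 0.6)
  expect_equal(w4[names(raw)], raw / max(raw))

  # outer genes contribute support but receive no weight
  sub <- build_subnetwork(toy, c("C", "D"), 0.5)
  ext <- extend_outer(toy, sub)
  wo <- connectivity_weights(ext)
  expect_setequal(names(wo), c("C", "D"))
  expect_equal(unname(wo["C"]), 1)  # C: 0.8+0.7+0.6 incl. outer edges
})

test_that("relevance formula boosts by connectivity and collapses at alpha 0", {
  cand <- make_candidates(c("A", "B"), c(1.5, 2.0))
  w <- c(A = 1, B = 0.25)
  rel <- relevance_scores(cand, w, alpha = 1)
  expect_equal(unname(rel["A"]), 3.0)              # 1.5 * (1 + 1)
  expect_equal(unname(rel["B"]), 2.0 * 1.25)
  expect_equal(relevance_scores(cand, w, alpha = 0),
               cand$ratio_of[names(rel)])          # identity limit
  # missing weight means no boost
  expect_equal(unname(relevance_scores(cand, c(A = 1), 1)["B"]), 2.0)
  expect_error(relevance_scores(cand, w, alpha = -1), "non-negative")
})

test_that("penalty factors count set hits and switch off at beta 0", {
  lib <- list(gene_set("D1", "", c("A", "B")), gene_set("D2", "", "B"))
  pf <- penalty_factors(c("A", "B", "C"), lib, beta = 0.5)
  expect_equal(pf$penalty_hits, c(1L, 2L, 0L))
  expect_equal(pf$penalty_factor, c(1 / 1.5, 0.5, 1))  # k=2 halves the score
  pf0 <- penalty_factors(c("A", "B", "C"), lib, beta = 0)
  expect_true(all(pf0$penalty_factor == 1))
  expect_error(penalty_factors("A", lib, beta = -0.1), "non-negative")
})

test_that("final scores chain the formulas, keep sub-1 genes, and sort deterministically", {
  cand <- make_candidates(c("A", "B", "C"), c(1.5, 1.3, 1.3))
  w <- c(A = 1)
  lib <- list(gene_set("D1", "", c("A", "B")), gene_set("D2", "", c("A", "B")))
  fs <- final_scores(cand, w, penalty_library = lib, alpha = 1, beta = 0.5)
  a <- fs[fs$gene == "A", ]
  expect_equal(a$relevance, 3.0)
  expect_equal(a$final_score, 1.5)                 # 3.0 * 1/(1+0.5*2)
  b <- fs[fs$gene == "B", ]
  expect_lt(b$final_score, 1)                      # sub-1 scores retained
  expect_true(all(c("A", "B", "C") %in% fs$gene))
  expect_equal(fs$score_nopenalty, fs$relevance)
  expect_equal(fs$final_score, sort(fs$final_score, decreasing = TRUE))
})

test_that("score bound chain and degenerate-parameter ranking hold on synthetic runs", {
  b <- generate_experiments(sim_config(seed = 6))
  cand <- exclude_genesets(filter_by_ratio(b$ratio_tables$training, 1.2),
                           b$exclusion_sets)
  sub <- build_subnetwork(b$network, cand, 0.7)
  w <- connectivity_weights(sub)
  for (alpha in c(0, 1, 2.5)) {
    fs <- final_scores(cand, w, penalty_library = b$penalty_library,
                       alpha = alpha, beta = 0.5)
    expect_true(all(fs$final_score <= fs$relevance + 1e-12))
    expect_true(all(fs$relevance <= fs$ratio * (1 + alpha) + 1e-12))
  }
  # alpha = beta = 0 degenerates to the pure fold-change ranking
  fs00 <- final_scores(cand, w, penalty_library = b$penalty_library,
                       alpha = 0, beta = 0)
  by_ratio <- cand$genes[order(-cand$ratio_of, cand$genes)]
  expect_equal(fs00$gene, by_ratio)

  # penalties reorder but never change membership
  fs_off <- final_scores(cand, w, penalty_library = b$penalty_library,
                         alpha = 1, beta = 0)
  fs_on <- final_scores(cand, w, penalty_library = b$penalty_library,
                        alpha = 1, beta = 0.5)
  expect_setequal(fs_off$gene, fs_on$gene)
  expect_false(identical(fs_off$gene, fs_on$gene))
})

test_that("network support ranks planted module genes above equal-ratio isolated genes", {
  b <- generate_experiments(sim_config(seed = 42))
  cand <- exclude_genesets(filter_by_ratio(b$ratio_tables$training, 1.2),
                           b$exclusion_sets)
  w <- connectivity_weights(build_subnetwork(b$network, cand, 0.7))
  rel <- relevance_scores(cand, w, alpha = 1)
  cls <- b$truth$class[match(cand$genes, b$truth$gene)]
  mean_boost <- function(k) mean(rel[cand$genes[cls == k]] /
                                   cand$ratio_of[cand$genes[cls == k]])
  expect_gt(mean_boost("signature"), mean_boost("background"))
})

test_that("combining experiments takes geometric means over the union with provenance", {
  a <- final_scores(make_candidates(c("X", "Y"), c(2.0, 1.4), "E1"),
                    numeric(0))
  b <- final_scores(make_candidates(c("X", "Z"), c(0.5, 1.1), "E2"),
                    numeric(0))
  sig <- combine_experiments(a, b)
  expect_equal(sig$combined_score[sig$gene == "X"], 1.0)   # sqrt(2 * 0.5)
  expect_equal(sig$provenance[sig$gene == "X"], "both")
  expect_equal(sig$combined_score[sig$gene == "Y"], 1.4)
  expect_equal(sig$provenance[sig$gene == "Y"], "training_only")
  expect_equal(sig$provenance[sig$gene == "Z"], "validation_only")
  strata <- signature_strata(sig)
  expect_equal(unname(strata["eq1"]), 1L)
  expect_equal(sum(strata[c("gt1", "lt1", "eq1")]), unname(strata["total"]))

  arith <- combine_experiments(a, b, method = "arithmetic")
  expect_equal(arith$combined_score[arith$gene == "X"], 1.25)
  expect_error(combine_experiments(a, a), "same experiment")
})

test_that("union of overlapping experiments reproduces inclusion-exclusion counts", {
  shared <- sprintf("S%02d", 1:15)
  only_a <- sprintf("A%02d", 1:31)
  only_b <- sprintf("B%02d", 1:15)
  a <- final_scores(make_candidates(c(shared, only_a),
                                    runif(46, 1.3, 3), "E1"), numeric(0))
  b <- final_scores(make_candidates(c(shared, only_b),
                                    runif(30, 1.3, 3), "E2"), numeric(0))
  sig <- combine_experiments(a, b)
  expect_equal(nrow(sig), 61L)   # 46 + 30 - 15
  expect_equal(sum(sig$provenance == "both"), 15L)
})
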