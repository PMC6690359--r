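test_that("generation is deterministic and honours dropout", {
  cfg <- sim_config(seed = 42)
  b1 <- generate_experiments(cfg)
  b2 <- generate_experiments(cfg)
  expect_identical(b1, b2)

  cfg0 <- sim_config(dropout_prob = 0, seed = 5)
  b0 <- generate_experiments(cfg0)
  n_tot <- nrow(b0$truth)
  expect_equal(nrow(b0$ratio_tables$training$records), n_tot)
  expect_equal(nrow(b0$ratio_tables$validation$records), n_tot)
})

test_that("truth classes partition the gene universe", {
  b <- generate_experiments(sim_config(seed = 42))
  cfg <- b$config
  expect_false(anyDuplicated(b$truth$gene) > 0)
  cls <- table(b$truth$class)
  expect_equal(as.integer(cls[c("signature", "gvhd", "background",
                                "contaminant")]),
               c(cfg$n_signature, cfg$n_gvhd, cfg$n_background,
                 cfg$n_contaminant))
  expect_setequal(b$truth$gene, b$network$nodes)
})

test_that("planted classes obey the ratio model", {
  b <- generate_experiments(sim_config(dropout_prob = 0, seed = 9))
  for (tab in b$ratio_tables) {
    rec <- tab$records
    cls <- b$truth$class[match(rec$gene_symbol, b$truth$gene)]
    # truncation: every signature ratio exceeds the selection threshold
    expect_true(all(rec$ratio[cls == "signature"] > 1.2))
    # background tail within 3 standard errors of the log-normal tail prob
    p_tail <- 1 - plnorm(1.2, 0, b$config$background_ratio_logsd)
    bg <- rec$ratio[cls == "background"]
    se <- sqrt(p_tail * (1 - p_tail) / length(bg))
    expect_lt(abs(mean(bg > 1.2) - p_tail), 3 * se)
  }
  # filter survivors match a direct scan of the emitted table
  cand <- filter_by_ratio(b$ratio_tables$training, 1.2)
  rec <- b$ratio_tables$training$records
  expect_setequal(cand$genes, rec$gene_symbol[rec$ratio > 1.2])
})

test_that("gvhd genes are always covered by an exclusion set; penalty sets avoid signature genes", {
  for (s in c(1, 42)) {
    b <- generate_experiments(sim_config(seed = s))
    excluded <- unique(unlist(lapply(b$exclusion_sets, `[[`, "members")))
    gvhd <- b$truth$gene[b$truth$class == "gvhd"]
    expect_true(all(gvhd %in% excluded))
    sig <- b$truth$gene[b$truth$class == "signature"]
    pen <- unique(unlist(lapply(b$penalty_library, `[[`, "members")))
    expect_length(intersect(sig, pen), 0L)
  }
  # robustness switch: contaminated penalty sets may hit signature genes
  bc <- generate_experiments(sim_config(seed = 1, contaminated_penalty = TRUE))
  sig <- bc$truth$gene[bc$truth$class == "signature"]
  pen <- unique(unlist(lapply(bc$penalty_library, `[[`, "members")))
  expect_gt(length(intersect(sig, pen)), 0L)
})

test_that("planted module edges are high-confidence signature-signature pairs", {
  cfg <- sim_config(seed = 3)
  b <- generate_experiments(cfg)
  sig <- b$truth$gene[b$truth$class == "signature"]
  e <- b$network$edges
  intra <- e$gene_a %in% sig & e$gene_b %in% sig
  expect_gte(sum(intra & e$confidence >= 0.7), 100)  # most of the 120 planted
  expect_true(all(e$confidence >= 0.15 & e$confidence <= 0.99))
})

test_that("bundle writes in the formats the readers consume", {
  b <- generate_experiments(sim_config(seed = 2))
  dir <- tempfile()
  paths <- write_bundle(b, dir)
  tab <- read_ratio_table(paths$training, "IPAS-01")
  expect_equal(tab$records[order(tab$records$gene_symbol), ],
               b$ratio_tables$training$records[
                 order(b$ratio_tables$training$records$gene_symbol), ],
               ignore_attr = TRUE)
  expect_equal(read_gmt(paths$penalty), b$penalty_library)
  expect_equal(read_ppi_edges(paths$ppi, "unit")$edges, b$network$edges)
})

test_that("single-cell simulation is deterministic and matches its expression model", {
  cfg <- sim_config(seed = 7)
  genes <- sprintf("SIG%02d", 1:40)
  r1 <- generate_singlecell(cfg, genes)
  r2 <- generate_singlecell(cfg, genes)
  expect_identical(r1, r2)
  expect_true(all(r1$truth$category %in%
                    c("prame_specific", "general_activation",
                      "cmv_specific", "not_expressed")))

  fr <- detection_fractions(r1$matrix)
  # silent genes: detection probability ~0.02; allow 6 binomial SEs over
  # 200 cells so the bound is sound across all gene-condition pairs
  p_off <- 1 - (cfg$sc_nb_size / (cfg$sc_nb_size + cfg$sc_mu_off))^cfg$sc_nb_size
  off_bound <- p_off + 6 * sqrt(p_off * (1 - p_off) / cfg$sc_cells_per_condition)
  for (i in seq_along(genes)) {
    cat_i <- r1$truth$category[i]
    if (cat_i == "not_expressed")
      expect_true(all(fr[i, ] < off_bound))
    if (cat_i == "general_activation")
      expect_true(all(fr[i, c("cmv_pos", "prame_pos")] >= 0.5))
    if (cat_i == "prame_specific") {
      expect_gte(fr[i, "prame_pos"], 0.5)
      expect_lt(fr[i, "cmv_pos"], off_bound)
    }
  }
  expect_error(generate_singlecell(cfg, character(0)), "non-empty")
  expect_error(generate_singlecell(cfg, genes, conditions = "cmv_pos"),
               "at least 2")
})
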