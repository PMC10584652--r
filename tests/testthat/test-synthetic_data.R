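test_that("bundles are byte-identical for the same seed", {
  cfg <- small_config(9)
  d1 <- tempfile("b1")
  d2 <- tempfile("b2")
  p1 <- write_bundle(generate_bundle(cfg), d1)
  p2 <- write_bundle(generate_bundle(cfg), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  # and a different seed gives a different bundle
  p3 <- write_bundle(generate_bundle(small_config(10)), tempfile("b3"))
  expect_false(identical(readLines(p1[["associations"]]),
                         readLines(p3[["associations"]])))
})

test_that("the planted manifest is internally consistent with the files", {
  cfg <- small_config(13, n_risk_genes = 5L)
  b <- generate_bundle(cfg)
  m <- b$manifest
  expect_equal(m$n_significant, sum(!duplicated(b$associations$rsid) &
                                      b$associations$p_value <
                                        cfg$p_threshold))
  fm <- as.matrix(m$flag_matrix[, flag_columns()])
  totals <- rowSums(fm)
  risk <- m$flag_matrix$gencode_id[totals >= cfg$risk_threshold]
  expect_equal(sort(risk), m$risk_genes)
  expect_length(m$risk_genes, 5L)
  expect_true(all(totals[!m$flag_matrix$gencode_id %in% risk] <
                    cfg$risk_threshold))
  expect_setequal(m$drugs$status,
                  c("approved_for_disease", "in_trial", "novel"))
})

test_that("an in-memory pipeline replay recovers the planted truth", {
  cfg <- small_config(17)
  b <- generate_bundle(cfg)
  leads <- deduplicate_snps(filter_associations(b$associations,
                                                cfg$p_threshold))
  proxies <- expand_ld(leads$rsid, b$ld_proxies, cfg$r2_threshold,
                       cfg$population)
  genes <- collect_genes(proxies)
  flags <- annotate_genes(genes, proxies, b$eqtl, b$go_membership,
                          b$pid_list, cfg$alpha, cfg$background_n)
  expect_equal(flags, b$manifest$flag_matrix, ignore_attr = TRUE)
  risk <- call_risk_genes(score_genes(flags, cfg$risk_threshold),
                          cfg$risk_threshold)
  expect_equal(sort(risk$gencode_id), b$manifest$risk_genes)
  exp <- expand_ppi(risk$gene_symbol, b$ppi_edges, cfg$ppi_min_score,
                    b$symbol_map)
  expect_equal(exp$genes, b$manifest$expanded_genes)
  expect_equal(nrow(exp$pairs), b$manifest$n_pairs)
  cand <- classify_drug_status(map_drugs(exp$genes, b$drug_targets),
                               b$approvals, b$trials, cfg$condition)
  expect_equal(cand$drug_name, b$manifest$drugs$drug_name)
  expect_equal(cand$status, b$manifest$drugs$status)
  expect_equal(cand$targets, b$manifest$drugs$targets)
})

test_that("a zero-significance config yields empty downstream results", {
  cfg <- small_config(19, fraction_significant = 0, n_risk_genes = 0L)
  b <- generate_bundle(cfg)
  expect_equal(b$manifest$n_significant, 0)
  expect_equal(nrow(b$manifest$flag_matrix), 0L)
  expect_length(b$manifest$expanded_genes, 0L)
  expect_equal(nrow(b$manifest$drugs), 0L)
  leads <- filter_associations(b$associations, cfg$p_threshold)
  expect_equal(nrow(leads), 0L)
})

test_that("infeasible configurations fail loudly", {
  expect_error(generator_config(n_genes = 5, n_risk_genes = 10),
               "infeasible")
  expect_error(generator_config(r2_threshold = 0.9, r2_high = c(0.85, 1)),
               "infeasible")
  # more risk genes than significant loci can cover
  expect_error(generate_bundle(small_config(1, n_snps = 6L,
                                            fraction_significant = 0.5,
                                            n_risk_genes = 4L)),
               "infeasible")
})

test_that("the published scoring-matrix fixture matches the printed table", {
  fx <- table1_fixture()
  expect_equal(dim(fx), c(14L, 8L))
  expect_equal(unlist(fx[fx$gene_symbol == "RFWD3", flag_columns()],
                      use.names = FALSE), c(1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(unlist(fx[fx$gene_symbol == "CBX7", flag_columns()],
                      use.names = FALSE), c(0L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(fx$gencode_id[fx$gene_symbol == "TNFRSF13B"],
               "ENSG00000240505")
})

test_that("the published drug-evidence fixture carries the printed records", {
  fx <- paper_drug_fixture()
  expect_equal(nrow(fx$trials), 4L)
  expect_setequal(fx$trials$nct_id,
                  c("NCT04813653", "NCT00131261", "NCT01502085",
                    "NCT00765102"))
  expect_equal(nrow(fx$approvals), 1L)
  expect_equal(fx$approvals$drug_name, "panobinostat")
  expect_equal(nrow(fx$drug_targets), 9L)
  expect_setequal(fx$drug_targets$target_gene, c("CAMLG", "HDAC2"))
})
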