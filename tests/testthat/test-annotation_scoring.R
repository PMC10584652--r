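test_that("hypergeometric tail handles boundary cases and the worked example", {
  expect_equal(hypergeometric_tail(0, 5, 3, 10), 1)      # whole support
  expect_equal(hypergeometric_tail(4, 4, 3, 10), 0)      # beyond min(K, n)
  # frozen from full-support enumeration: sum over i >= 2 of
  # C(4,i) C(6,3-i) / C(10,3) = (36 + 4) / 120
  expect_equal(hypergeometric_tail(2, 4, 3, 10), 1 / 3, tolerance = 1e-14)
  expect_error(hypergeometric_tail(1, 11, 3, 10), "invalid")
  expect_error(hypergeometric_tail(-1, 2, 3, 10), "invalid")
})

test_that("hypergeometric tail matches phyper and is non-increasing in k", {
  withr::with_seed(41, {
    for (rep in 1:50) {
      N <- sample(5:500, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      ks <- 0:min(K, n)
      ours <- hypergeometric_tail(ks, K, n, N)
      ref <- stats::phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(ours, ref, tolerance = 1e-12)
      expect_true(all(diff(ours) <= 1e-15))
    }
  })
})

test_that("annotation flags implement the six criteria", {
  genes <- gene_df(c("ENSG1", "ENSG2"), c("RFWD3", "CDCA7L"))
  proxies <- ld_df(c("rs1", "rs1", "rs2"), c("rs1", "rs11", "rs2"),
                   c(1, 0.9, 1),
                   gid = c("ENSG1", "ENSG1", "ENSG2"),
                   sym = c("RFWD3", "RFWD3", "CDCA7L"),
                   csq = c("missense", "intronic", "intronic"))
  expect_equal(flag_missense(genes, proxies), c(1L, 0L))

  eqtl <- data.frame(rsid = c("rs11", "rs2"),
                     gencode_id = c("ENSG1", "ENSG2"),
                     tissue = c("whole blood", "liver"),
                     significant = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(flag_cis_eqtl(genes, proxies, eqtl), c(1L, 0L))

  membership <- data.frame(
    category = c("BP", "BP", "MF"),
    term_id = c("GO:BP1", "GO:BP2", "GO:MF1"),
    gencode_id = c("ENSG1", "ENSG2", "ENSG2"),
    term_size = c(2L, 8000L, 9000L), stringsAsFactors = FALSE)
  enr <- enrich_terms(genes$gencode_id, membership)
  expect_equal(flag_go_category(genes, enr, membership, "BP"), c(1L, 0L))
  expect_equal(flag_go_category(genes, enr, membership, "MF"), c(0L, 0L))

  expect_equal(flag_pid(genes, c("tnfrsf13b", "rfwd3")), c(1L, 0L))
  expect_equal(flag_pid(genes, "ENSG2"), c(0L, 1L))
})

test_that("scoring reproduces the published matrix, totals and ordering", {
  scores <- score_genes(table1_fixture())
  expect_equal(nrow(scores), 14L)
  expect_equal(scores$total,
               c(5L, 3L, 3L, 3L, rep(2L, 10)))
  expect_equal(scores$gene_symbol[1:4],
               c("RFWD3", "HMGXB4", "CDCA7L", "CCHCR1"))
  expect_equal(scores$gene_symbol[5:14],
               c("NCAPH2", "SRCAP", "CBX7", "DTNB", "PRR14", "ULK4",
                 "TRAK1", "HLA-C", "POU5F1", "TNFRSF13B"))
  rfwd3 <- scores[scores$gene_symbol == "RFWD3", flag_columns()]
  expect_equal(unlist(rfwd3, use.names = FALSE), c(1L, 1L, 1L, 1L, 1L, 0L))
  tnf <- scores[scores$gene_symbol == "TNFRSF13B", ]
  expect_equal(tnf$total, 2L)
  expect_true(tnf$is_risk)

  expect_equal(nrow(call_risk_genes(scores, 2)), 14L)
  top <- call_risk_genes(scores, 3)
  expect_equal(top$gene_symbol, c("RFWD3", "HMGXB4", "CDCA7L", "CCHCR1"))
  expect_equal(nrow(call_risk_genes(scores, 7)), 0L)
  expect_equal(nrow(call_risk_genes(scores, 5)), 1L)
})

test_that("risk sets nest across thresholds and flags act monotonically", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 20
      flags <- gene_df(sprintf("ENSG%03d", 1:n))
      for (f in flag_columns()) flags[[f]] <- rbinom(n, 1, 0.4)
      scores <- score_genes(flags)
      prev <- NULL
      for (t in 0:7) {
        ids <- call_risk_genes(scores, t)$gencode_id
        if (!is.null(prev)) expect_true(all(ids %in% prev))
        prev <- ids
      }
      # setting one flag from 0 to 1 never decreases total or rank
      zero <- which(as.matrix(flags[, flag_columns()]) == 0L,
                    arr.ind = TRUE)
      if (nrow(zero)) {
        pick <- zero[sample.int(nrow(zero), 1), ]
        bumped <- flags
        bumped[pick[1], flag_columns()[pick[2]]] <- 1L
        s2 <- score_genes(bumped)
        g <- flags$gencode_id[pick[1]]
        expect_equal(s2$total[s2$gencode_id == g],
                     scores$total[scores$gencode_id == g] + 1L)
        expect_lte(match(g, s2$gencode_id), match(g, scores$gencode_id))
      }
    }
  })
})

test_that("optional BH correction adjusts within categories", {
  membership <- data.frame(
    category = rep("BP", 4),
    term_id = sprintf("GO:%d", 1:4),
    gencode_id = "ENSG1",
    term_size = c(2L, 50L, 500L, 5000L), stringsAsFactors = FALSE)
  raw <- enrich_terms("ENSG1", membership)
  adj <- enrich_terms("ENSG1", membership, correction = "BH")
  expect_equal(adj$raw_p, raw$p_value)
  expect_equal(adj$p_value, p.adjust(raw$p_value, "BH"))
  expect_true(all(adj$p_value >= adj$raw_p))
})

test_that("scoring validates inputs", {
  flags <- table1_fixture()
  expect_error(score_genes(flags, risk_threshold = 9), "risk_threshold")
  flags$missense[1] <- 3L
  expect_error(score_genes(flags), "0/1")
})
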