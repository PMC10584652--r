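test_that("one-hop expansion collects qualifying neighbors of risk genes", {
  edges <- edge_df(c("HUB", "HUB", "HUB", "X"),
                   c("N1", "N2", "N3", "Y"),
                   c(900, 500, 400, 990))
  got <- expand_ppi("HUB", edges, 400)
  expect_equal(got$genes, c("HUB", "N1", "N2", "N3"))
  expect_equal(nrow(got$pairs), 3L)  # X-Y is not incident to a risk gene

  low <- expand_ppi("HUB", edges, 950)
  expect_equal(low$genes, "HUB")
  expect_equal(nrow(low$pairs), 0L)

  expect_warning(empty <- expand_ppi(character(0), edges), "empty")
  expect_equal(empty$genes, character(0))
})

test_that("expansion equals a brute-force incident-edge scan on random graphs", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      nodes <- sprintf("N%02d", 1:50)
      n <- 200
      edges <- edge_df(sample(nodes, n, replace = TRUE),
                       sample(nodes, n, replace = TRUE),
                       sample(0:1000, n, replace = TRUE))
      edges <- edges[edges$protein_a != edges$protein_b, ]
      risk <- sample(nodes, 5)
      min_score <- 400
      got <- expand_ppi(risk, edges, min_score)
      keep <- edges$combined_score >= min_score &
        (edges$protein_a %in% risk | edges$protein_b %in% risk)
      want_genes <- sort(unique(c(risk, edges$protein_a[keep],
                                  edges$protein_b[keep])))
      expect_equal(got$genes, want_genes)
      want_pairs <- unique(paste(pmin(edges$protein_a, edges$protein_b),
                                 pmax(edges$protein_a,
                                      edges$protein_b))[keep])
      expect_setequal(paste(got$pairs$protein_a, got$pairs$protein_b),
                      want_pairs)
      # every added gene touches a risk gene through a retained edge
      added <- setdiff(got$genes, risk)
      for (g in added)
        expect_true(any((got$pairs$protein_a == g &
                           got$pairs$protein_b %in% risk) |
                          (got$pairs$protein_b == g &
                             got$pairs$protein_a %in% risk)))
    }
  })
})

test_that("raising min_score never enlarges the expanded set", {
  withr::with_seed(52, {
    nodes <- sprintf("N%02d", 1:30)
    edges <- edge_df(sample(nodes, 150, replace = TRUE),
                     sample(nodes, 150, replace = TRUE),
                     sample(0:1000, 150, replace = TRUE))
    edges <- edges[edges$protein_a != edges$protein_b, ]
    risk <- sample(nodes, 4)
    prev <- NULL
    for (s in c(0, 300, 600, 900, 1000)) {
      genes <- expand_ppi(risk, edges, s)$genes
      expect_true(all(risk %in% genes))
      if (!is.null(prev)) expect_true(all(genes %in% prev))
      prev <- genes
    }
  })
})

test_that("expansion summaries recount degrees and sizes consistently", {
  edges <- edge_df(c("HUB", "HUB", "HUB"), c("N1", "N2", "N3"), 900)
  got <- expand_ppi("HUB", edges, 400)
  s <- summarize_expansion("HUB", got$genes, got$pairs)
  expect_equal(s$n_risk, 1L)
  expect_equal(s$n_expanded, 4L)
  expect_equal(s$n_pairs, 3L)
  expect_equal(unname(s$degree["HUB"]), 3L)

  e <- suppressWarnings(expand_ppi("Z", edges[0, ], 400))
  s0 <- summarize_expansion("Z", union("Z", e$genes), e$pairs)
  expect_equal(s0$n_expanded, s0$n_risk)

  withr::with_seed(53, {
    nodes <- sprintf("N%02d", 1:20)
    edges <- edge_df(sample(nodes, 80, replace = TRUE),
                     sample(nodes, 80, replace = TRUE),
                     sample(0:1000, 80, replace = TRUE))
    edges <- edges[edges$protein_a != edges$protein_b, ]
    risk <- sample(nodes, 3)
    got <- expand_ppi(risk, edges, 500)
    s <- summarize_expansion(risk, got$genes, got$pairs)
    recount <- table(factor(c(got$pairs$protein_a, got$pairs$protein_b),
                            levels = got$genes))
    expect_equal(unname(s$degree), as.integer(recount))
  })
})

test_that("unmapped edge endpoints are dropped when a symbol map is given", {
  edges <- edge_df(c("A", "A"), c("B", "GHOST"), c(900, 900))
  map <- data.frame(gene_symbol = c("A", "B"), gencode_id = c("E1", "E2"),
                    stringsAsFactors = FALSE)
  got <- suppressMessages(expand_ppi("A", edges, 400, symbol_map = map))
  expect_equal(got$genes, c("A", "B"))
})
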