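test_that("drug mapping keeps drugs with targets inside the expanded set", {
  dt <- data.frame(
    drug_id = c("D1", "D1", "D2", "D3"),
    drug_name = c("alpha", "alpha", "beta", "gamma"),
    target_gene = c("GENEA", "GENEB", "GENEC", "GENEA"),
    pharmacological_action = c("yes", "no", "unknown", "unknown"),
    groups = "approved", stringsAsFactors = FALSE)
  got <- map_drugs(c("GENEA", "GENEB"), dt)
  expect_equal(got$drug_name, c("alpha", "gamma"))  # beta targets outside
  expect_equal(got$targets[got$drug_name == "alpha"], "GENEA;GENEB")
  expect_equal(got$n_targets[got$drug_name == "alpha"], 2L)
  expect_true(got$pharm_action_any[got$drug_name == "alpha"])
  expect_false(got$pharm_action_any[got$drug_name == "gamma"])
  expect_true(all(is.na(got$status)))

  # strict mode keeps only links with known pharmacological action
  strict <- map_drugs(c("GENEA", "GENEB"), dt, pharm_action_only = TRUE)
  expect_equal(strict$drug_name, "alpha")
  expect_equal(strict$targets, "GENEA")
})

test_that("drug mapping equals a brute-force join on random tables", {
  withr::with_seed(61, {
    genes <- sprintf("G%02d", 1:20)
    n <- 100
    dt <- data.frame(
      drug_id = sample(sprintf("D%02d", 1:15), n, replace = TRUE),
      drug_name = NA_character_,
      target_gene = sample(genes, n, replace = TRUE),
      pharmacological_action = sample(c("yes", "no", "unknown"), n,
                                      replace = TRUE),
      groups = "x", stringsAsFactors = FALSE)
    dt$drug_name <- tolower(dt$drug_id)
    expanded <- sample(genes, 8)
    got <- map_drugs(expanded, dt)
    hit <- dt[dt$target_gene %in% expanded, ]
    expect_setequal(got$drug_id, unique(hit$drug_id))
    for (i in seq_len(nrow(got))) {
      h <- hit[hit$drug_id == got$drug_id[i], ]
      expect_equal(got$targets[i],
                   paste(sort(unique(h$target_gene)), collapse = ";"))
      expect_equal(got$pharm_action_any[i],
                   any(h$pharmacological_action == "yes"))
    }
  })
})

test_that("status triage follows the precedence approved > in_trial > novel", {
  fx <- paper_drug_fixture()
  cand <- map_drugs(c("CAMLG", "HDAC2"), fx$drug_targets)
  got <- classify_drug_status(cand, fx$approvals, fx$trials)
  stat <- setNames(got$status, got$drug_name)
  expect_equal(stat[["panobinostat"]], "approved_for_disease")
  expect_equal(stat[["cyclosporine"]], "in_trial")
  expect_equal(got$evidence[got$drug_name == "cyclosporine"],
               "NCT04813653")
  expect_equal(stat[["theophylline"]], "novel")

  # an approval beats a trial record for the same drug and disease
  trials2 <- rbind(fx$trials, data.frame(
    nct_id = "NCT99999999", drug_name = "panobinostat",
    condition = "Multiple Myeloma", status = "Completed"))
  got2 <- classify_drug_status(cand, fx$approvals, trials2)
  expect_equal(got2$status[got2$drug_name == "panobinostat"],
               "approved_for_disease")
  # removing the approval demotes it to in_trial, not novel
  got3 <- classify_drug_status(cand, fx$approvals[0, ], trials2)
  expect_equal(got3$status[got3$drug_name == "panobinostat"], "in_trial")
  expect_equal(got3$evidence[got3$drug_name == "panobinostat"],
               "NCT99999999")
})

test_that("name normalization strips salts and matching is condition-restricted", {
  expect_equal(normalize_drug_name("  Belinostat  SODIUM "), "belinostat")
  expect_equal(normalize_drug_name("vorinostat"), "vorinostat")
  expect_equal(normalize_drug_name("sodium"), "sodium")  # never strip whole

  cand <- data.frame(drug_id = "D1", drug_name = "Belinostat",
                     targets = "HDAC2", n_targets = 1L,
                     pharm_action_any = TRUE, status = NA_character_,
                     evidence = "", stringsAsFactors = FALSE)
  trials <- data.frame(nct_id = c("NCT00000001", "NCT00000002"),
                       drug_name = c("belinostat sodium", "belinostat"),
                       condition = c("Multiple Myeloma", "Breast Cancer"),
                       status = "x", stringsAsFactors = FALSE)
  apr <- data.frame(drug_name = character(0), condition = character(0),
                    approval_id = character(0), stringsAsFactors = FALSE)
  got <- classify_drug_status(cand, apr, trials)
  expect_equal(got$status, "in_trial")
  expect_equal(got$evidence, "NCT00000001")  # breast-cancer trial ignored
})

test_that("partitioning is total, exclusive, and matches a recount", {
  fx <- paper_drug_fixture()
  cand <- classify_drug_status(map_drugs(c("CAMLG", "HDAC2"),
                                         fx$drug_targets),
                               fx$approvals, fx$trials)
  p <- partition_candidates(cand)
  expect_equal(sum(p$counts), nrow(cand))
  expect_equal(unname(p$counts),
               c(1L, 4L, 4L))
  expect_equal(p$drugs$in_trial,
               sort(c("cyclosporine", "belinostat", "vorinostat",
                      "romidepsin")))

  expect_equal(unname(partition_candidates(cand[0, ])$counts),
               c(0L, 0L, 0L))
  bad <- cand
  bad$status[1] <- NA_character_
  expect_error(partition_candidates(bad), "classified")

  withr::with_seed(62, {
    rnd <- cand[sample(nrow(cand), 30, replace = TRUE), ]
    rnd$status <- sample(c("approved_for_disease", "in_trial", "novel"),
                         30, replace = TRUE)
    p2 <- partition_candidates(rnd)
    expect_equal(unname(p2$counts),
                 unname(vapply(c("approved_for_disease", "in_trial",
                                 "novel"),
                               function(s) sum(rnd$status == s),
                               integer(1))))
  })
})
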