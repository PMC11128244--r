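test_that("the cascade assigns tiers in order with viral precedence", {
  v <- test_vocab()
  e <- make_element("C1", n = 3)
  plsdb <- list(accession = "NZ_1", mash_distance = 0.05, mash_pvalue = 0.01,
                host_metadata = "Proteobacteria")

  # confident viral category wins even with a plasmid hit present
  r <- classify_element(e, evidence_bundle("C1", virsorter_category = 2,
                                           plsdb_hit = plsdb), v)
  expect_equal(r$label, "viral")
  expect_equal(r$tier, "virsorter")

  # low-confidence category 3 is not viral evidence; nothing else -> cryptic
  r <- classify_element(e, evidence_bundle("C1", virsorter_category = 3), v)
  expect_equal(r$label, "cryptic")
  expect_equal(r$tier, "none")

  # plasmid tier fires for non-viral with in-threshold mash hit
  r <- classify_element(e, evidence_bundle("C1", plsdb_hit = plsdb), v)
  expect_equal(r$label, "plasmid")
  expect_equal(r$tier, "plsdb")

  # mash thresholds are inclusive
  border <- list(accession = "NZ_2", mash_distance = 0.1, mash_pvalue = 0.1,
                 host_metadata = "x")
  r <- classify_element(e, evidence_bundle("C1", plsdb_hit = border), v)
  expect_equal(r$label, "plasmid")
  over <- list(accession = "NZ_3", mash_distance = 0.100001, mash_pvalue = 0.1,
               host_metadata = "x")
  r <- classify_element(e, evidence_bundle("C1", plsdb_hit = over), v)
  expect_equal(r$label, "cryptic")
})

test_that("Pfam and extended-domain tiers mark unclassified MGEs", {
  v <- test_vocab()
  rep_pfam <- v$replication_pfams[1]
  e <- make_element("C2", n = 3, pfams = list(character(), rep_pfam,
                                              character()))
  r <- classify_element(e, NULL, v)
  expect_equal(r$label, "unclassified_mge")
  expect_equal(r$tier, "pfam_screen")
  expect_true(r$plasmid_replication_domain)
  expect_equal(r$supporting_ids, rep_pfam)

  mob_pfam <- setdiff(v$mge_pfams, v$replication_pfams)[1]
  e <- make_element("C3", n = 2, pfams = mob_pfam)
  r <- classify_element(e, NULL, v)
  expect_equal(r$label, "unclassified_mge")
  expect_false(r$plasmid_replication_domain)

  e <- make_element("C4", n = 2, domains = v$extended_mge_domains[1])
  r <- classify_element(e, NULL, v)
  expect_equal(r$label, "unclassified_mge")
  expect_equal(r$tier, "extended_domains")

  e <- make_element("C5", n = 2)
  expect_equal(classify_element(e, NULL, v)$label, "cryptic")
})

test_that("adding an MGE Pfam moves a cryptic element only to unclassified_mge", {
  v <- test_vocab()
  base <- make_element("C6", n = 3)
  expect_equal(classify_element(base, evidence_bundle("C6"), v)$label,
               "cryptic")
  for (pf in v$mge_pfams) {
    e <- make_element("C6", n = 3, pfams = list(pf, character(), character()))
    expect_equal(classify_element(e, evidence_bundle("C6"), v)$label,
                 "unclassified_mge")
  }
})

test_that("classification recovers every planted synthetic label", {
  sim <- simulate_mobilome(generator_config(seed = 61, n_high = 200,
                                            n_low = 200), test_vocab())
  classes <- classify_elements(sim$elements, sim$evidence, test_vocab())
  expect_equal(stats::setNames(classes$label, classes$element_id)[
    sim$truth$element_id],
    stats::setNames(sim$truth$true_class, sim$truth$element_id))
  # reordering inputs changes no label
  perm <- rev(seq_along(sim$elements))
  classes2 <- classify_elements(sim$elements[perm], sim$evidence, test_vocab())
  m <- match(classes$element_id, classes2$element_id)
  expect_equal(classes2$label[m], classes$label)
})

test_that("class summaries conserve counts and normalize proportions", {
  sim <- simulate_mobilome(generator_config(seed = 67, n_high = 150,
                                            n_low = 150), test_vocab())
  classes <- classify_elements(sim$elements, sim$evidence, test_vocab())
  summ <- summarize_classes(classes, sim$elements)
  for (s in c("high_U", "low_U")) {
    sub <- summ[summ$stratum == s, ]
    expect_equal(sum(sub$count), 150L)
    expect_equal(sum(sub$proportion), 1)
  }
  # all-cryptic set
  els <- as_named(lapply(1:10, function(i) make_element(paste0("X", i), n = 2)))
  cl <- classify_elements(els, list(), test_vocab())
  summ <- summarize_classes(cl, els)
  expect_equal(summ$proportion[summ$label == "cryptic"], 1)
  expect_error(summarize_classes(cl[-1, ], els), "unclassified element")
})

test_that("viral proportion matches the configured rate at scale", {
  sim <- simulate_mobilome(generator_config(seed = 71, n_high = 1000,
                                            n_low = 1000), test_vocab())
  classes <- classify_elements(sim$elements, sim$evidence, test_vocab())
  prop <- mean(classes$label == "viral")
  ci <- 1.96 * sqrt(0.07 * 0.93 / 2000)
  expect_lt(abs(prop - 0.07), ci + 1e-9)
})
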