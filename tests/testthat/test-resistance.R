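test_that("gene screening emits one hit per matching COG", {
  v <- test_vocab()
  e <- make_element("R1", n = 3,
                    cogs = list(c("COG2217", "COG1249"),  # zntA + merA, one gene
                                "COG9001", character()))
  hits <- screen_genes(as_named(e), v, "HMRG")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$orf_index, c(0L, 0L))
  expect_setequal(hits$gene_name, c("zntA", "merA"))
  expect_true(all(c("Zn", "Cd") %in%
                    strsplit(hits$metals[hits$gene_name == "zntA"], ",")[[1]]))
  expect_equal(nrow(screen_genes(as_named(make_element("R2", n = 2)), v,
                                 "HMRG")), 0L)
})

test_that("densities follow the per-Mbp and per-CDS arithmetic", {
  v <- test_vocab()
  # 16 HMRG genes across 500,000 bp -> 32 per Mbp
  els <- as_named(
    make_hmrg_element("D1", n = 250, orfs = 0:15,
                      cog_ids = names(v$hmrg_cogs)[1:8],
                      length_bp = 250000L),
    make_element("D2", n = 250, length_bp = 250000L))
  hits <- screen_genes(els, v, "HMRG")
  dens <- stratum_density(els, hits)
  expect_equal(dens$per_mbp, 32)
  expect_equal(dens$per_cds_fraction, 16 / 500)

  none <- stratum_density(as_named(make_element("D3", n = 2)),
                          screen_genes(as_named(make_element("D3", n = 2)),
                                       v, "HMRG"))
  expect_equal(none$per_mbp, 0)
  expect_equal(none$per_cds_fraction, 0)

  # ratio invariance: duplicating every element leaves densities unchanged
  dup <- c(els, stats::setNames(lapply(els, function(e) {
    e$element_id <- paste0(e$element_id, "_dup"); e
  }), paste0(names(els), "_dup")))
  dens2 <- stratum_density(dup, screen_genes(dup, v, "HMRG"))
  expect_equal(dens2$per_mbp, dens$per_mbp)
  expect_equal(dens2$per_cds_fraction, dens$per_cds_fraction)
})

test_that("enrichment rows exist for every COG with BH across the category", {
  v <- test_vocab()
  els <- as_named(
    make_hmrg_element("EH", n = 50, orfs = 0:9,
                      cog_ids = rep("COG2217", 10), stratum = "high_U"),
    make_element("EL", n = 50, stratum = "low_U"))
  tab <- enrichment_table(els, v, "HMRG")
  expect_setequal(tab$cog_id, names(v$hmrg_cogs))
  zero <- tab[tab$count_high == 0 & tab$count_low == 0, ]
  expect_true(all(zero$p == 1))
  znt <- tab[tab$gene_name == "zntA", ]
  expect_equal(znt$count_high, 10L)
  expect_equal(znt$p,
               fisher_exact_two_tailed(10, 40, 0, 50))
  expect_equal(tab$q, bh_adjust(tab$p))
  expect_error(enrichment_table(els["EH"], v, "HMRG"), "both strata")
})

test_that("adjacency honors circular wrap and the window", {
  v <- test_vocab()
  wrap <- make_hmrg_element("A1", n = 10, orfs = c(1L, 9L),
                            cog_ids = c("COG2217", "COG1249"))
  expect_equal(adjacency_probability(as_named(wrap), v, window = 4), 1)
  far <- make_hmrg_element("A2", n = 12, orfs = c(0L, 6L),
                           cog_ids = c("COG2217", "COG1249"))
  expect_equal(adjacency_probability(as_named(far), v, window = 4), 0)
  # --linear switch disables the wrap
  expect_equal(adjacency_probability(as_named(wrap), v, window = 4,
                                     circular = FALSE), 0)
  # two HMRG COGs on a single gene are not self-adjacent
  one <- make_element("A3", n = 10, cogs = c(list(c("COG2217", "COG1249")),
                                             rep(list(character()), 9)))
  expect_equal(adjacency_probability(as_named(one), v, window = 4), 0)
  # window = 0 is always 0 (orf indices are unique)
  expect_equal(adjacency_probability(as_named(wrap), v, window = 0), 0)
  expect_warning(res <- adjacency_probability(
    as_named(make_element("A4", n = 3)), v), "undefined")
  expect_true(is.na(res))
})

test_that("adjacency equals the brute-force pairwise oracle on random fixtures", {
  v <- test_vocab()
  hmrg_ids <- names(v$hmrg_cogs)
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(8:40, 1)
    k <- sample(2:min(6, n), 1)
    orfs <- sort(sample(0:(n - 1), k))
    e <- make_hmrg_element(paste0("Z", rep), n = n, orfs = orfs,
                           cog_ids = sample(hmrg_ids, k, replace = TRUE))
    w <- sample(0:6, 1)
    got <- adjacency_probability(as_named(e), v, window = w)
    # O(n^2) oracle over all ordered pairs of HMRG genes
    oracle <- mean(vapply(orfs, function(o) {
      any(vapply(setdiff(orfs, o), function(p) {
        d <- abs(p - o); min(d, n - d) <= w
      }, logical(1)))
    }, numeric(1)))
    expect_equal(got, oracle, info = paste("rep", rep))
  }
})

test_that("co-occurrence matrix counts shared elements symmetrically", {
  v <- test_vocab()
  els <- as_named(
    make_hmrg_element("M1", n = 6, orfs = c(0L, 1L),
                      cog_ids = c("COG0789", "COG2059")),   # merR + chrA
    make_hmrg_element("M2", n = 6, orfs = 0L, cog_ids = "COG0789"))
  m <- cooccurrence_matrix(els, v)
  expect_equal(m["merR", "chrA"], 1L)
  expect_equal(m["chrA", "merR"], 1L)
  expect_equal(m["merR", "merR"], 2L)
  expect_equal(m["merR", "zntA"], 0L)
  expect_true(isSymmetric(m))
})

test_that("planted co-occurrence concentrates on the named frequent set", {
  v <- test_vocab()
  sim <- simulate_mobilome(generator_config(seed = 77, n_high = 300,
                                            n_low = 0), v)
  m <- cooccurrence_matrix(sim$elements, v)
  named <- c("merR", "chrB1", "chrA", "copZ", "merA", "arsR", "cusA",
             "cusF", "pcoB", "czcD", "zntA")
  off <- m; diag(off) <- 0L
  in_named <- sum(off[named, named])
  expect_gt(in_named / sum(off), 0.6)
})

test_that("conjugative flags and the HMRG association behave at the extremes", {
  v <- test_vocab()
  conj_el <- make_hmrg_element("G1", n = 8, orfs = 0L, cog_ids = "COG2217")
  conj_el$genes$cogs[[3]] <- v$conj_cogs[1]
  plain <- make_element("G2", n = 8)
  expect_true(conjugative_flag(conj_el, v))
  expect_false(conjugative_flag(plain, v))

  els <- as_named(conj_el, plain)
  classes <- data.frame(element_id = c("G1", "G2", "G3"),
                        label = c("unclassified_mge", "cryptic", "viral"))
  res <- hmrg_conjugation_association(els, v, classes)
  expect_equal(res$fraction_hmrg_on_conjugative, 1)
  expect_equal(res$table["yes", "yes"], 1L)
  expect_equal(res$n_conjugative, 1L)

  viral_el <- make_element("G3", n = 4)
  expect_error(conjugative_flag(viral_el, v, classes), "viral")
  expect_error(hmrg_conjugation_association(as_named(conj_el, viral_el), v,
                                            classes), "viral")
})

test_that("AMG identification excludes viral-function and hypothetical genes", {
  v <- test_vocab()
  e <- make_element("V9", n = 4,
                    cogs = list(character(), character(), "COG2310",
                                character()),
                    product = c("major capsid protein",
                                "hypothetical protein",
                                "TerD domain-containing protein",
                                "oxidoreductase"))
  amgs <- identify_amgs(as_named(e), v)
  expect_setequal(amgs$product, c("TerD domain-containing protein",
                                  "oxidoreductase"))
  expect_equal(amgs$metal_related[amgs$product ==
                                    "TerD domain-containing protein"], TRUE)
  expect_equal(amgs$metal_related[amgs$product == "oxidoreductase"], FALSE)
})

test_that("size statistics use strict thresholds and Welch between strata", {
  els <- as_named(
    make_element("S1", n = 2, length_bp = 20000L),
    make_element("S2", n = 2, length_bp = 20001L),
    make_element("S3", n = 2, length_bp = 150000L),
    make_element("S4", n = 2, length_bp = 3000L, stratum = "low_U"),
    make_element("S5", n = 2, length_bp = 4000L, stratum = "low_U"))
  res <- size_stats(els)
  high <- res$by_stratum[res$by_stratum$stratum == "high_U", ]
  expect_equal(high$count_gt_20000, 2L)      # 20000 itself excluded
  expect_equal(high$count_gt_100000, 1L)
  expect_equal(high$mean_length, mean(c(20000, 20001, 150000)))
  expect_true(res$welch$p < 1)

  eq <- as_named(make_element("T1", n = 2, length_bp = 5000L),
                 make_element("T2", n = 2, length_bp = 6000L),
                 make_element("T3", n = 2, length_bp = 5000L,
                              stratum = "low_U"),
                 make_element("T4", n = 2, length_bp = 6000L,
                              stratum = "low_U"))
  expect_equal(size_stats(eq)$welch$p, 1)
  expect_equal(size_stats(eq)$welch$t, 0)
})
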