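test_that("empty configuration produces empty outputs", {
  sim <- simulate_mobilome(generator_config(seed = 1, n_high = 0, n_low = 0),
                           test_vocab())
  expect_length(sim$elements, 0L)
  expect_length(sim$evidence, 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- generator_config(seed = 23, n_high = 25, n_low = 25)
  s1 <- simulate_mobilome(cfg, test_vocab())
  s2 <- simulate_mobilome(cfg, test_vocab())
  expect_identical(s1$elements, s2$elements)
  expect_identical(s1$evidence, s2$evidence)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation_table(s1$elements, f1)
  write_annotation_table(s2$elements, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_ground_truth(s1$truth, g1); write_ground_truth(s2$truth, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("planted HMRG genes equal HMRG-COG-bearing genes in the annotation", {
  sim <- simulate_mobilome(generator_config(seed = 31, n_high = 120,
                                            n_low = 120), test_vocab())
  hits <- screen_genes(sim$elements, test_vocab(), "HMRG")
  expect_equal(nrow(hits), sum(sim$truth$n_planted_hmrg))
  # and at exactly the planted positions
  for (i in which(sim$truth$n_planted_hmrg > 0)) {
    id <- sim$truth$element_id[i]
    expect_setequal(hits$orf_index[hits$element_id == id],
                    sim$truth$planted_hmrg_positions[[i]])
  }
  # clusters occupy consecutive circular orf positions
  for (i in which(sim$truth$n_planted_hmrg > 1)) {
    pos <- sort(sim$truth$planted_hmrg_positions[[i]])
    n <- n_genes(sim$elements[[sim$truth$element_id[i]]])
    gaps <- diff(c(pos, pos[1] + n))
    expect_equal(sum(gaps > 1), if (length(pos) == n) 0L else 1L,
                 info = sim$truth$element_id[i])
  }
})

test_that("emitted evidence is consistent with the planted class", {
  sim <- simulate_mobilome(generator_config(seed = 37, n_high = 150,
                                            n_low = 150), test_vocab())
  for (i in seq_len(nrow(sim$truth))) {
    id <- sim$truth$element_id[i]
    ev <- sim$evidence[[id]]
    cls <- sim$truth$true_class[i]
    confident_viral <- !is.null(ev$virsorter_category) &&
      ev$virsorter_category %in% c(1, 2, 4, 5)
    expect_equal(confident_viral, cls == "viral", info = id)
    expect_equal(!is.null(ev$plsdb_hit), cls == "plasmid", info = id)
  }
})

test_that("realized lengths follow the configured bimodal mixture", {
  cfg <- generator_config(seed = 41, n_high = 2000, n_low = 0)
  sim <- simulate_mobilome(cfg, test_vocab())
  lens <- as.numeric(element_lengths(sim$elements))

  mix_mean <- sum(cfg$length_weights$high_U *
                    exp(cfg$length_meanlog + cfg$length_sdlog^2 / 2))
  expect_lt(abs(mean(lens) - mix_mean) / mix_mean, 0.20)

  mix_cdf <- function(q) {
    w <- cfg$length_weights$high_U
    w[1] * plnorm(q, cfg$length_meanlog[1], cfg$length_sdlog) +
      w[2] * plnorm(q, cfg$length_meanlog[2], cfg$length_sdlog)
  }
  ks <- suppressWarnings(stats::ks.test(lens, mix_cdf))
  expect_lt(unname(ks$statistic), 0.05)

  # bimodal: both mode regions carry more mass than the inter-mode valley
  p_small <- mean(lens >= 2000 & lens <= 4500)
  p_large <- mean(lens >= 47000 & lens <= 104000)
  p_valley <- mean(lens >= 10000 & lens <= 21000)
  expect_gt(p_small, p_valley)
  expect_gt(p_large, p_valley)
})

test_that("null_config removes every planted stratum effect and is idempotent", {
  cfg <- generator_config(seed = 1)
  nul <- null_config(cfg)
  expect_equal(unname(nul$hmrg_cluster_rate),
               rep(cfg$hmrg_cluster_rate[["low_U"]], 2))
  expect_identical(nul$host_mixture$high_U, cfg$host_mixture$low_U)
  expect_identical(nul$length_weights$high_U, cfg$length_weights$low_U)
  expect_identical(null_config(nul), nul)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(p_viral = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(n_high = -1), ">= 0")
  expect_error(
    generator_config(length_weights = list(high_U = c(0, 0),
                                           low_U = c(0.8, 0.2))),
    "zero-weight")
})

test_that("ground-truth manifest round-trips through JSON", {
  sim <- simulate_mobilome(generator_config(seed = 3, n_high = 10, n_low = 10),
                           test_vocab())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$element_id, sim$truth$element_id)
  expect_equal(back$true_class, sim$truth$true_class)
  expect_equal(back$planted_conj, sim$truth$planted_conj)
  expect_equal(back$planted_hmrg_positions, sim$truth$planted_hmrg_positions,
               ignore_attr = TRUE)
})
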