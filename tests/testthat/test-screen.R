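test_that("organelle detection applies the inclusive 0.5 threshold", {
  v <- test_vocab()
  chloro <- make_element("O1", n = 4,
                         product = c("chloroplast envelope protein",
                                     "chloroplast ATP synthase",
                                     "photosystem II protein",
                                     "chloroplast rRNA"))
  expect_true(detect_organelle(chloro, v))                    # 3 of 4
  none <- make_element("O2", n = 4, product = "efflux pump")
  expect_false(detect_organelle(none, v))
  half <- make_element("O3", n = 4,
                       product = c("mitochondrial carrier", "cox1",
                                   "mitochondrial ribosomal protein", "cox2"))
  expect_true(detect_organelle(half, v))                      # exactly 2 of 4
  # taxonomy lineage alone can trigger the screen
  tax <- make_element("O4", n = 2, tax_phylum = "Streptophyta")
  expect_true(detect_organelle(tax, v))
})

test_that("tandem-repeat artifacts are detected via whole-copy identity", {
  perfect <- strrep("ACGT", 100)                              # 400 bp, k = 100
  expect_true(detect_tandem_repeat_artifact(perfect))

  set.seed(99)
  random <- random_dna(400)
  # oracle: exhaustive periodicity scan over every divisor of the length
  oracle <- function(s, thr = 0.95) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    for (k in 2:n) {
      if (n %% k != 0) next
      m <- matrix(ch, nrow = n / k)
      if (all(colMeans(m == m[, 1]) >= thr)) return(TRUE)
    }
    FALSE
  }
  expect_false(oracle(random))
  expect_false(detect_tandem_repeat_artifact(random))

  unit <- random_dna(300)
  two <- paste0(unit, unit)
  mut <- strsplit(two, "")[[1]]
  pos <- sample(301:600, 9)                   # 3% mismatches in copy 2
  mut[pos] <- vapply(mut[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  mutated <- paste(mut, collapse = "")
  expect_true(detect_tandem_repeat_artifact(mutated))         # identity 0.97
  expect_true(oracle(mutated))
  expect_true(is.na(detect_tandem_repeat_artifact(NA_character_)))
})

test_that("dereplication collapses duplicates and rotations", {
  set.seed(7)
  seq1 <- random_dna(2000)
  els <- as_named(
    make_element("A_long", n = 2, length_bp = 2000, sequence = seq1),
    make_element("B_copy", n = 2, length_bp = 2000, sequence = seq1),
    make_element("C_rot", n = 2, length_bp = 2000,
                 sequence = rotate_seq(seq1, 17)))
  der <- dereplicate(els)
  expect_length(der$representatives, 1L)
  expect_equal(sum(der$report$removed), 2L)
  expect_true(all(der$report$cluster_representative == "A_long"))

  # reverse complement also collapses
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq1)))
  els2 <- as_named(make_element("A", n = 2, length_bp = 2000, sequence = seq1),
                   make_element("B", n = 2, length_bp = 2000, sequence = rc))
  expect_length(dereplicate(els2)$representatives, 1L)
})

test_that("mutually divergent elements all remain representatives", {
  set.seed(13)
  els <- as_named(lapply(1:5, function(i)
    make_element(paste0("D", i), n = 2, length_bp = 1500,
                 sequence = random_dna(1500))))
  # oracle: all-pairs identity is far below 0.99 for independent sequences
  for (i in 1:4) for (j in (i + 1):5) {
    hit <- metamobilome:::circular_identity(els[[i]]$sequence,
                                            els[[j]]$sequence)
    expect_lt(hit$identity * hit$coverage, 0.99 * 0.90)
  }
  der <- dereplicate(els)
  expect_length(der$representatives, 5L)
})

test_that("dereplication is idempotent, order-independent, and rejects mixed strata", {
  sim <- simulate_mobilome(generator_config(seed = 55, n_high = 40, n_low = 0),
                           test_vocab())
  d1 <- dereplicate(sim$elements)
  d2 <- dereplicate(d1$representatives)
  expect_identical(names(d2$representatives), names(d1$representatives))
  expect_false(any(d2$report$removed))

  perm <- sample(length(sim$elements))
  d3 <- dereplicate(sim$elements[perm])
  expect_setequal(names(d3$representatives), names(d1$representatives))
  r1 <- d1$report[order(d1$report$element_id), ]
  r3 <- d3$report[order(d3$report$element_id), ]
  expect_equal(r1$cluster_representative, r3$cluster_representative)

  mixed <- simulate_mobilome(generator_config(seed = 56, n_high = 3, n_low = 3),
                             test_vocab())
  expect_error(dereplicate(mixed$elements), "single stratum")
})

test_that("screen_elements combines filters and per-stratum dereplication", {
  v <- test_vocab()
  set.seed(21)
  seqA <- random_dna(2000)
  els <- as_named(
    make_element("K1", n = 2, length_bp = 2000, sequence = seqA),
    make_element("K2", n = 2, length_bp = 2000, sequence = seqA,
                 stratum = "low_U"),           # same seq, other stratum: kept
    make_element("K3", n = 2, length_bp = 2000, sequence = rotate_seq(seqA, 5)),
    make_element("K4", n = 4, product = "chloroplast protein",
                 sequence = random_dna(4000), length_bp = 4000),
    make_element("K5", n = 2, length_bp = 400, pitch = 100,
                 sequence = strrep("ACGT", 100)))
  res <- suppressMessages(screen_elements(els, v))
  rep <- res$report
  expect_setequal(names(res$representatives), c("K1", "K2"))
  expect_equal(rep$reason[rep$element_id == "K3"], "duplicate")
  expect_equal(rep$reason[rep$element_id == "K4"], "organelle")
  expect_equal(rep$reason[rep$element_id == "K5"], "tandem_repeat_artifact")
  expect_true(rep$removed[rep$element_id == "K3"])
  # every surviving element maps to itself
  kept <- rep[!rep$removed, ]
  expect_equal(kept$cluster_representative, kept$element_id)
})
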