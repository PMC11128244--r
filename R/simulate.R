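#' Configuration for the synthetic mobilome generator
#'
#' Defines the statistical structure of a simulated population of annotated
#' circular elements: a bimodal (two-component log-normal) length mixture
#' with modes near 3 kb and 70 kb, stratum-dependent heavy-metal-resistance
#' gene (HMRG) cluster planting, conjugation modules on large elements,
#' host-taxonomy mixtures with imperfect per-gene annotation fidelity, and
#' external-tool evidence (viral categories, plasmid-database hits, CRISPR
#' spacers, k-mer host calls).
#'
#' @param seed Integer RNG seed; a fixed seed makes [simulate_mobilome()]
#'   fully deterministic.
#' @param n_high,n_low Number of elements per contamination stratum.
#' @param length_meanlog,length_sdlog Log-normal location (defaults
#'   `log(3000)`, `log(70000)`) and common shape (0.5) of the two length
#'   components.
#' @param length_weights Per-stratum mixture weights (small, large); the low
#'   stratum is skewed toward the small mode.
#' @param gene_pitch Mean bp per gene (default 1000).
#' @param p_viral Fraction of elements given a confident viral category
#'   (1/2/4/5).
#' @param p_viral_decoy Fraction of otherwise-cryptic elements given a
#'   low-confidence viral category (3/6), which the classifier must discard.
#' @param p_plasmid_hit Fraction of non-viral elements given a
#'   plasmid-database hit within the mash thresholds.
#' @param p_mge_pfam Fraction of remaining elements given an MGE-associated
#'   Pfam domain.
#' @param p_mge_domain Fraction of remaining elements given an
#'   extended-library MGE domain (second-pass screen tier).
#' @param hmrg_cluster_rate Named per-stratum probability that a non-viral
#'   element carries a planted HMRG cluster.
#' @param cluster_mean_extra HMRG cluster size is `1 + Poisson(mean)` genes
#'   at consecutive ORF positions.
#' @param p_conj Probability that an element larger than `conj_min_bp`
#'   carries a conjugation module of 5-10 distinct conjugal COGs.
#' @param conj_min_bp Size threshold for conjugation modules (default
#'   20000).
#' @param host_mixture Per-stratum phylum frequency map; the high stratum is
#'   skewed toward Proteobacteria.
#' @param annotation_fidelity Probability that an annotated gene's taxonomy
#'   equals the element's true host.
#' @param p_unannotated_tax Probability that a gene carries no taxonomy.
#' @param p_gene_annotated Probability that a background gene carries a COG
#'   annotation at all.
#' @param php_accuracy Phylum-level accuracy of the simulated k-mer host
#'   predictor for viral elements.
#' @param p_crispr Probability that a viral element has CRISPR-spacer hits.
#' @param p_viral_metal_amg Probability that a viral element carries one
#'   metal-related auxiliary gene (tellurium-resistance-family COG).
#' @param emit_sequences Generate nucleotide sequences (slower; only needed
#'   for sequence-level screening tests).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_high = 100L, n_low = 100L,
                             length_meanlog = log(c(3000, 70000)),
                             length_sdlog = 0.5,
                             length_weights = list(high_U = c(0.5, 0.5),
                                                   low_U = c(0.8, 0.2)),
                             gene_pitch = 1000,
                             p_viral = 0.07, p_viral_decoy = 0.02,
                             p_plasmid_hit = 0.015, p_mge_pfam = 0.3,
                             p_mge_domain = 0.05,
                             hmrg_cluster_rate = c(high_U = 0.10, low_U = 0.02),
                             cluster_mean_extra = 3,
                             p_conj = 0.25, conj_min_bp = 20000,
                             host_mixture = list(
                               high_U = c(Proteobacteria = 0.70,
                                          Bacteroidota = 0.10,
                                          Actinomycetota = 0.10,
                                          Bacillota = 0.05,
                                          Acidobacteriota = 0.05),
                               low_U = c(Proteobacteria = 0.35,
                                         Bacteroidota = 0.20,
                                         Actinomycetota = 0.20,
                                         Bacillota = 0.15,
                                         Acidobacteriota = 0.10)),
                             annotation_fidelity = 0.7,
                             p_unannotated_tax = 0.2,
                             p_gene_annotated = 0.7,
                             php_accuracy = 0.8, p_crispr = 0.3,
                             p_viral_metal_amg = 0.02,
                             emit_sequences = FALSE) {
  cfg <- list(seed = as.integer(seed), n_high = as.integer(n_high),
              n_low = as.integer(n_low), length_meanlog = length_meanlog,
              length_sdlog = length_sdlog, length_weights = length_weights,
              gene_pitch = gene_pitch, p_viral = p_viral,
              p_viral_decoy = p_viral_decoy, p_plasmid_hit = p_plasmid_hit,
              p_mge_pfam = p_mge_pfam, p_mge_domain = p_mge_domain,
              hmrg_cluster_rate = hmrg_cluster_rate,
              cluster_mean_extra = cluster_mean_extra, p_conj = p_conj,
              conj_min_bp = conj_min_bp, host_mixture = host_mixture,
              annotation_fidelity = annotation_fidelity,
              p_unannotated_tax = p_unannotated_tax,
              p_gene_annotated = p_gene_annotated,
              php_accuracy = php_accuracy, p_crispr = p_crispr,
              p_viral_metal_amg = p_viral_metal_amg,
              emit_sequences = isTRUE(emit_sequences))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_viral, cfg$p_viral_decoy, cfg$p_plasmid_hit, cfg$p_mge_pfam,
             cfg$p_mge_domain, cfg$hmrg_cluster_rate, cfg$p_conj,
             cfg$annotation_fidelity, cfg$p_unannotated_tax,
             cfg$p_gene_annotated, cfg$php_accuracy, cfg$p_crispr,
             cfg$p_viral_metal_amg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_high < 0L || cfg$n_low < 0L) stop("element counts must be >= 0")
  for (s in c("high_U", "low_U")) {
    w <- cfg$length_weights[[s]]
    n <- if (s == "high_U") cfg$n_high else cfg$n_low
    if (length(w) != 2L || any(w < 0)) stop("invalid length weights for ", s)
    if (n > 0L && sum(w) == 0)
      stop("zero-weight length mixture in stratum ", s, " with n > 0")
    if (n > 0L && abs(sum(w) - 1) > 1e-8)
      stop("length mixture weights for ", s, " must sum to 1")
    h <- cfg$host_mixture[[s]]
    if (n > 0L && (is.null(h) || abs(sum(h) - 1) > 1e-8 || any(h < 0)))
      stop("host mixture for ", s, " must be non-negative and sum to 1")
  }
  if (!all(c("high_U", "low_U") %in% names(cfg$hmrg_cluster_rate)))
    stop("hmrg_cluster_rate must be named high_U / low_U")
  cfg
}

#' Null counterpart of a generator configuration
#'
#' Returns a copy in which both strata share the low-contamination stratum's
#' HMRG cluster rate, host mixture and length mixture, so no stratum effect
#' is planted. Used as the type-I-error harness for downstream enrichment
#' testing. Idempotent.
#'
#' @param config A `generator_config`.
#' @return A `generator_config` with no between-stratum differences.
#' @export
null_config <- function(config) {
  config$hmrg_cluster_rate[] <- config$hmrg_cluster_rate[["low_U"]]
  config$host_mixture$high_U <- config$host_mixture$low_U
  config$length_weights$high_U <- config$length_weights$low_U
  config
}

.proteo_classes <- c(Gammaproteobacteria = 0.5, Betaproteobacteria = 0.3,
                     Alphaproteobacteria = 0.2)
.phylum_class <- c(Bacteroidota = "Bacteroidia",
                   Actinomycetota = "Actinomycetes",
                   Bacillota = "Bacilli",
                   Acidobacteriota = "Acidobacteriae")
.phylum_genera <- list(
  Proteobacteria = c("Rhodanobacter", "Pseudomonas", "Burkholderia"),
  Bacteroidota = c("Flavobacterium", "Chryseobacterium"),
  Actinomycetota = c("Arthrobacter", "Mycobacterium"),
  Bacillota = c("Bacillus", "Clostridium"),
  Acidobacteriota = c("Terriglobus"))
.viral_products <- c("major capsid protein", "terminase large subunit",
                     "portal protein", "tail fiber protein",
                     "phage tail sheath protein", "baseplate assembly protein",
                     "phage integrase", "DNA polymerase", "DNA primase",
                     "holin", "N-acetylmuramoyl-L-alanine amidase endolysin")
.functional_products <- c("oxidoreductase", "SAM-dependent methyltransferase",
                          "ABC transporter ATP-binding protein",
                          "MFS transporter", "response regulator",
                          "two-component sensor histidine kinase",
                          "acyl-CoA dehydrogenase", "GNAT family acetyltransferase")

#' Simulate a synthetic annotated mobilome
#'
#' Generates a population of annotated circular elements for both
#' contamination strata under `config`, the matching external-evidence
#' bundles, and a ground-truth manifest for recovery tests. HMRG clusters
#' occupy consecutive ORF positions (so neighborhood statistics can recover
#' them); cluster COGs are drawn without replacement, weighted toward the
#' frequently co-occurring set (merR, chrB1, chrA, copZ, merA, arsR, cusA,
#' cusF, pcoB, czcD, zntA); background genes draw from a neutral COG pool
#' disjoint from every curated list, so planted signal is unambiguous.
#' Cryptic elements simply emit no MGE-related evidence or domains.
#'
#' @param config A [generator_config()].
#' @param vocab An [load_vocabulary()] vocabulary supplying the curated COG
#'   and Pfam ids to plant.
#' @return A list with `elements` (named list of `circular_element`),
#'   `evidence` (named list of `evidence_bundle`), and `truth` (data frame
#'   with `element_id`, `true_class`, `true_host_phylum`, `true_host_class`,
#'   `planted_conj`, and list column `planted_hmrg_positions`).
#' @export
simulate_mobilome <- function(config, vocab = load_vocabulary()) {
  validate_generator_config(config)
  set.seed(config$seed)

  named_cooccur <- c("merR", "chrB1", "chrA", "copZ", "merA", "arsR", "cusA",
                     "cusF", "pcoB", "czcD", "zntA")
  hmrg_ids <- names(vocab$hmrg_cogs)
  gene_name <- hmrg_gene_names(vocab)
  hmrg_weights <- ifelse(gene_name[hmrg_ids] %in% named_cooccur, 8, 1)
  te_cogs <- hmrg_ids[vapply(vocab$hmrg_cogs, function(m) "Te" %in% m, logical(1))]
  neutral_pool <- sprintf("COG9%03d", 0:299)

  elements <- list(); evidence <- list(); truth_rows <- list()
  idx <- 0L
  for (stratum in c("high_U", "low_U")) {
    n <- if (stratum == "high_U") config$n_high else config$n_low
    if (n == 0L) next
    w <- config$length_weights[[stratum]]
    comp <- sample.int(2L, n, replace = TRUE, prob = w)
    lengths <- pmax(500L, as.integer(round(stats::rlnorm(
      n, config$length_meanlog[comp], config$length_sdlog))))
    hosts <- sample(names(config$host_mixture[[stratum]]), n, replace = TRUE,
                    prob = config$host_mixture[[stratum]])
    for (i in seq_len(n)) {
      idx <- idx + 1L
      out <- simulate_element(
        sprintf("SYN_%s_%04d", sub("_U$", "", stratum), idx),
        sprintf("S_%s_%02d", sub("_U$", "", stratum), 1L + (idx %% 5L)),
        stratum, lengths[i], hosts[i], config, vocab,
        hmrg_ids, hmrg_weights, te_cogs, neutral_pool, gene_name)
      elements[[out$element$element_id]] <- out$element
      evidence[[out$element$element_id]] <- out$evidence
      truth_rows[[out$element$element_id]] <- out$truth
    }
  }
  truth <- do.call(rbind, lapply(truth_rows, function(r) {
    data.frame(element_id = r$element_id, true_class = r$true_class,
               true_host_phylum = r$true_host_phylum,
               true_host_class = r$true_host_class,
               planted_conj = r$planted_conj,
               n_planted_hmrg = length(r$planted_hmrg_positions),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(element_id = character(), true_class = character(),
                        true_host_phylum = character(),
                        true_host_class = character(),
                        planted_conj = logical(), n_planted_hmrg = integer())
    truth$planted_hmrg_positions <- list()
  } else {
    truth$planted_hmrg_positions <-
      lapply(truth_rows, function(r) r$planted_hmrg_positions)
    rownames(truth) <- NULL
  }
  list(elements = elements, evidence = evidence, truth = truth)
}

simulate_element <- function(id, sample_id, stratum, length_bp, host_phylum,
                             config, vocab, hmrg_ids, hmrg_weights, te_cogs,
                             neutral_pool, gene_name) {
  n_gene <- max(1L, stats::rpois(1L, length_bp / config$gene_pitch))
  host_class <- if (host_phylum == "Proteobacteria")
    sample(names(.proteo_classes), 1L, prob = .proteo_classes)
  else .phylum_class[[host_phylum]] %||% paste0(host_phylum, "_cl")

  # role draw mirrors the classification cascade tiers
  u <- stats::runif(1)
  role <- if (u < config$p_viral) "viral"
  else if (u < config$p_viral + config$p_plasmid_hit) "plasmid"
  else if (u < config$p_viral + config$p_plasmid_hit + config$p_mge_pfam) "mge_pfam"
  else if (u < config$p_viral + config$p_plasmid_hit + config$p_mge_pfam +
           config$p_mge_domain) "mge_domain"
  else "cryptic"

  # gene scaffold on the circle; a random phase lets the last gene span the origin
  pitch <- length_bp / n_gene
  phase <- sample.int(length_bp, 1L) - 1L
  start <- (floor((seq_len(n_gene) - 1L) * pitch) + phase) %% length_bp + 1L
  glen <- pmax(90L, as.integer(floor(pitch * 0.75)))
  end <- start + glen - 1L   # may exceed length_bp: origin-spanning, mod length
  strand <- sample(c("+", "-"), n_gene, replace = TRUE)

  # background annotation
  has_cog <- stats::runif(n_gene) < config$p_gene_annotated
  cogs <- vector("list", n_gene)
  cogs[has_cog] <- as.list(sample(neutral_pool, sum(has_cog), replace = TRUE))
  cogs[!has_cog] <- list(character())
  product <- ifelse(has_cog,
                    sample(.functional_products, n_gene, replace = TRUE),
                    NA_character_)
  pfams <- rep(list(character()), n_gene)
  domains <- rep(list(character()), n_gene)

  if (role == "viral") {
    r <- stats::runif(n_gene)
    viral_gene <- r < 0.55
    unann <- r >= 0.55 & r < 0.80
    product[viral_gene] <- sample(.viral_products, sum(viral_gene), replace = TRUE)
    product[unann] <- NA_character_
    cogs[unann] <- list(character())
  }

  planted <- integer()
  # HMRG cluster planting (non-viral elements)
  if (role != "viral" &&
      stats::runif(1) < config$hmrg_cluster_rate[[stratum]]) {
    size <- min(n_gene, 1L + stats::rpois(1L, config$cluster_mean_extra))
    anchor <- sample.int(n_gene, 1L) - 1L
    planted <- (anchor + 0:(size - 1L)) %% n_gene        # consecutive orfs, wrap
    picked <- sample(hmrg_ids, size, replace = size > length(hmrg_ids),
                     prob = hmrg_weights)
    for (j in seq_len(size)) {
      g <- planted[j] + 1L
      cogs[[g]] <- picked[j]
      product[g] <- paste(gene_name[[picked[j]]], "family heavy metal resistance protein")
    }
  }
  # single metal-related auxiliary gene on an occasional viral element
  if (role == "viral" && stats::runif(1) < config$p_viral_metal_amg) {
    g <- sample.int(n_gene, 1L)
    pick <- sample(te_cogs, 1L)
    cogs[[g]] <- pick
    product[g] <- paste(gene_name[[pick]], "domain-containing protein")
    planted <- g - 1L
  }

  # conjugation module on large elements
  planted_conj <- FALSE
  if (length_bp > config$conj_min_bp && stats::runif(1) < config$p_conj) {
    k <- min(sample(5:10, 1L), length(vocab$conj_cogs))
    free <- setdiff(seq_len(n_gene) - 1L, planted)
    if (length(free) >= k) {
      slots <- sample(free, k) + 1L
      picked <- sample(vocab$conj_cogs, k)
      for (j in seq_len(k)) {
        cogs[[slots[j]]] <- picked[j]
        product[slots[j]] <- "conjugal transfer protein"
      }
      planted_conj <- TRUE
    }
  }

  # MGE domains defining the pfam/extended tiers
  if (role == "mge_pfam") {
    g <- sample.int(n_gene, 1L)
    pfams[[g]] <- sample(vocab$mge_pfams, 1L)
    product[g] <- if (pfams[[g]] %in% vocab$replication_pfams)
      "plasmid replication initiation protein" else "mobile element protein"
  } else if (role == "mge_domain") {
    g <- sample.int(n_gene, 1L)
    domains[[g]] <- sample(vocab$extended_mge_domains, 1L)
    product[g] <- "mobilization protein"
  }

  # per-gene taxonomy with imperfect fidelity
  all_phyla <- names(config$host_mixture[[stratum]])
  tax_phylum <- rep(NA_character_, n_gene); tax_class <- rep(NA_character_, n_gene)
  r <- stats::runif(n_gene)
  annotated_tax <- r >= config$p_unannotated_tax
  correct <- annotated_tax & (stats::runif(n_gene) < config$annotation_fidelity)
  wrong <- annotated_tax & !correct
  tax_phylum[correct] <- host_phylum; tax_class[correct] <- host_class
  if (any(wrong)) {
    others <- setdiff(all_phyla, host_phylum)
    wp <- sample(others, sum(wrong), replace = TRUE)
    tax_phylum[wrong] <- wp
    tax_class[wrong] <- vapply(wp, function(p) {
      if (p == "Proteobacteria") sample(names(.proteo_classes), 1L,
                                        prob = .proteo_classes)
      else .phylum_class[[p]] %||% paste0(p, "_cl")
    }, character(1))
  }

  genes <- gene_table(
    gene_id = sprintf("%s_g%03d", id, seq_len(n_gene) - 1L),
    orf_index = seq_len(n_gene) - 1L, start = start, end = end,
    strand = strand, cogs = cogs, pfams = pfams, domains = domains,
    tax_phylum = tax_phylum, tax_class = tax_class, product = product)
  sequence <- if (config$emit_sequences)
    paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
          collapse = "") else NA_character_
  element <- circular_element(id, sample_id, stratum, length_bp, genes, sequence)

  # evidence emission consistent with the planted role
  ev <- switch(role,
    viral = {
      crispr <- data.frame(taxon = character(), mismatches = integer())
      if (stats::runif(1) < config$p_crispr) {
        nh <- sample(1:2, 1L)
        crispr <- data.frame(
          taxon = sample(.phylum_genera[[host_phylum]], nh, replace = TRUE),
          mismatches = sample(0:3, nh, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      php <- if (stats::runif(1) < config$php_accuracy) host_phylum
             else sample(setdiff(all_phyla, host_phylum), 1L)
      evidence_bundle(id, virsorter_category = sample(c(1L, 2L, 4L, 5L), 1L),
                      crispr_hits = crispr, php_phylum = php,
                      lifestyle = sample(c("temperate", "virulent"), 1L,
                                         prob = c(0.45, 0.55)))
    },
    plasmid = evidence_bundle(id, plsdb_hit = list(
      accession = sprintf("NZ_CP%06d", sample.int(999999L, 1L)),
      mash_distance = stats::runif(1, 0, 0.1),
      mash_pvalue = stats::runif(1, 0, 0.1),
      host_metadata = host_phylum)),
    cryptic = if (stats::runif(1) < config$p_viral_decoy)
      evidence_bundle(id, virsorter_category = sample(c(3L, 6L), 1L))
    else evidence_bundle(id),
    evidence_bundle(id))

  true_class <- switch(role, viral = "viral", plasmid = "plasmid",
                       mge_pfam = "unclassified_mge",
                       mge_domain = "unclassified_mge", cryptic = "cryptic")
  list(element = element, evidence = ev,
       truth = list(element_id = id, true_class = true_class,
                    true_host_phylum = host_phylum,
                    true_host_class = host_class,
                    planted_conj = planted_conj,
                    planted_hmrg_positions = as.integer(sort(planted))))
}

#' Write / read a ground-truth manifest
#'
#' JSON serialization of the generator's ground truth, for recovery tests
#' run from files rather than in-memory objects.
#'
#' @param truth Ground-truth data frame from [simulate_mobilome()].
#' @param path JSON path.
#' @return `write_ground_truth()`: invisibly, the path; `read_ground_truth()`:
#'   the ground-truth data frame.
#' @export
write_ground_truth <- function(truth, path) {
  recs <- lapply(seq_len(nrow(truth)), function(i) list(
    element_id = truth$element_id[i], true_class = truth$true_class[i],
    true_host_phylum = truth$true_host_phylum[i],
    true_host_class = truth$true_host_class[i],
    planted_conj = truth$planted_conj[i],
    planted_hmrg_positions = truth$planted_hmrg_positions[[i]]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  recs <- jsonlite::read_json(path)
  truth <- data.frame(
    element_id = vapply(recs, `[[`, character(1), "element_id"),
    true_class = vapply(recs, `[[`, character(1), "true_class"),
    true_host_phylum = vapply(recs, `[[`, character(1), "true_host_phylum"),
    true_host_class = vapply(recs, `[[`, character(1), "true_host_class"),
    planted_conj = vapply(recs, `[[`, logical(1), "planted_conj"),
    stringsAsFactors = FALSE)
  truth$n_planted_hmrg <- vapply(recs, function(r)
    length(r$planted_hmrg_positions), integer(1))
  truth$planted_hmrg_positions <- lapply(recs, function(r)
    as.integer(unlist(r$planted_hmrg_positions)))
  truth
}
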