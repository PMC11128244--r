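#' Configuration for a full pipeline run
#'
#' Gathers every stage threshold in one serializable object so that a run is
#' reproducible from its configuration alone. Defaults are the documented
#' package defaults.
#'
#' @param vocab_dir Vocabulary directory (default: packaged vocabulary).
#' @param organelle_fraction Organelle screen threshold (default 0.5).
#' @param repeat_identity Tandem-repeat screen identity (default 0.95).
#' @param derep_identity,derep_coverage Dereplication thresholds (0.99,
#'   0.90).
#' @param mash_max_pvalue,mash_max_distance Plasmid-tier thresholds (0.1,
#'   0.1).
#' @param vote_denominator `"all"` or `"annotated"` CDS for the host vote.
#' @param crispr_max_mismatches CRISPR spacer filter (default 1).
#' @param adjacency_window Neighborhood window in ORFs (default 4).
#' @param adjacency_circular Honor circular topology (default `TRUE`).
#' @param fdr_alpha Significance level on BH-adjusted q-values (0.05).
#' @param include_cryptic Keep cryptic elements in enrichment (default
#'   `TRUE`).
#' @return List of class `run_config`.
#' @export
run_config <- function(vocab_dir = system.file("extdata", "vocab",
                                               package = "metamobilome"),
                       organelle_fraction = 0.5, repeat_identity = 0.95,
                       derep_identity = 0.99, derep_coverage = 0.90,
                       mash_max_pvalue = 0.1, mash_max_distance = 0.1,
                       vote_denominator = "all", crispr_max_mismatches = 1L,
                       adjacency_window = 4L, adjacency_circular = TRUE,
                       fdr_alpha = 0.05, include_cryptic = TRUE) {
  structure(list(
    vocab_dir = vocab_dir, organelle_fraction = organelle_fraction,
    repeat_identity = repeat_identity, derep_identity = derep_identity,
    derep_coverage = derep_coverage, mash_max_pvalue = mash_max_pvalue,
    mash_max_distance = mash_max_distance,
    vote_denominator = vote_denominator,
    crispr_max_mismatches = as.integer(crispr_max_mismatches),
    adjacency_window = as.integer(adjacency_window),
    adjacency_circular = adjacency_circular, fdr_alpha = fdr_alpha,
    include_cryptic = include_cryptic), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes screen -> classify -> host -> resistance statistics on a set of
#' elements plus evidence, and returns a machine-readable summary embedding
#' the resolved configuration and vocabulary checksums. Identical inputs and
#' configuration give identical output.
#'
#' @param elements Named list of `circular_element`.
#' @param evidence Named list of `evidence_bundle`.
#' @param config A [run_config()].
#' @param outdir Optional directory: when given, writes `summary.json` plus
#'   TSV tables (`screen_report`, `classes`, `hosts`, `enrichment`,
#'   `densities`, `conjugation`, `amgs`, `cooccurrence`).
#' @return List with `summary` (plain list, JSON-serializable) and `tables`
#'   (the intermediate data frames).
#' @export
run_pipeline <- function(elements, evidence, config = run_config(),
                         outdir = NULL) {
  vocab <- load_vocabulary(config$vocab_dir)

  scr <- screen_elements(elements, vocab,
                         identity = config$derep_identity,
                         coverage = config$derep_coverage,
                         organelle_fraction = config$organelle_fraction,
                         repeat_identity = config$repeat_identity)
  surv <- scr$representatives
  if (length(surv) == 0L) stop("screening removed every element")

  classes <- classify_elements(surv, evidence, vocab,
                               config$mash_max_pvalue, config$mash_max_distance)
  class_summary <- summarize_classes(classes, surv)
  hosts <- host_summary(surv, classes, evidence,
                        denominator = config$vote_denominator)

  lab <- stats::setNames(classes$label, classes$element_id)
  nonviral <- surv[lab[element_ids(surv)] != "viral"]
  viral <- surv[lab[element_ids(surv)] == "viral"]

  hmrg_hits <- screen_genes(surv, vocab, "HMRG")
  dens <- stratum_density(surv, hmrg_hits)
  sizes <- size_stats(surv)

  strata <- element_strata(surv)
  both_strata <- all(c("high_U", "low_U") %in% strata)
  enr <- if (both_strata)
    enrichment_table(surv, vocab, "HMRG",
                     include_cryptic = config$include_cryptic,
                     classes = classes) else NULL

  adjacency <- stats::setNames(lapply(unique(strata), function(s)
    suppressWarnings(adjacency_probability(
      surv[strata == s], vocab, config$adjacency_window,
      config$adjacency_circular))), unique(strata))

  assoc <- hmrg_conjugation_association(nonviral, vocab, classes)
  amgs <- identify_amgs(viral, vocab)
  cooc <- cooccurrence_matrix(surv, vocab)

  summary <- list(
    n_input = length(elements),
    n_after_screen = length(surv),
    n_removed = sum(scr$report$removed),
    class_summary = class_summary,
    host_proportions = hosts,
    hmrg_density = dens,
    size_stats = sizes$by_stratum,
    welch_length_p = if (!is.null(sizes$welch)) sizes$welch$p else NA,
    adjacency = lapply(adjacency, function(x) if (is.na(x)) NULL else x),
    conjugation = list(p = assoc$p,
                       fraction_hmrg_on_conjugative =
                         assoc$fraction_hmrg_on_conjugative,
                       n_conjugative = assoc$n_conjugative),
    n_amg_candidates = nrow(amgs),
    significant_cogs = if (!is.null(enr))
      enr$gene_name[enr$q < config$fdr_alpha] else character(),
    config = unclass(config),
    vocab_checksums = as.list(tools::md5sum(vocab$source_files)))

  tables <- list(screen_report = scr$report, classes = classes,
                 class_summary = class_summary, hosts = hosts,
                 enrichment = enr, densities = dens, conjugation = assoc,
                 amgs = amgs, cooccurrence = cooc)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    wt <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    wt(scr$report, "screen_report"); wt(classes, "classes")
    wt(class_summary, "class_summary"); wt(hosts, "hosts")
    wt(enr, "enrichment"); wt(dens, "densities"); wt(amgs, "amgs")
    utils::write.table(cooc, file.path(outdir, "cooccurrence.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  list(summary = summary, tables = tables)
}
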