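#' Classify one circular element
#'
#' Four-tier evidence cascade; exactly one tier fires:
#' 1. **viral** -- confident viral category (1, 2, 4 or 5); low-confidence
#'    categories 3 and 6 are discarded as evidence.
#' 2. **plasmid** -- plasmid-database hit with `mash_pvalue <= 0.1` and
#'    `mash_distance <= 0.1` (inclusive; the thresholds are the search
#'    parameters of the database comparison).
#' 3. **unclassified_mge** -- any gene carries an MGE-associated Pfam.
#' 4. **unclassified_mge** -- any gene carries an extended-library MGE
#'    domain (second-pass screen).
#' 5. otherwise **cryptic**.
#'
#' The viral tier outranks the plasmid tier (the plasmid comparison is run
#' on non-viral elements only). `plasmid_replication_domain` marks elements
#' whose matched Pfams include a plasmid replication-initiation family.
#'
#' @param element A `circular_element`.
#' @param evidence The element's `evidence_bundle` (or `NULL` for none).
#' @param vocab An `mge_vocabulary`.
#' @param mash_max_pvalue,mash_max_distance Plasmid-tier thresholds
#'   (inclusive), default 0.1 each.
#' @return List with `element_id`, `label`, `tier` (one of `virsorter`,
#'   `plsdb`, `pfam_screen`, `extended_domains`, `none`),
#'   `plasmid_replication_domain`, `supporting_ids`.
#' @export
classify_element <- function(element, evidence, vocab,
                             mash_max_pvalue = 0.1, mash_max_distance = 0.1) {
  pfam_hits <- intersect(unique(unlist(element$genes$pfams)), vocab$mge_pfams)
  rep_domain <- length(intersect(pfam_hits, vocab$replication_pfams)) > 0L

  vs <- if (!is.null(evidence)) evidence$virsorter_category else NULL
  if (!is.null(vs) && vs %in% c(1L, 2L, 4L, 5L))
    return(list(element_id = element$element_id, label = "viral",
                tier = "virsorter", plasmid_replication_domain = FALSE,
                supporting_ids = character()))

  hit <- if (!is.null(evidence)) evidence$plsdb_hit else NULL
  if (!is.null(hit) && hit$mash_pvalue <= mash_max_pvalue &&
      hit$mash_distance <= mash_max_distance)
    return(list(element_id = element$element_id, label = "plasmid",
                tier = "plsdb", plasmid_replication_domain = rep_domain,
                supporting_ids = pfam_hits))

  if (length(pfam_hits))
    return(list(element_id = element$element_id, label = "unclassified_mge",
                tier = "pfam_screen", plasmid_replication_domain = rep_domain,
                supporting_ids = pfam_hits))

  domain_hits <- intersect(unique(unlist(element$genes$domains)),
                           vocab$extended_mge_domains)
  if (length(domain_hits))
    return(list(element_id = element$element_id, label = "unclassified_mge",
                tier = "extended_domains",
                plasmid_replication_domain = rep_domain,
                supporting_ids = domain_hits))

  list(element_id = element$element_id, label = "cryptic", tier = "none",
       plasmid_replication_domain = FALSE, supporting_ids = character())
}

#' Classify a set of circular elements
#'
#' @param elements Named list of `circular_element`.
#' @param evidence Named list of `evidence_bundle` keyed by element id;
#'   elements without a bundle are classified on annotation alone.
#' @inheritParams classify_element
#' @return Data frame with one row per element: `element_id`, `label`,
#'   `tier`, `plasmid_replication_domain`, and comma-joined
#'   `supporting_ids`.
#' @export
classify_elements <- function(elements, evidence, vocab,
                              mash_max_pvalue = 0.1, mash_max_distance = 0.1) {
  rows <- lapply(elements, function(e) {
    r <- classify_element(e, evidence[[e$element_id]], vocab,
                          mash_max_pvalue, mash_max_distance)
    data.frame(element_id = r$element_id, label = r$label, tier = r$tier,
               plasmid_replication_domain = r$plasmid_replication_domain,
               supporting_ids = paste(r$supporting_ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stratum class counts and proportions
#'
#' @param classes Classification data frame from [classify_elements()].
#' @param elements The classified elements (supplies the stratum labels).
#' @return Data frame with `stratum`, `label`, `count`, `proportion`;
#'   proportions sum to 1 within each stratum.
#' @export
summarize_classes <- function(classes, elements) {
  missing <- setdiff(element_ids(elements), classes$element_id)
  if (length(missing))
    stop("unclassified element id(s): ", paste(missing, collapse = ", "))
  strata <- element_strata(elements)
  lab <- stats::setNames(classes$label, classes$element_id)
  ids <- element_ids(elements)
  tab <- table(stratum = strata[ids], label = factor(lab[ids],
               levels = c("viral", "plasmid", "unclassified_mge", "cryptic")))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3L] <- "count"
  totals <- stats::setNames(rowSums(tab), rownames(tab))
  out$proportion <- out$count / totals[out$stratum]
  out <- out[order(out$stratum, out$label), ]
  rownames(out) <- NULL
  out
}
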