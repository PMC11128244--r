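#' Host call by gene-taxonomy majority vote
#'
#' For a non-viral element, tallies the taxonomic assignments of its CDS at
#' the requested level and assigns the modal taxon iff its count strictly
#' exceeds half the denominator (">50% of CDS"); otherwise the element is
#' unassigned. With `denominator = "all"` (default) unannotated genes count
#' in the denominator, a conservative reading that matches the high
#' unassigned rates seen in environmental data; `"annotated"` restricts the
#' denominator to genes with a taxonomy at that level. Ties (two taxa at
#' exactly half) are unassigned. Phylum and class level votes are computed
#' independently.
#'
#' @param element A non-viral `circular_element`.
#' @param level `"phylum"` or `"class"`.
#' @param denominator `"all"` CDS or `"annotated"` CDS only.
#' @return List with `element_id`, `level`, `taxon` (`NA` when unassigned),
#'   `vote_fraction` (winning-taxon count over the denominator),
#'   `n_genes_total`, `n_genes_annotated`.
#' @export
vote_taxonomy <- function(element, level = c("phylum", "class"),
                          denominator = c("all", "annotated")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  tax <- if (level == "phylum") element$genes$tax_phylum else element$genes$tax_class
  n_total <- length(tax)
  n_annot <- sum(!is.na(tax))
  denom <- if (denominator == "all") n_total else n_annot
  out <- list(element_id = element$element_id, level = level,
              taxon = NA_character_, vote_fraction = 0,
              n_genes_total = n_total, n_genes_annotated = n_annot)
  if (n_total == 0L || n_annot == 0L || denom == 0L) return(out)
  counts <- sort(table(tax[!is.na(tax)]), decreasing = TRUE)
  if (counts[1L] > denom / 2) {
    out$taxon <- names(counts)[1L]
    out$vote_fraction <- unname(counts[1L]) / denom
  } else {
    out$vote_fraction <- unname(counts[1L]) / denom
  }
  out
}

#' CRISPR-spacer host taxa for a viral element
#'
#' Retains spacer hits with at most `max_mismatches` mismatches (the 0-or-1
#' mismatch filter by default) and deduplicates by source taxon, preserving
#' first-hit order.
#'
#' @param evidence An `evidence_bundle`.
#' @param max_mismatches Maximum mismatches allowed (default 1).
#' @return Character vector of source taxa (possibly empty).
#' @export
crispr_host <- function(evidence, max_mismatches = 1L) {
  hits <- evidence$crispr_hits
  if (is.null(hits) || nrow(hits) == 0L) return(character())
  unique(hits$taxon[hits$mismatches <= max_mismatches])
}

#' Host calls for all non-viral elements
#'
#' @param elements Named list of `circular_element`.
#' @param classes Classification data frame ([classify_elements()]).
#' @param level,denominator Passed to [vote_taxonomy()].
#' @param evidence Optional evidence list; when given, adds a
#'   `plsdb_host_consistent` column comparing the vote result with the
#'   plasmid-database host metadata (string-normalized, phylum level).
#' @return Data frame of host calls, one row per non-viral element.
#' @export
host_calls <- function(elements, classes, level = "phylum",
                       denominator = "all", evidence = NULL) {
  lab <- stats::setNames(classes$label, classes$element_id)
  nonviral <- elements[lab[element_ids(elements)] != "viral"]
  rows <- lapply(nonviral, function(e) {
    v <- vote_taxonomy(e, level, denominator)
    consistent <- NA
    if (!is.null(evidence)) {
      hit <- evidence[[e$element_id]]$plsdb_hit
      if (!is.null(hit) && !is.na(hit$host_metadata) && !is.na(v$taxon))
        consistent <- tolower(trimws(hit$host_metadata)) ==
          tolower(trimws(v$taxon))
    }
    data.frame(element_id = v$element_id, level = v$level,
               taxon = ifelse(is.na(v$taxon), "unassigned", v$taxon),
               vote_fraction = v$vote_fraction,
               n_genes_total = v$n_genes_total,
               n_genes_annotated = v$n_genes_annotated,
               plsdb_host_consistent = consistent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(), level = character(),
                      taxon = character(), vote_fraction = numeric(),
                      n_genes_total = integer(), n_genes_annotated = integer(),
                      plsdb_host_consistent = logical())
  rownames(out) <- NULL
  out
}

#' Per-stratum host-phylum proportions
#'
#' Viral and non-viral elements are tallied separately: viral hosts come
#' from the k-mer predictor (`php_phylum` evidence), non-viral hosts from
#' the gene-taxonomy majority vote. Proportions are normalized against the
#' total number of elements of that group in each stratum; `unassigned` is
#' a reported category.
#'
#' @param elements Named list of `circular_element`.
#' @param classes Classification data frame.
#' @param evidence Named list of `evidence_bundle`.
#' @param level,denominator Passed to [vote_taxonomy()].
#' @return Data frame: `stratum`, `group` (viral/non_viral), `taxon`,
#'   `count`, `proportion`.
#' @export
host_summary <- function(elements, classes, evidence, level = "phylum",
                         denominator = "all") {
  lab <- stats::setNames(classes$label, classes$element_id)
  ids <- element_ids(elements)
  if (anyDuplicated(ids))
    stop("element id(s) present more than once: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  strata <- element_strata(elements)
  is_viral <- lab[ids] == "viral"

  taxon <- character(length(ids)); names(taxon) <- ids
  for (id in ids[is_viral]) {
    php <- evidence[[id]]$php_phylum
    taxon[id] <- if (is.null(php)) "unassigned" else php
  }
  calls <- host_calls(elements[!is_viral], classes, level, denominator)
  taxon[calls$element_id] <- calls$taxon

  group <- ifelse(is_viral, "viral", "non_viral")
  rows <- list()
  for (s in unique(strata)) for (g in c("viral", "non_viral")) {
    sel <- strata == s & group == g
    if (!any(sel)) next
    tab <- table(taxon[ids[sel]])
    rows[[paste(s, g)]] <- data.frame(
      stratum = s, group = g, taxon = names(tab),
      count = as.integer(tab), proportion = as.numeric(tab) / sum(sel),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
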