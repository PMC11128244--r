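#' Construct a circular element
#'
#' A circular element is one circularized DNA molecule recovered from a
#' metagenome assembly graph: a putative mobile genetic element (plasmid,
#' phage, ICE, or cryptic circle). Topology is always circular; gene
#' coordinates are 1-based inclusive and a gene spanning the origin has
#' `end > length_bp`, interpreted modulo the element length.
#'
#' @param element_id Unique element identifier.
#' @param sample_id Identifier of the source sample.
#' @param stratum Contamination stratum of the source site, `"high_U"` or
#'   `"low_U"` (split at uranium 0.126 uM in the groundwater).
#' @param length_bp Element length in bp (>= 200).
#' @param genes Data frame of gene features (see [gene_table()]); one row per
#'   CDS, ordered by `orf_index`.
#' @param sequence Optional nucleotide sequence over A/C/G/T/N whose length
#'   must equal `length_bp`; `NA` when unavailable.
#' @return An object of class `circular_element`.
#' @export
circular_element <- function(element_id, sample_id, stratum, length_bp,
                             genes = gene_table(), sequence = NA_character_) {
  stopifnot(is.character(element_id), length(element_id) == 1L, nzchar(element_id))
  stratum <- match.arg(stratum, c("high_U", "low_U"))
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp < 200L)
    stop("element '", element_id, "': length_bp must be an integer >= 200")
  genes <- validate_gene_table(genes, element_id)
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length_bp)
      stop("element '", element_id, "': sequence length (", nchar(sequence),
           ") != length_bp (", length_bp, ")")
    if (grepl("[^ACGTN]", sequence))
      stop("element '", element_id, "': sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(element_id = element_id, sample_id = sample_id, stratum = stratum,
         length_bp = length_bp, sequence = sequence, genes = genes),
    class = "circular_element"
  )
}

#' Construct a gene feature table
#'
#' One row per CDS. `cogs`, `pfams` and `domains` are list columns of
#' character vectors (COG ids, Pfam ids, and ids from extended domain
#' libraries such as CDD/TIGRFAM/SMART/PGAP). `tax_phylum`/`tax_class` hold
#' the taxonomic lineage of the best annotation hit (`NA` when the gene is
#' unannotated at that level).
#'
#' @param gene_id,orf_index,start,end,strand,product Per-gene vectors.
#' @param cogs,pfams,domains Lists of character vectors (or a single
#'   character vector recycled per gene).
#' @param tax_phylum,tax_class Character vectors, `NA` for unannotated.
#' @return A data frame with class `gene_table`.
#' @export
gene_table <- function(gene_id = character(), orf_index = integer(),
                       start = integer(), end = integer(),
                       strand = character(), cogs = list(), pfams = list(),
                       domains = list(), tax_phylum = NA_character_,
                       tax_class = NA_character_, product = NA_character_) {
  n <- length(gene_id)
  as_idlist <- function(x) {
    if (n == 0L) return(list())
    if (!is.list(x)) x <- list(as.character(x))
    x <- rep_len(x, n)
    lapply(x, function(v) as.character(v[!is.na(v) & nzchar(v)]))
  }
  df <- data.frame(
    gene_id = as.character(gene_id),
    orf_index = as.integer(orf_index),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    tax_phylum = rep_len(as.character(tax_phylum), n),
    tax_class = rep_len(as.character(tax_class), n),
    product = rep_len(as.character(product), n),
    stringsAsFactors = FALSE
  )
  df$cogs <- as_idlist(cogs)
  df$pfams <- as_idlist(pfams)
  df$domains <- as_idlist(domains)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(genes, element_id = "?") {
  required <- c("gene_id", "orf_index", "start", "end", "strand",
                "tax_phylum", "tax_class", "product", "cogs", "pfams", "domains")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    stop("element '", element_id, "': gene table lacks columns: ",
         paste(missing, collapse = ", "))
  n <- nrow(genes)
  if (n == 0L) return(genes)
  if (anyNA(genes$orf_index) || anyNA(genes$start) || anyNA(genes$end))
    stop("element '", element_id, "': non-integer orf_index/start/end")
  if (anyDuplicated(genes$orf_index)) {
    dup <- genes$orf_index[duplicated(genes$orf_index)][1L]
    stop("element '", element_id, "': duplicate orf_index ", dup)
  }
  genes <- genes[order(genes$orf_index), , drop = FALSE]
  rownames(genes) <- NULL
  if (!identical(as.integer(genes$orf_index), 0:(n - 1L)))
    stop("element '", element_id, "': orf_index values must be consecutive 0..",
         n - 1L)
  if (any(genes$start < 1L) || any(genes$start > genes$end))
    stop("element '", element_id, "': require 1 <= start <= end for every gene")
  if (!all(genes$strand %in% c("+", "-")))
    stop("element '", element_id, "': strand must be '+' or '-'")
  genes
}

#' @export
print.circular_element <- function(x, ...) {
  cat(sprintf("<circular_element> %s  [%s, %s]  %d bp, %d genes, sequence: %s\n",
              x$element_id, x$sample_id, x$stratum, x$length_bp, nrow(x$genes),
              if (is.na(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Number of genes on an element
#' @param element A `circular_element`.
#' @return Integer gene count.
#' @export
n_genes <- function(element) nrow(element$genes)

#' Stratum labels of a set of elements
#' @param elements A list of `circular_element` objects.
#' @return Character vector of strata, named by element id.
#' @export
element_strata <- function(elements) {
  vapply(elements, function(e) e$stratum, character(1),
         USE.NAMES = FALSE) |> stats::setNames(element_ids(elements))
}

#' @rdname element_strata
#' @export
element_ids <- function(elements) {
  vapply(elements, function(e) e$element_id, character(1), USE.NAMES = FALSE)
}

#' Element lengths in bp
#' @inheritParams element_strata
#' @return Integer vector named by element id.
#' @export
element_lengths <- function(elements) {
  vapply(elements, function(e) e$length_bp, integer(1),
         USE.NAMES = FALSE) |> stats::setNames(element_ids(elements))
}

#' Construct an external-evidence bundle for one element
#'
#' Collects the per-element outputs of upstream external tools, consumed as
#' precomputed inputs: the viral-prediction category (1-6; categories 3 and 6
#' are low-confidence), the best plasmid-database hit with its mash distance
#' and p-value, CRISPR-spacer matches with mismatch counts, a k-mer-based
#' host-phylum prediction, and a predicted phage lifestyle.
#'
#' @param element_id Element identifier.
#' @param virsorter_category Integer in 1..6, or `NULL` when no viral
#'   prediction exists.
#' @param plsdb_hit `NULL`, or a list with `accession`, `mash_distance`
#'   (in \[0,1\]), `mash_pvalue` (in \[0,1\]) and `host_metadata`.
#' @param crispr_hits Data frame with columns `taxon`, `mismatches`.
#' @param php_phylum Predicted host phylum (k-mer method), or `NULL`.
#' @param lifestyle `"temperate"`, `"virulent"`, or `NULL`.
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(element_id, virsorter_category = NULL,
                            plsdb_hit = NULL,
                            crispr_hits = data.frame(taxon = character(),
                                                     mismatches = integer()),
                            php_phylum = NULL, lifestyle = NULL) {
  if (!is.null(virsorter_category)) {
    virsorter_category <- as.integer(virsorter_category)
    if (!virsorter_category %in% 1:6)
      stop("evidence for '", element_id, "': virsorter_category must be in 1..6")
  }
  if (!is.null(plsdb_hit)) {
    need <- c("accession", "mash_distance", "mash_pvalue", "host_metadata")
    if (!all(need %in% names(plsdb_hit)))
      stop("evidence for '", element_id, "': incomplete plsdb_hit (need ",
           paste(need, collapse = ", "), ")")
    d <- plsdb_hit$mash_distance; p <- plsdb_hit$mash_pvalue
    if (is.na(d) || d < 0 || d > 1)
      stop("evidence for '", element_id, "': mash_distance outside [0,1]")
    if (is.na(p) || p < 0 || p > 1)
      stop("evidence for '", element_id, "': mash_pvalue outside [0,1]")
  }
  if (nrow(crispr_hits) && any(crispr_hits$mismatches < 0))
    stop("evidence for '", element_id, "': negative CRISPR mismatch count")
  if (!is.null(lifestyle))
    lifestyle <- match.arg(lifestyle, c("temperate", "virulent"))
  structure(
    list(element_id = element_id, virsorter_category = virsorter_category,
         plsdb_hit = plsdb_hit, crispr_hits = crispr_hits,
         php_phylum = php_phylum, lifestyle = lifestyle),
    class = "evidence_bundle"
  )
}

#' Map a uranium concentration to a contamination stratum
#'
#' Sites are split at the drinking-water maximum contaminant level for
#' uranium: \[U\] > 0.126 uM marks the highly contaminated stratum.
#'
#' @param u_um Uranium concentration(s) in micromolar.
#' @param threshold_um Stratum threshold, default 0.126 uM.
#' @return Character vector `"high_U"`/`"low_U"`.
#' @export
stratum_from_uranium <- function(u_um, threshold_um = 0.126) {
  ifelse(u_um > threshold_um, "high_U", "low_U")
}

#' Class labels for circular elements
#'
#' The five possible end states of the screening + classification workflow.
#' @return Character vector of valid labels.
#' @export
class_labels <- function() {
  c("removed_false_positive", "viral", "plasmid", "unclassified_mge", "cryptic")
}
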