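#' Screen genes for curated resistance / conjugation COGs
#'
#' Scans every gene of every element for COGs in the requested curated
#' category. A gene annotated with two matching COGs yields two hits. Output
#' order is deterministic (element order, then orf order, then COG id).
#'
#' @param elements Named list of `circular_element` (caller chooses the
#'   subset, e.g. non-viral elements only).
#' @param vocab An `mge_vocabulary`.
#' @param category `"HMRG"`, `"ARG"` or `"CONJ"`.
#' @return Data frame of gene hits: `element_id`, `orf_index`, `cog_id`,
#'   `category`, `gene_name`, `metals` (comma-joined, HMRG only).
#' @export
screen_genes <- function(elements, vocab, category = c("HMRG", "ARG", "CONJ")) {
  category <- match.arg(category)
  wanted <- switch(category, HMRG = names(vocab$hmrg_cogs),
                   ARG = vocab$arg_cogs, CONJ = vocab$conj_cogs)
  rows <- lapply(elements, function(e) {
    g <- e$genes
    hit_list <- lapply(seq_len(nrow(g)), function(i)
      sort(intersect(g$cogs[[i]], wanted)))
    n_hit <- lengths(hit_list)
    if (!sum(n_hit)) return(NULL)
    data.frame(element_id = e$element_id,
               orf_index = rep(g$orf_index, n_hit),
               cog_id = unlist(hit_list), category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(), orf_index = integer(),
                      cog_id = character(), category = character())
  out$gene_name <- if (category == "HMRG")
    unname(hmrg_gene_names(vocab, out$cog_id)) else out$cog_id
  out$metals <- if (category == "HMRG" && nrow(out))
    vapply(vocab$hmrg_cogs[out$cog_id], paste, character(1), collapse = ",")
  else character(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-stratum gene-hit densities
#'
#' Normalizes hit counts two ways: per million base pairs of element
#' sequence, and as a fraction of the total CDS count. Run on the
#' dereplicated element set.
#'
#' @param elements Named list of `circular_element` (both strata).
#' @param hits Gene-hit data frame from [screen_genes()].
#' @return Data frame: `stratum`, `n_hits`, `total_bp`, `total_cds`,
#'   `per_mbp`, `per_cds_fraction`.
#' @export
stratum_density <- function(elements, hits) {
  strata <- element_strata(elements)
  hit_stratum <- strata[hits$element_id]
  rows <- lapply(unique(strata), function(s) {
    sub <- elements[strata == s]
    nh <- sum(hit_stratum == s)
    bp <- sum(as.numeric(element_lengths(sub)))
    cds <- sum(vapply(sub, n_genes, integer(1)))
    data.frame(stratum = s, n_hits = nh, total_bp = bp, total_cds = cds,
               per_mbp = if (bp > 0) 1e6 * nh / bp else 0,
               per_cds_fraction = if (cds > 0) nh / cds else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-COG enrichment between contamination strata
#'
#' For every COG in the requested curated category, builds the 2x2 table
#' (hits vs other CDS, high vs low stratum), computes the two-tailed Fisher
#' exact p-value on absolute gene counts, and applies Benjamini-Hochberg
#' correction across all COGs of the category. `include_cryptic = FALSE`
#' reruns the comparison on the element set with cryptic elements removed
#' (the conservative variant).
#'
#' @param elements Named list of classified `circular_element` (both strata).
#' @param vocab An `mge_vocabulary`.
#' @param category `"HMRG"` or `"ARG"`.
#' @param include_cryptic Keep cryptic elements in the comparison (default
#'   `TRUE`).
#' @param classes Classification data frame; required when
#'   `include_cryptic = FALSE`.
#' @return Data frame, one row per COG: `cog_id`, `gene_name`,
#'   `count_high`, `count_low`, `total_cds_high`, `total_cds_low`,
#'   `odds_ratio`, `p`, `q`.
#' @export
enrichment_table <- function(elements, vocab, category = c("HMRG", "ARG"),
                             include_cryptic = TRUE, classes = NULL) {
  category <- match.arg(category)
  if (!include_cryptic) {
    if (is.null(classes))
      stop("classes required when include_cryptic = FALSE")
    lab <- stats::setNames(classes$label, classes$element_id)
    elements <- elements[lab[element_ids(elements)] != "cryptic"]
  }
  strata <- element_strata(elements)
  if (!all(c("high_U", "low_U") %in% strata))
    stop("both strata must be non-empty")
  total_cds <- vapply(split(vapply(elements, n_genes, integer(1)), strata),
                      sum, numeric(1))
  hits <- screen_genes(elements, vocab, category)
  hit_stratum <- strata[hits$element_id]
  wanted <- switch(category, HMRG = names(vocab$hmrg_cogs), ARG = vocab$arg_cogs)
  rows <- lapply(wanted, function(cog) {
    ch <- sum(hits$cog_id == cog & hit_stratum == "high_U")
    cl <- sum(hits$cog_id == cog & hit_stratum == "low_U")
    a <- ch; b <- total_cds[["high_U"]] - ch
    c <- cl; d <- total_cds[["low_U"]] - cl
    p <- if (ch + cl == 0) 1 else fisher_exact_two_tailed(a, b, c, d)
    data.frame(cog_id = cog,
               gene_name = if (category == "HMRG")
                 unname(hmrg_gene_names(vocab, cog)) else cog,
               count_high = ch, count_low = cl,
               total_cds_high = total_cds[["high_U"]],
               total_cds_low = total_cds[["low_U"]],
               odds_ratio = sample_odds_ratio(a, b, c, d), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' HMRG neighborhood clustering probability
#'
#' The probability that an individual HMRG gene lies within `window` ORFs of
#' another HMRG gene on its (circular) element: over all HMRG gene hits in
#' the set, the fraction with at least one other HMRG-carrying gene at
#' circular ordinal distance <= `window` (minimum of the clockwise and
#' counterclockwise ORF difference). A gene carrying two HMRG COGs is one
#' gene and is not self-adjacent.
#'
#' @param elements Named list of `circular_element`.
#' @param vocab An `mge_vocabulary`.
#' @param window Maximum ORF distance (default 4).
#' @param circular Honor the circular topology (default `TRUE`; `FALSE`
#'   treats the gene order as linear for sensitivity analysis).
#' @param per_element_mean Pool genes across all elements (default) or
#'   average per-element probabilities.
#' @return Probability in \[0, 1\]; `NA` (with a warning) when the set
#'   contains no HMRG gene, which is distinct from an observed 0.
#' @export
adjacency_probability <- function(elements, vocab, window = 4L,
                                  circular = TRUE, per_element_mean = FALSE) {
  hits <- screen_genes(elements, vocab, "HMRG")
  if (nrow(hits) == 0L) {
    warning("no HMRG genes in the element set; adjacency undefined")
    return(NA_real_)
  }
  per_gene <- function(e) {
    orfs <- sort(unique(hits$orf_index[hits$element_id == e$element_id]))
    if (!length(orfs)) return(logical())
    n <- n_genes(e)
    vapply(orfs, function(o) {
      others <- setdiff(orfs, o)
      if (!length(others)) return(FALSE)
      d <- abs(others - o)
      if (circular) d <- pmin(d, n - d)
      any(d <= window)
    }, logical(1))
  }
  flags <- lapply(elements[unique(hits$element_id)], per_gene)
  if (per_element_mean) {
    means <- vapply(flags, mean, numeric(1))
    mean(means)
  } else {
    mean(unlist(flags))
  }
}

#' HMRG co-occurrence matrix
#'
#' Symmetric matrix over canonical HMRG gene names; entry (g1, g2) counts
#' the elements carrying at least one hit of each gene, the diagonal counts
#' elements carrying the gene.
#'
#' @param elements Named list of `circular_element`.
#' @param vocab An `mge_vocabulary`.
#' @return Integer matrix with dimnames set to HMRG gene names.
#' @export
cooccurrence_matrix <- function(elements, vocab) {
  genes <- unname(hmrg_gene_names(vocab))
  hits <- screen_genes(elements, vocab, "HMRG")
  m <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  for (id in unique(hits$element_id)) {
    present <- unique(hits$gene_name[hits$element_id == id])
    m[present, present] <- m[present, present] + 1L
  }
  m
}

#' Is an element conjugative?
#'
#' TRUE iff at least one gene carries a conjugal-transfer-system COG.
#' Conjugative elements (self-transmissible plasmids and ICEs) encode their
#' own transfer machinery; viral elements are outside this notion and are
#' rejected.
#'
#' @param element A non-viral `circular_element`.
#' @param vocab An `mge_vocabulary`.
#' @param classes Optional classification data frame used to enforce the
#'   non-viral precondition.
#' @return Logical.
#' @export
conjugative_flag <- function(element, vocab, classes = NULL) {
  if (!is.null(classes)) {
    lab <- classes$label[classes$element_id == element$element_id]
    if (length(lab) && lab == "viral")
      stop("conjugative_flag() is undefined for viral element '",
           element$element_id, "'")
  }
  any(unlist(element$genes$cogs) %in% vocab$conj_cogs)
}

#' Association between HMRG carriage and conjugative elements
#'
#' Element-level 2x2 table (rows: conjugative yes/no; columns: carries >= 1
#' HMRG yes/no) over non-viral elements, with the two-tailed Fisher exact
#' p-value, plus the fraction of HMRG gene hits located on conjugative
#' elements. Viral elements must be excluded by the caller (enforced when
#' `classes` is supplied).
#'
#' @param elements Named list of non-viral `circular_element`.
#' @param vocab An `mge_vocabulary`.
#' @param classes Optional classification data frame for the viral check.
#' @return List with `table` (2x2 matrix), `p`,
#'   `fraction_hmrg_on_conjugative`, `n_conjugative`.
#' @export
hmrg_conjugation_association <- function(elements, vocab, classes = NULL) {
  if (!is.null(classes)) {
    lab <- stats::setNames(classes$label, classes$element_id)
    viral <- element_ids(elements)[lab[element_ids(elements)] == "viral"]
    if (length(viral))
      stop("viral element(s) must be excluded: ", paste(viral, collapse = ", "))
  }
  conj <- vapply(elements, conjugative_flag, logical(1), vocab = vocab)
  hits <- screen_genes(elements, vocab, "HMRG")
  has_hmrg <- element_ids(elements) %in% hits$element_id
  tab <- matrix(c(sum(conj & has_hmrg), sum(conj & !has_hmrg),
                  sum(!conj & has_hmrg), sum(!conj & !has_hmrg)),
                nrow = 2, byrow = TRUE,
                dimnames = list(conjugative = c("yes", "no"),
                                hmrg = c("yes", "no")))
  p <- if (sum(tab) == 0) NA_real_
  else fisher_exact_two_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  frac <- if (nrow(hits)) {
    on_conj <- conj[hits$element_id]
    mean(on_conj)
  } else NA_real_
  list(table = tab, p = p, fraction_hmrg_on_conjugative = frac,
       n_conjugative = sum(conj))
}

#' Candidate auxiliary metabolic genes on viral elements
#'
#' Reports genes on viral elements that carry a functional annotation (a
#' product other than a hypothetical protein, or at least one COG) and whose
#' product does not match any viral replication/structure/function keyword.
#' Genes carrying an HMRG-category COG are flagged as metal-related.
#'
#' @param elements Named list of viral `circular_element`.
#' @param vocab An `mge_vocabulary`.
#' @return Data frame: `element_id`, `gene_id`, `product`, `cogs`
#'   (comma-joined), `metal_related`.
#' @export
identify_amgs <- function(elements, vocab) {
  pat <- paste(tolower(vocab$viral_function_keywords), collapse = "|")
  rows <- lapply(elements, function(e) {
    g <- e$genes
    product <- ifelse(is.na(g$product), "", g$product)
    annotated <- nzchar(product) &
      !grepl("hypothetical", product, ignore.case = TRUE) |
      lengths(g$cogs) > 0L
    viral_fun <- grepl(pat, tolower(product))
    keep <- annotated & !viral_fun
    if (!any(keep)) return(NULL)
    data.frame(element_id = e$element_id, gene_id = g$gene_id[keep],
               product = g$product[keep],
               cogs = vapply(g$cogs[keep], paste, character(1), collapse = ","),
               metal_related = vapply(g$cogs[keep], function(v)
                 any(v %in% names(vocab$hmrg_cogs)), logical(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(), gene_id = character(),
                      product = character(), cogs = character(),
                      metal_related = logical())
  rownames(out) <- NULL
  out
}

#' Per-stratum element size statistics
#'
#' Arithmetic mean length, counts above strict size thresholds, and the
#' two-sided Welch t-test between the strata. Run on the dereplicated set.
#'
#' @param elements Named list of `circular_element` (both strata).
#' @param thresholds Strict (>) size thresholds in bp.
#' @return List with `by_stratum` (data frame: `stratum`, `n`,
#'   `mean_length`, one `count_gt_<threshold>` column per threshold) and
#'   `welch` (list `t`, `df`, `p`, or `NULL` when a stratum has < 2
#'   elements).
#' @export
size_stats <- function(elements, thresholds = c(20000, 100000)) {
  strata <- element_strata(elements)
  lens <- element_lengths(elements)
  rows <- lapply(unique(strata), function(s) {
    l <- lens[strata == s]
    row <- data.frame(stratum = s, n = length(l), mean_length = mean(l))
    for (th in thresholds)
      row[[paste0("count_gt_", format(th, scientific = FALSE))]] <- sum(l > th)
    row
  })
  by_stratum <- do.call(rbind, rows)
  rownames(by_stratum) <- NULL
  welch <- NULL
  if (all(c("high_U", "low_U") %in% strata) &&
      sum(strata == "high_U") >= 2L && sum(strata == "low_U") >= 2L)
    welch <- welch_t_two_sided(lens[strata == "high_U"], lens[strata == "low_U"])
  list(by_stratum = by_stratum, welch = welch)
}
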