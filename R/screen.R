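#' Detect organellar false positives
#'
#' Circularized fragments of mitochondrial/chloroplast genomes show up in
#' metagenome assemblies as spurious "circular elements". An element is
#' flagged when at least half of its genes match organelle keyword tokens in
#' their product text or taxonomic lineage (case-insensitive substring
#' match; the 0.5 threshold is inclusive).
#'
#' @param element A `circular_element`.
#' @param vocab An `mge_vocabulary` supplying `organelle_keywords`.
#' @param min_fraction Flagging threshold on the matching-gene fraction
#'   (default 0.5, inclusive).
#' @return Logical; `FALSE` for an element without genes.
#' @export
detect_organelle <- function(element, vocab, min_fraction = 0.5) {
  g <- element$genes
  if (nrow(g) == 0L) return(FALSE)
  hay <- tolower(paste(ifelse(is.na(g$product), "", g$product),
                       ifelse(is.na(g$tax_phylum), "", g$tax_phylum),
                       ifelse(is.na(g$tax_class), "", g$tax_class)))
  pat <- paste(tolower(vocab$organelle_keywords), collapse = "|")
  mean(grepl(pat, hay, fixed = FALSE)) >= min_fraction
}

#' Detect tandem-repeat circularization artifacts
#'
#' A long repeat region traversed several times by the assembler can be
#' emitted as a spurious circle consisting of k whole tandem copies of one
#' unit. The test checks every divisor k >= 2 of the sequence length and
#' flags the sequence when all copies of the length/k unit agree with the
#' first copy at >= `min_identity` positions. Rotation of the circle does
#' not affect the decision (a rotated tandem array is still a tandem array).
#'
#' @param sequence Nucleotide string (length >= 200).
#' @param min_identity Per-copy identity threshold (default 0.95).
#' @return Logical. An absent (`NA`) sequence signals "cannot screen" by
#'   returning `NA`.
#' @export
detect_tandem_repeat_artifact <- function(sequence, min_identity = 0.95) {
  if (is.na(sequence)) return(NA)
  n <- nchar(sequence)
  if (n < 200L) stop("sequence shorter than 200 bp")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  divisors <- which(n %% seq_len(n) == 0L)
  ks <- divisors[divisors >= 2L]
  for (k in ks) {
    unit <- n %/% k
    m <- matrix(chars, nrow = unit)          # one copy per column
    ident <- colMeans(m == m[, 1L])
    if (all(ident >= min_identity)) return(TRUE)
  }
  FALSE
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# lexicographically least rotation of min(seq, revcomp): canonical circular form
canonical_circular_form <- function(seq) {
  least_rotation <- function(s) {
    n <- nchar(s)
    doubled <- paste0(s, s)
    min(substring(doubled, seq_len(n), seq_len(n) + n - 1L))
  }
  min(least_rotation(seq), least_rotation(revcomp(seq)))
}

# rotation/orientation-invariant local alignment of the shorter sequence
# against the doubled longer one; returns identity over the aligned region
# and the aligned fraction (coverage) of the shorter sequence
circular_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  doubled <- Biostrings::DNAString(paste0(b, b))
  best <- list(identity = 0, coverage = 0)
  for (query in c(a, revcomp(a))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), doubled, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    w <- Biostrings::width(Biostrings::pattern(aln))
    if (w == 0) next
    cand <- list(identity = Biostrings::nmatch(aln) / w,
                 coverage = w / nchar(a))
    if (cand$identity * cand$coverage > best$identity * best$coverage)
      best <- cand
  }
  best
}

# orientation/rotation-canonical gene-content fingerprint, used when
# sequences are unavailable
annotation_fingerprint <- function(element) {
  g <- element$genes
  per_gene <- vapply(seq_len(nrow(g)), function(i) {
    paste(paste(sort(g$cogs[[i]]), collapse = "+"),
          paste(sort(g$pfams[[i]]), collapse = "+"), sep = "|")
  }, character(1))
  canon <- function(v) {
    n <- length(v)
    rots <- vapply(seq_len(n), function(i)
      paste(v[((seq_len(n) + i - 2L) %% n) + 1L], collapse = ";"), character(1))
    min(rots)
  }
  if (length(per_gene) == 0L) return("")
  min(canon(per_gene), canon(rev(per_gene)))
}

#' Dereplicate circular elements within one stratum
#'
#' Greedy longest-first clustering: an element joins an existing
#' representative when its rotation- and reverse-complement-invariant
#' nucleotide identity to the representative is at least `identity` over at
#' least `coverage` of the shorter sequence. When either sequence is absent
#' the comparison falls back to exact equality of the rotation-canonical
#' ordered COG/Pfam fingerprint. Representatives are the longest member of
#' each cluster; processing order (length descending, then element id) makes
#' the result independent of input order.
#'
#' @param elements Named list of `circular_element`, all from one stratum.
#' @param identity Nucleotide identity threshold (default 0.99).
#' @param coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.90).
#' @return List with `representatives` (named list of elements) and
#'   `report` (data frame: `element_id`, `removed`, `reason`,
#'   `cluster_representative`).
#' @export
dereplicate <- function(elements, identity = 0.99, coverage = 0.90) {
  if (length(elements) == 0L)
    return(list(representatives = elements,
                report = data.frame(element_id = character(),
                                    removed = logical(), reason = character(),
                                    cluster_representative = character())))
  strata <- unique(element_strata(elements))
  if (length(strata) > 1L)
    stop("dereplicate() requires elements from a single stratum; got: ",
         paste(strata, collapse = ", "))
  ord <- order(-element_lengths(elements), element_ids(elements))
  elements <- elements[ord]

  reps <- list(); rep_fp <- character(); rep_of <- character()
  for (e in elements) {
    assigned <- NA_character_
    fp <- if (is.na(e$sequence)) annotation_fingerprint(e) else NA_character_
    for (r in names(reps)) {
      rep_el <- reps[[r]]
      if (!is.na(e$sequence) && !is.na(rep_el$sequence)) {
        hit <- circular_identity(e$sequence, rep_el$sequence)
        if (hit$identity >= identity && hit$coverage >= coverage) {
          assigned <- r; break
        }
      } else {
        # annotation fallback: identical ordered fingerprint AND a length
        # difference no larger than the identity tolerance allows
        len_ok <- abs(e$length_bp - rep_el$length_bp) <=
          (1 - identity) * rep_el$length_bp
        if (len_ok && identical(fp, rep_fp[[r]]) && nzchar(fp)) {
          assigned <- r; break
        }
      }
    }
    if (is.na(assigned)) {
      reps[[e$element_id]] <- e
      rep_fp[[e$element_id]] <-
        if (is.na(e$sequence)) annotation_fingerprint(e) else NA_character_
      rep_of[[e$element_id]] <- e$element_id
    } else {
      rep_of[[e$element_id]] <- assigned
    }
  }
  ids <- element_ids(elements)
  report <- data.frame(
    element_id = ids,
    removed = rep_of[ids] != ids,
    reason = ifelse(rep_of[ids] != ids, "duplicate", "none"),
    cluster_representative = unname(rep_of[ids]),
    stringsAsFactors = FALSE)
  list(representatives = reps, report = report)
}

#' Screen a set of circular elements
#'
#' Applies the false-positive filters (organellar fragments; tandem-repeat
#' circularization artifacts, where a sequence is available) and then
#' dereplicates the survivors within each contamination stratum. Elements
#' without a sequence pass the repeat filter with a logged warning.
#'
#' @param elements Named list of `circular_element` (both strata allowed).
#' @param vocab An `mge_vocabulary`.
#' @param identity,coverage Dereplication thresholds (see [dereplicate()]).
#' @param organelle_fraction Organelle-gene fraction threshold.
#' @param repeat_identity Tandem-repeat per-copy identity threshold.
#' @return List with `representatives` (elements surviving all filters and
#'   dereplication) and `report` (one row per input element: `element_id`,
#'   `removed`, `reason` in organelle/tandem_repeat_artifact/duplicate/none,
#'   `cluster_representative`).
#' @export
screen_elements <- function(elements, vocab, identity = 0.99, coverage = 0.90,
                            organelle_fraction = 0.5, repeat_identity = 0.95) {
  ids <- element_ids(elements)
  reason <- stats::setNames(rep("none", length(elements)), ids)
  n_unscreened <- 0L
  for (e in elements) {
    if (detect_organelle(e, vocab, organelle_fraction)) {
      reason[e$element_id] <- "organelle"
    } else {
      rep_flag <- detect_tandem_repeat_artifact(e$sequence, repeat_identity)
      if (is.na(rep_flag)) n_unscreened <- n_unscreened + 1L
      else if (rep_flag) reason[e$element_id] <- "tandem_repeat_artifact"
    }
  }
  if (n_unscreened > 0L)
    message(n_unscreened,
            " element(s) without sequence could not be repeat-screened")
  survivors <- elements[reason[ids] == "none"]
  reps <- list()
  rep_of <- stats::setNames(rep(NA_character_, length(elements)), ids)
  for (s in unique(element_strata(survivors))) {
    sub <- survivors[element_strata(survivors) == s]
    der <- dereplicate(sub, identity, coverage)
    reps <- c(reps, der$representatives)
    rep_of[der$report$element_id] <- der$report$cluster_representative
    dup <- der$report$element_id[der$report$removed]
    reason[dup] <- "duplicate"
  }
  report <- data.frame(
    element_id = ids, removed = reason[ids] != "none",
    reason = unname(reason[ids]),
    cluster_representative = unname(rep_of[ids]),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(representatives = reps, report = report)
}
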