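#' Read a gene-level annotation table into circular elements
#'
#' The annotation dialect is a tab-separated file with a header, `#` comment
#' lines, one row per CDS and `-` encoding absent values. Columns:
#' `element_id, sample_id, stratum, element_length, gene_id, orf_index,
#' start, end, strand, cogs, pfams, domains, tax_phylum, tax_class, product`
#' with `cogs`/`pfams`/`domains` comma-joined id lists.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Optional named character vector (e.g. from
#'   [read_fasta()]) attaching nucleotide sequences by element id.
#' @return Named list of [circular_element()] objects, genes ordered by
#'   `orf_index`.
#' @export
read_annotation_table <- function(path, sequences = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("element_id", "sample_id", "stratum", "element_length",
                "gene_id", "orf_index", "start", "end", "strand", "cogs",
                "pfams", "domains", "tax_phylum", "tax_class", "product")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))

  bad <- which(!df$stratum %in% c("high_U", "low_U"))
  if (length(bad))
    stop("unknown stratum token '", df$stratum[bad[1L]], "' (data row ", bad[1L], ")")
  for (col in c("element_length", "orf_index", "start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v != suppressWarnings(as.numeric(df[[col]])))
    if (length(bad))
      stop("non-integer ", col, " '", df[[col]][bad[1L]], "' (data row ", bad[1L], ")")
    df[[col]] <- v
  }
  dup <- which(duplicated(df[, c("element_id", "orf_index")]))
  if (length(dup))
    stop("duplicate orf_index ", df$orf_index[dup[1L]], " for element '",
         df$element_id[dup[1L]], "' (data row ", dup[1L], ")")

  blank_to_na <- function(x) ifelse(x == "-" | x == "", NA_character_, x)
  split_ids <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE), function(v) {
      v <- trimws(v)
      v[nzchar(v) & v != "-"]
    })
  }
  df$tax_phylum <- blank_to_na(df$tax_phylum)
  df$tax_class <- blank_to_na(df$tax_class)
  df$product <- blank_to_na(df$product)

  elements <- lapply(split(seq_len(nrow(df)), factor(df$element_id, levels = unique(df$element_id))),
                     function(idx) {
    sub <- df[idx, , drop = FALSE]
    genes <- gene_table(
      gene_id = sub$gene_id, orf_index = sub$orf_index, start = sub$start,
      end = sub$end, strand = sub$strand, cogs = split_ids(sub$cogs),
      pfams = split_ids(sub$pfams), domains = split_ids(sub$domains),
      tax_phylum = sub$tax_phylum, tax_class = sub$tax_class,
      product = sub$product)
    id <- sub$element_id[1L]
    seq <- if (!is.null(sequences) && id %in% names(sequences))
      sequences[[id]] else NA_character_
    circular_element(id, sub$sample_id[1L], sub$stratum[1L],
                     sub$element_length[1L], genes, seq)
  })
  names(elements) <- vapply(elements, function(e) e$element_id, character(1))
  elements
}

#' Write circular elements to the annotation-table dialect
#'
#' Inverse of [read_annotation_table()] (sequences are written separately
#' with [write_fasta()]).
#'
#' @param elements Named list of `circular_element` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation_table <- function(elements, path) {
  join_ids <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  na_to_dash <- function(x) ifelse(is.na(x), "-", x)
  rows <- lapply(elements, function(e) {
    g <- e$genes
    data.frame(
      element_id = e$element_id, sample_id = e$sample_id, stratum = e$stratum,
      element_length = e$length_bp, gene_id = g$gene_id,
      orf_index = g$orf_index, start = g$start, end = g$end,
      strand = g$strand,
      cogs = vapply(g$cogs, join_ids, character(1)),
      pfams = vapply(g$pfams, join_ids, character(1)),
      domains = vapply(g$domains, join_ids, character(1)),
      tax_phylum = na_to_dash(g$tax_phylum),
      tax_class = na_to_dash(g$tax_class),
      product = na_to_dash(g$product),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external-evidence table
#'
#' TSV with columns `element_id, virsorter_category, plsdb_accession,
#' mash_distance, mash_pvalue, plsdb_host, crispr_hits, php_phylum,
#' lifestyle`; `-` encodes absent values; `crispr_hits` is a semicolon-joined
#' list of `taxon:mismatches` pairs.
#'
#' @param path Path to the evidence TSV.
#' @return Named list of [evidence_bundle()] objects keyed by element id.
#' @export
read_evidence_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("element_id", "virsorter_category", "plsdb_accession",
                "mash_distance", "mash_pvalue", "plsdb_host", "crispr_hits",
                "php_phylum", "lifestyle")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("evidence table lacks columns: ", paste(missing, collapse = ", "))
  absent <- function(x) is.na(x) | x == "-" | x == ""
  bundles <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    vs <- if (absent(row$virsorter_category)) NULL else as.integer(row$virsorter_category)
    plsdb <- NULL
    if (!absent(row$plsdb_accession)) {
      d <- as.numeric(row$mash_distance); p <- as.numeric(row$mash_pvalue)
      if (is.na(d) || is.na(p))
        stop("element '", row$element_id,
             "': plsdb hit requires mash_distance and mash_pvalue together")
      plsdb <- list(accession = row$plsdb_accession, mash_distance = d,
                    mash_pvalue = p,
                    host_metadata = if (absent(row$plsdb_host)) NA_character_
                                    else row$plsdb_host)
    } else if (!absent(row$mash_distance) || !absent(row$mash_pvalue)) {
      stop("element '", row$element_id,
           "': mash fields present without a plsdb accession")
    }
    crispr <- data.frame(taxon = character(), mismatches = integer())
    if (!absent(row$crispr_hits)) {
      parts <- strsplit(row$crispr_hits, ";", fixed = TRUE)[[1L]]
      fields <- strsplit(parts, ":", fixed = TRUE)
      if (any(lengths(fields) != 2L))
        stop("element '", row$element_id, "': malformed crispr_hits '",
             row$crispr_hits, "'")
      crispr <- data.frame(
        taxon = vapply(fields, `[`, character(1), 1L),
        mismatches = as.integer(vapply(fields, `[`, character(1), 2L)),
        stringsAsFactors = FALSE)
    }
    evidence_bundle(
      row$element_id, virsorter_category = vs, plsdb_hit = plsdb,
      crispr_hits = crispr,
      php_phylum = if (absent(row$php_phylum)) NULL else row$php_phylum,
      lifestyle = if (absent(row$lifestyle)) NULL else row$lifestyle)
  })
  names(bundles) <- df$element_id
  bundles
}

#' Write an external-evidence table
#'
#' Inverse of [read_evidence_table()].
#'
#' @param evidence Named list of `evidence_bundle` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_evidence_table <- function(evidence, path) {
  dash <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) "-" else as.character(x)
  rows <- lapply(evidence, function(b) {
    crispr <- if (nrow(b$crispr_hits))
      paste(sprintf("%s:%d", b$crispr_hits$taxon, b$crispr_hits$mismatches),
            collapse = ";") else "-"
    data.frame(
      element_id = b$element_id,
      virsorter_category = dash(b$virsorter_category),
      plsdb_accession = dash(b$plsdb_hit$accession),
      mash_distance = if (is.null(b$plsdb_hit)) "-"
                      else sprintf("%.17g", b$plsdb_hit$mash_distance),
      mash_pvalue = if (is.null(b$plsdb_hit)) "-"
                    else sprintf("%.17g", b$plsdb_hit$mash_pvalue),
      plsdb_host = dash(b$plsdb_hit$host_metadata),
      crispr_hits = crispr,
      php_phylum = dash(b$php_phylum),
      lifestyle = dash(b$lifestyle),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write element sequences to FASTA / read them back
#'
#' Sequences are written 70 columns wide, keyed by element id; elements
#' without a sequence are skipped with a warning giving the skip count. On
#' read, sequences are uppercased; duplicate ids are rejected.
#'
#' @param elements Named list of `circular_element` objects.
#' @param path FASTA path.
#' @return `write_fasta()`: invisibly, the number of records written.
#'   `read_fasta()`: named character vector of uppercase sequences.
#' @export
write_fasta <- function(elements, path) {
  seqs <- vapply(elements, function(e) e$sequence, character(1))
  ids <- element_ids(elements)
  keep <- !is.na(seqs)
  if (any(!keep))
    warning(sum(!keep), " element(s) without sequence skipped")
  if (anyDuplicated(ids[keep]))
    stop("duplicate element id in FASTA output: ",
         ids[keep][duplicated(ids[keep])][1L])
  set <- Biostrings::DNAStringSet(seqs[keep])
  names(set) <- ids[keep]
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(sum(keep))
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate element id in FASTA: ", ids[duplicated(ids)][1L])
  stats::setNames(toupper(as.character(set)), ids)
}
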