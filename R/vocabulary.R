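#' Load the curated gene vocabularies
#'
#' Reads the curated COG/Pfam/domain/keyword lists that drive gene screening
#' and classification: heavy-metal-resistance COGs with the metals each gene
#' confers resistance to, antibiotic-resistance COGs, conjugal-transfer-system
#' COGs, MGE-associated Pfam domains (with the plasmid-replication subset
#' flagged), extended-library domain ids for the second-pass MGE screen, and
#' keyword token lists (viral structural/replication functions; organellar
#' markers). The package ships a default vocabulary under
#' `inst/extdata/vocab/`; pass a directory to override any file.
#'
#' @param dir Directory containing `hmrg_cogs.tsv`, `arg_cogs.tsv`,
#'   `conj_cogs.tsv`, `mge_pfams.tsv`, `extended_mge_domains.tsv`,
#'   `keywords.tsv`. Defaults to the packaged vocabulary.
#' @return An object of class `mge_vocabulary`: a list with entries
#'   `hmrg_cogs` (named list, COG id -> character vector of metal symbols),
#'   `hmrg_gene_names` (named character, COG id -> canonical gene name),
#'   `arg_cogs`, `conj_cogs` (character vectors), `mge_pfams`,
#'   `replication_pfams`, `extended_mge_domains` (character vectors),
#'   `viral_function_keywords`, `organelle_keywords` (character vectors),
#'   and `source_files` (paths used, for provenance).
#' @export
load_vocabulary <- function(dir = system.file("extdata", "vocab",
                                              package = "metamobilome")) {
  read_voc <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("vocabulary file not found: ", path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  hmrg <- read_voc("hmrg_cogs.tsv")
  arg <- read_voc("arg_cogs.tsv")
  conj <- read_voc("conj_cogs.tsv")
  pfam <- read_voc("mge_pfams.tsv")
  ext <- read_voc("extended_mge_domains.tsv")
  kw <- read_voc("keywords.tsv")

  split_ids <- function(x) {
    out <- strsplit(as.character(x), ",", fixed = TRUE)
    lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
  }
  hmrg_cogs <- stats::setNames(split_ids(hmrg$metals), hmrg$cog_id)
  if (anyDuplicated(hmrg$cog_id))
    stop("duplicate COG id in hmrg_cogs.tsv: ",
         hmrg$cog_id[duplicated(hmrg$cog_id)][1L])
  if (any(lengths(hmrg_cogs) == 0L))
    stop("HMRG COG with empty metal set: ",
         names(hmrg_cogs)[lengths(hmrg_cogs) == 0L][1L])
  gene_names <- stats::setNames(
    as.character(hmrg$gene_name %||% hmrg$cog_id), hmrg$cog_id)

  voc <- structure(list(
    hmrg_cogs = hmrg_cogs,
    hmrg_gene_names = gene_names,
    arg_cogs = unique(as.character(arg$cog_id)),
    conj_cogs = unique(as.character(conj$cog_id)),
    mge_pfams = unique(as.character(pfam$pfam_id)),
    replication_pfams = unique(as.character(pfam$pfam_id[pfam$replication == "yes"])),
    extended_mge_domains = unique(as.character(ext$domain_id)),
    viral_function_keywords = as.character(kw$token[kw$type == "viral_function"]),
    organelle_keywords = as.character(kw$token[kw$type == "organelle"]),
    source_files = file.path(dir, c("hmrg_cogs.tsv", "arg_cogs.tsv",
                                    "conj_cogs.tsv", "mge_pfams.tsv",
                                    "extended_mge_domains.tsv", "keywords.tsv"))
  ), class = "mge_vocabulary")
  validate_vocabulary(voc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_vocabulary <- function(voc) {
  overlap <- intersect(names(voc$hmrg_cogs), voc$conj_cogs)
  if (length(overlap))
    stop("COG id in both HMRG and conjugal lists: ", paste(overlap, collapse = ", "))
  overlap <- intersect(voc$arg_cogs, voc$conj_cogs)
  if (length(overlap))
    stop("COG id in both ARG and conjugal lists: ", paste(overlap, collapse = ", "))
  if (!length(voc$mge_pfams)) stop("empty MGE Pfam list")
  extra <- setdiff(voc$replication_pfams, voc$mge_pfams)
  if (length(extra))
    stop("replication Pfams not in MGE Pfam list: ", paste(extra, collapse = ", "))
  voc
}

#' @export
print.mge_vocabulary <- function(x, ...) {
  cat(sprintf(paste0("<mge_vocabulary> %d HMRG COGs, %d ARG COGs, %d conjugal COGs,\n",
                     "  %d MGE Pfams (%d replication), %d extended domains\n"),
              length(x$hmrg_cogs), length(x$arg_cogs), length(x$conj_cogs),
              length(x$mge_pfams), length(x$replication_pfams),
              length(x$extended_mge_domains)))
  invisible(x)
}

#' Canonical gene names for HMRG COGs
#'
#' @param vocab An `mge_vocabulary`.
#' @param cog_ids COG ids to translate; defaults to all HMRG COGs.
#' @return Character vector of gene names (falls back to the COG id when no
#'   name is recorded), named by COG id.
#' @export
hmrg_gene_names <- function(vocab, cog_ids = names(vocab$hmrg_cogs)) {
  out <- vocab$hmrg_gene_names[cog_ids]
  missing <- is.na(out)
  out[missing] <- cog_ids[missing]
  stats::setNames(as.character(out), cog_ids)
}
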