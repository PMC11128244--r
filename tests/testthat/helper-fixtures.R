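# Compact constructors for hand-built fixtures.

# element with n genes laid out one per `pitch` bp; per-gene annotation given
# as lists/vectors recycled to n
make_element <- function(id, n = 4L, stratum = "high_U", length_bp = NULL,
                         cogs = list(character()), pfams = list(character()),
                         domains = list(character()),
                         tax_phylum = NA_character_, tax_class = NA_character_,
                         product = NA_character_, sequence = NA_character_,
                         sample_id = "S1", pitch = 1000L) {
  if (is.null(length_bp)) length_bp <- max(500L, n * pitch)
  start <- (seq_len(n) - 1L) * pitch + 1L
  genes <- gene_table(
    gene_id = sprintf("%s_g%d", id, seq_len(n) - 1L),
    orf_index = seq_len(n) - 1L, start = start,
    end = start + as.integer(pitch * 0.7), strand = rep("+", n),
    cogs = rep_len(if (is.list(cogs)) cogs else list(cogs), n),
    pfams = rep_len(if (is.list(pfams)) pfams else list(pfams), n),
    domains = rep_len(if (is.list(domains)) domains else list(domains), n),
    tax_phylum = rep_len(tax_phylum, n), tax_class = rep_len(tax_class, n),
    product = rep_len(product, n))
  circular_element(id, sample_id, stratum, length_bp, genes, sequence)
}

# element whose genes at `orfs` carry the given HMRG cog ids (one per orf)
make_hmrg_element <- function(id, n, orfs, cog_ids, stratum = "high_U", ...) {
  cogs <- rep(list(character()), n)
  cogs[orfs + 1L] <- as.list(rep_len(cog_ids, length(orfs)))
  make_element(id, n = n, stratum = stratum, cogs = cogs, ...)
}

as_named <- function(...) {
  els <- list(...)
  if (length(els) == 1L && is.list(els[[1]]) &&
      !inherits(els[[1]], "circular_element")) els <- els[[1]]
  stats::setNames(els, vapply(els, function(e) e$element_id, character(1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

test_vocab <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- load_vocabulary()
    v
  }
})
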