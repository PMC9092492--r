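#' Load a genome as a DNAStringSet
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path. Sequence names
#'   are truncated at the first whitespace.
#' @return A `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1) {
    if (!file.exists(genome)) abort(paste0("genome FASTA not found: ", genome))
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  abort("genome must be a DNAStringSet or a FASTA path")
}

# plus-strand base at (contig, pos); "" when out of range
genome_base <- function(genome, contig, pos) {
  genome_context(genome, contig, pos, pos)
}

# plus-strand subsequence [start, end]; "" when out of range
genome_context <- function(genome, contig, start, end) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    if (!ct %in% names(genome)) {
      abort(paste0("contig absent from genome: ", ct))
    }
    seqstr <- as.character(genome[[ct]])
    ok <- start[i] >= 1 & end[i] <= nchar(seqstr) & start[i] <= end[i]
    out[i[ok]] <- substring(seqstr, start[i][ok], end[i][ok])
  }
  out
}

iupac_match1 <- function(base, code) {
  map <- Biostrings::IUPAC_CODE_MAP
  allowed <- strsplit(unname(map[code]), "")[[1]]
  base %in% allowed
}

# does each transcript-strand context match the IUPAC motif exactly?
# contexts containing characters outside A/C/G/T never match (conservative).
iupac_match <- function(context, motif) {
  k <- nchar(motif)
  ok <- nchar(context) == k
  codes <- strsplit(motif, "")[[1]]
  for (j in seq_len(k)) {
    b <- substring(context, j, j)
    ok <- ok & b %in% c("A", "C", "G", "T") &
      vapply(b, iupac_match1, logical(1), code = codes[j])
  }
  unname(ok)
}

#' Transcript-strand sequence context of edit sites
#'
#' Returns, for each site, the `width`-mer of the transcript strand ending
#' at the edited base: for plus-strand genes the plus-strand genome window
#' `[pos - width + 1, pos]`, for minus-strand genes the reverse complement
#' of `[pos, pos + width - 1]`.
#'
#' @param sites a site tibble with `contig`, `pos`, `strand`.
#' @param genome a genome ([load_genome()]).
#' @param width context width in nt (default 3, matching the RAC motif).
#' @return Character vector of contexts (`""` where out of range).
#' @export
motif_context <- function(sites, genome, width = 3L) {
  genome <- load_genome(genome)
  plus <- sites$strand == "+"
  start <- if_else(plus, sites$pos - width + 1L, sites$pos)
  end <- if_else(plus, sites$pos, sites$pos + width - 1L)
  ctx <- genome_context(genome, sites$contig, start, end)
  rc <- !plus & nzchar(ctx)
  if (any(rc)) {
    ctx[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx[rc])))
  }
  ctx
}

#' Keep only sites in the m6A consensus motif
#'
#' C-to-U edit sites are retained iff the transcript-strand trinucleotide
#' ending at the edited cytidine matches the RAC consensus (R-A-C, R = A/G):
#' the edited C sits immediately 3' of the methylated adenosine. Minus-
#' strand genes are evaluated on the reverse complement. Ambiguous genome
#' bases (N etc.) fail the test. A-to-I site sets are refused: A-to-I
#' editing is not immediately adjacent to the methylated base, so no motif
#' filter applies.
#'
#' @param sites a site tibble (edit type `C2U`).
#' @param genome genome ([load_genome()]).
#' @param motif IUPAC motif anchored with the edited base at its final
#'   position (default `"RAC"`).
#' @return The subset of `sites` whose context matches.
#' @export
filter_motif <- function(sites, genome, motif = "RAC") {
  if (!nzchar(motif)) abort("motif must be non-empty")
  if (any(sites$edit_type == "A2I")) {
    abort("motif filter not applicable to A2I site sets")
  }
  if (nrow(sites) == 0) return(sites)
  ctx <- motif_context(sites, genome, width = nchar(motif))
  sites[iupac_match(ctx, motif), , drop = FALSE]
}

#' Remove blacklisted positions from a site set
#'
#' Subtracts editing events attributable to the deaminase alone: any site
#' whose key `(contig, pos, strand, edit_type)` appears in the union of the
#' blacklist sets — i.e. observed in any deaminase-alone replicate — is
#' removed.
#'
#' @param sites a site tibble.
#' @param blacklists a site tibble or a list of site tibbles (e.g. one per
#'   deaminase-alone replicate). An empty list is the identity.
#' @return The subset of `sites` not blacklisted.
#' @export
filter_blacklist <- function(sites, blacklists) {
  if (is.data.frame(blacklists)) blacklists <- list(blacklists)
  if (length(blacklists) == 0 || nrow(sites) == 0) return(sites)
  bad <- unique(unlist(lapply(blacklists, site_key)))
  sites[!site_key(sites) %in% bad, , drop = FALSE]
}
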