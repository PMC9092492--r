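#' Build a gene index from exon and CDS tables
#'
#' The gene index is the package's transcript-model container: per-transcript
#' exon structure plus derived 5'UTR/CDS/3'UTR lengths in transcript space,
#' with one canonical transcript flagged per gene. All genomic coordinates
#' are 1-based and closed; transcript offsets run 5' to 3' on the transcript
#' strand starting at 1.
#'
#' @param exons tibble with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (1-based closed, one row per
#'   exon). Exons may be given in any order; they are stored sorted and must
#'   not overlap within a transcript.
#' @param cds optional tibble with columns `transcript_id`, `cds_start`,
#'   `cds_end` (genomic bounds of the coding region). Transcripts absent
#'   from `cds` are flagged noncoding and excluded from metagene profiles.
#' @return An object of class `gene_index`: a list with tibbles
#'   `transcripts` (ids, strand, region lengths, `coding`, `canonical`) and
#'   `exons` (with 5'-to-3' rank and cumulative offsets used for coordinate
#'   mapping).
#' @export
gene_index <- function(exons, cds = NULL) {
  need <- c("transcript_id", "gene_id", "contig", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) {
    abort(paste0("exon table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ex <- as_tibble(exons) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$transcript_id, .data$start)
  if (any(ex$end < ex$start)) abort("exon end < start")
  bad <- ex |>
    group_by(.data$transcript_id) |>
    summarise(ok = all(diff(.data$start) > 0) &&
                all(head(.data$end, -1) < tail(.data$start, -1)) ||
                n() == 1L,
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste0("overlapping or duplicated exons in transcript ",
                 bad$transcript_id[1]))
  }
  ex <- ex |>
    mutate(width = .data$end - .data$start + 1L) |>
    group_by(.data$transcript_id) |>
    mutate(
      cum_before = ifelse(.data$strand == "+",
                          cumsum(.data$width) - .data$width,
                          rev(cumsum(rev(.data$width))) - .data$width),
      rank5 = ifelse(.data$strand == "+", row_number(), rev(row_number()))
    ) |>
    ungroup()

  tx <- ex |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = .data$gene_id[1], contig = .data$contig[1],
              strand = .data$strand[1],
              tx_start = min(.data$start), tx_end = max(.data$end),
              exonic_len = sum(.data$width), n_exons = n(),
              .groups = "drop")

  tx$cds_start <- NA_integer_
  tx$cds_end <- NA_integer_
  if (!is.null(cds) && nrow(cds)) {
    cds <- as_tibble(cds)
    i <- match(tx$transcript_id, cds$transcript_id)
    tx$cds_start <- as.integer(cds$cds_start[i])
    tx$cds_end <- as.integer(cds$cds_end[i])
  }
  tx$coding <- !is.na(tx$cds_start)

  # transcript-space region lengths; errors if CDS bounds are not exonic
  tx$utr5_len <- 0L
  tx$cds_len <- 0L
  tx$utr3_len <- 0L
  if (any(tx$coding)) {
    cod <- tx[tx$coding, ]
    g5 <- if_else(cod$strand == "+", cod$cds_start, cod$cds_end)
    off5 <- tx_offset(ex, cod$transcript_id, g5)
    if (anyNA(off5)) {
      abort(paste0("CDS outside exons of transcript ",
                   cod$transcript_id[which(is.na(off5))[1]]))
    }
    g3 <- if_else(cod$strand == "+", cod$cds_end, cod$cds_start)
    off3 <- tx_offset(ex, cod$transcript_id, g3)
    if (anyNA(off3)) {
      abort(paste0("CDS outside exons of transcript ",
                   cod$transcript_id[which(is.na(off3))[1]]))
    }
    cds_len <- off3 - off5 + 1L
    tx$utr5_len[tx$coding] <- off5 - 1L
    tx$cds_len[tx$coding] <- cds_len
    tx$utr3_len[tx$coding] <- tx$exonic_len[tx$coding] - (off5 - 1L) - cds_len
  }

  canon <- select_canonical(tx)
  tx$canonical <- tx$transcript_id %in% canon$transcript_id

  structure(list(transcripts = tx, exons = ex), class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat("<gene_index> ", nrow(x$transcripts), " transcripts (",
      sum(x$transcripts$coding), " coding) in ",
      length(unique(x$transcripts$gene_id)), " genes\n", sep = "")
  invisible(x)
}

# transcript offset (1-based, 5'->3' on transcript strand) of genomic
# positions; NA where the position is not exonic in the transcript.
tx_offset <- function(ex, transcript_id, pos) {
  q <- tibble(transcript_id = transcript_id, pos = as.integer(pos),
              .q = seq_along(pos))
  hit <- inner_join(q, ex, by = "transcript_id",
                    relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    mutate(off = if_else(.data$strand == "+",
                         .data$cum_before + (.data$pos - .data$start + 1L),
                         .data$cum_before + (.data$end - .data$pos + 1L)))
  out <- rep(NA_integer_, length(pos))
  out[hit$.q] <- hit$off
  out
}

# inverse: genomic position of transcript offsets (vectorized)
tx_to_genomic <- function(ex, transcript_id, off) {
  q <- tibble(transcript_id = transcript_id, off = as.integer(off),
              .q = seq_along(off))
  hit <- inner_join(q, ex, by = "transcript_id",
                    relationship = "many-to-many") |>
    filter(.data$off > .data$cum_before,
           .data$off <= .data$cum_before + .data$width) |>
    mutate(pos = if_else(.data$strand == "+",
                         .data$start + (.data$off - .data$cum_before) - 1L,
                         .data$end - (.data$off - .data$cum_before) + 1L))
  out <- rep(NA_integer_, length(off))
  out[hit$.q] <- hit$pos
  out
}

#' Select the canonical transcript of each gene
#'
#' Canonical = longest CDS; ties broken by longest exonic length, then by
#' lexicographically smallest `transcript_id`. A stable, annotation-version
#' independent proxy for the representative transcript used in metagene
#' analysis.
#'
#' @param transcripts a tibble of transcripts as found in
#'   `gene_index$transcripts` (needs `gene_id`, `transcript_id`, `cds_len`,
#'   `exonic_len`).
#' @return One row per gene, the chosen transcript.
#' @export
select_canonical <- function(transcripts) {
  if (nrow(transcripts) == 0) abort("no transcripts to select from")
  transcripts |>
    arrange(.data$gene_id, dplyr::desc(.data$cds_len),
            dplyr::desc(.data$exonic_len), .data$transcript_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    ungroup()
}

canonical_tx <- function(index) {
  index$transcripts[index$transcripts$canonical, , drop = FALSE]
}

canonical_exons <- function(index) {
  semi_join(index$exons, canonical_tx(index), by = "transcript_id")
}

#' Read transcript annotation from GTF or BED12
#'
#' GTF needs `exon` features with `transcript_id` and `gene_id` attributes
#' and optional `CDS` features; BED12 uses the block structure for exons and
#' the thick range for the CDS, with the `name` field as both transcript and
#' gene identifier.
#'
#' @param path a GTF/GFF2 (`.gtf`) or BED12 (`.bed`) file.
#' @return A [gene_index()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- gr$blocks
    if (is.null(blocks)) {
      # BED6: one exon per record
      exons <- tibble(
        transcript_id = as.character(gr$name), gene_id = as.character(gr$name),
        contig = as.character(GenomicRanges::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
      return(gene_index(exons))
    }
    nb <- lengths(blocks)
    exstart <- unlist(IRanges::start(blocks)) + rep(GenomicRanges::start(gr), nb) - 1L
    exend <- unlist(IRanges::end(blocks)) + rep(GenomicRanges::start(gr), nb) - 1L
    exons <- tibble(
      transcript_id = rep(as.character(gr$name), nb),
      gene_id = rep(as.character(gr$name), nb),
      contig = rep(as.character(GenomicRanges::seqnames(gr)), nb),
      strand = rep(as.character(GenomicRanges::strand(gr)), nb),
      start = exstart, end = exend)
    th <- gr$thick
    has_cds <- !is.null(th) & IRanges::width(th) > 0 &
      !(IRanges::start(th) == GenomicRanges::end(gr) + 1L)
    cds <- tibble(transcript_id = as.character(gr$name)[has_cds],
                  cds_start = IRanges::start(th)[has_cds],
                  cds_end = IRanges::end(th)[has_cds])
    return(gene_index(exons, cds))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(gr$type)
  exi <- gr[typ == "exon"]
  if (length(exi) == 0) abort("GTF contains no exon features")
  exons <- tibble(
    transcript_id = as.character(exi$transcript_id),
    gene_id = as.character(exi$gene_id),
    contig = as.character(GenomicRanges::seqnames(exi)),
    strand = as.character(GenomicRanges::strand(exi)),
    start = GenomicRanges::start(exi), end = GenomicRanges::end(exi))
  cdsi <- gr[typ == "CDS"]
  cds <- NULL
  if (length(cdsi)) {
    cds <- tibble(transcript_id = as.character(cdsi$transcript_id),
                  start = GenomicRanges::start(cdsi),
                  end = GenomicRanges::end(cdsi)) |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = min(.data$start), cds_end = max(.data$end),
                .groups = "drop")
  }
  gene_index(exons, cds)
}

#' Assign genomic positions to genes, strands and transcript regions
#'
#' Each `(contig, pos)` is located on the canonical transcript of the gene
#' covering it. Region is one of `5UTR`, `CDS`, `3UTR` (exonic positions of
#' coding genes), `noncoding` (exonic in a noncoding gene), `intronic`
#' (inside the gene body but not exonic; gene and strand are still reported)
#' or `intergenic` (strand `NA`). When several genes cover a position,
#' exonic coverage wins; remaining ties go to the smaller `gene_id`.
#'
#' @param sites a tibble with columns `contig` and `pos` (1-based).
#' @param index a [gene_index()].
#' @return `sites` with added/overwritten columns `gene_id`, `strand`,
#'   `region` and `transcript_id`.
#' @export
locate_sites <- function(sites, index) {
  if (!all(c("contig", "pos") %in% names(sites))) {
    abort("sites need columns contig and pos")
  }
  if (!inherits(index, "gene_index")) abort("index must be a gene_index")
  s <- as_tibble(sites)
  s$.row <- seq_len(nrow(s))
  ex <- canonical_exons(index)
  sgr <- GenomicRanges::GRanges(s$contig, IRanges::IRanges(s$pos, s$pos))
  egr <- GenomicRanges::GRanges(ex$contig, IRanges::IRanges(ex$start, ex$end))
  ov <- GenomicRanges::findOverlaps(sgr, egr, ignore.strand = TRUE)
  hits <- dplyr::bind_cols(
    s[S4Vectors::queryHits(ov), c(".row", "contig", "pos")],
    ex[S4Vectors::subjectHits(ov),
       c("transcript_id", "strand", "start", "end")])
  txs <- index$transcripts
  hits <- left_join(hits,
                    txs |> select("transcript_id", "gene_id2" = "gene_id",
                                  "coding", "utr5_len", "cds_len"),
                    by = "transcript_id") |>
    arrange(.data$.row, .data$gene_id2) |>
    distinct(.data$.row, .keep_all = TRUE)
  off <- tx_offset(index$exons, hits$transcript_id, hits$pos)
  hits$region <- dplyr::case_when(
    !hits$coding ~ "noncoding",
    off <= hits$utr5_len ~ "5UTR",
    off <= hits$utr5_len + hits$cds_len ~ "CDS",
    TRUE ~ "3UTR")

  gene_id <- rep(NA_character_, nrow(s))
  strand <- rep(NA_character_, nrow(s))
  region <- rep("intergenic", nrow(s))
  transcript_id <- rep(NA_character_, nrow(s))
  gene_id[hits$.row] <- hits$gene_id2
  strand[hits$.row] <- hits$strand
  region[hits$.row] <- hits$region
  transcript_id[hits$.row] <- hits$transcript_id

  # non-exonic positions inside a canonical transcript span: intronic
  rest <- setdiff(s$.row, hits$.row)
  if (length(rest)) {
    ctx <- canonical_tx(index)
    rs <- s[match(rest, s$.row), c(".row", "contig", "pos")]
    rgr <- GenomicRanges::GRanges(rs$contig, IRanges::IRanges(rs$pos, rs$pos))
    tgr <- GenomicRanges::GRanges(ctx$contig,
                                  IRanges::IRanges(ctx$tx_start, ctx$tx_end))
    iov <- GenomicRanges::findOverlaps(rgr, tgr, ignore.strand = TRUE)
    ih <- dplyr::bind_cols(
      rs[S4Vectors::queryHits(iov), , drop = FALSE],
      ctx[S4Vectors::subjectHits(iov),
          c("transcript_id", "gene_id", "strand")]) |>
      arrange(.data$.row, .data$gene_id) |>
      distinct(.data$.row, .keep_all = TRUE)
    gene_id[ih$.row] <- ih$gene_id
    strand[ih$.row] <- ih$strand
    region[ih$.row] <- "intronic"
    transcript_id[ih$.row] <- ih$transcript_id
  }
  s$gene_id <- gene_id
  s$strand <- strand
  s$region <- region
  s$transcript_id <- transcript_id
  s$.row <- NULL
  s
}

#' Map genomic positions to metagene coordinates
#'
#' Transcript positions are rescaled so that the 5'UTR, CDS and 3'UTR each
#' span one unit: `[0,1)`, `[1,2)` and `[2,3)` respectively, measured 5' to
#' 3' on the transcript strand. Region boundaries follow a half-open
#' convention: the first CDS base maps to exactly 1.0 and belongs to the CDS
#' unit. Only exonic positions of coding transcripts are mappable.
#'
#' @param contig,pos vectors of genomic positions (1-based).
#' @param index a [gene_index()].
#' @param transcript_id optional vector of transcript ids; when `NULL` the
#'   canonical transcript of the covering gene is used.
#' @return Numeric vector of metagene coordinates in `[0, 3)`.
#' @export
meta_coordinate <- function(contig, pos, index, transcript_id = NULL) {
  if (is.null(transcript_id)) {
    loc <- locate_sites(tibble(contig = contig, pos = pos), index)
    transcript_id <- loc$transcript_id
  }
  txs <- index$transcripts
  i <- match(transcript_id, txs$transcript_id)
  if (anyNA(i)) abort("position is not exonic in any coding transcript")
  if (any(!txs$coding[i])) abort("metagene coordinates need coding transcripts")
  off <- tx_offset(index$exons, transcript_id, pos)
  if (anyNA(off)) abort("position is not exonic in the given transcript")
  u5 <- txs$utr5_len[i]; cl <- txs$cds_len[i]; u3 <- txs$utr3_len[i]
  dplyr::case_when(
    off <= u5 ~ (off - 1) / u5,
    off <= u5 + cl ~ 1 + (off - 1 - u5) / cl,
    TRUE ~ 2 + (off - 1 - u5 - cl) / u3
  )
}
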