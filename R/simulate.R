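#' Configuration of the synthetic DART-seq study
#'
#' Defines the generative model the caller assumes: multi-exon genes with
#' 5'UTR/CDS/3'UTR structure on both strands, truth m6A sites planted in
#' RAC contexts with a 3'UTR placement bias, negative-binomial coverage,
#' beta-distributed per-site DART editing rates, residual editing of truth
#' sites in the control (the binding-deficient YTHmut fusion retains
#' low-level m6A binding), a low background off-target rate at all eligible
#' bases, and deaminase-alone artifact positions edited independently of
#' methylation.
#'
#' @param edit_type `"C2U"` or `"A2I"`.
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene inclusive range of exon counts.
#' @param utr5_range,cds_range,utr3_range inclusive ranges (nt) of region
#'   lengths in transcript space.
#' @param intron_range,gap_range inclusive ranges (nt) of intron and
#'   intergenic-gap lengths.
#' @param frac_minus fraction of genes on the minus strand.
#' @param n_true_sites number of ground-truth methylation sites.
#' @param utr3_bias fraction of truth sites placed in the 3'UTR (default
#'   0.6; the remainder is split 3:1 between CDS and 5'UTR), emulating the
#'   enrichment of m6A in 3'UTRs and near the stop codon.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   model (mean and size).
#' @param dart_rate_shape Beta shape parameters `c(a, b)` of the per-site
#'   DART editing rate (default `c(3, 7)`, mean 0.3).
#' @param control_multiplier control residual editing at truth sites as a
#'   multiple of the site's DART rate (default 0.1).
#' @param background_rate off-target editing rate at all eligible bases
#'   (default 0.005).
#' @param deaminase_rate,n_artifact_sites editing rate and number of
#'   deaminase-alone artifact positions; artifacts are planted in the same
#'   sequence context as truth sites (so the motif filter cannot remove
#'   them) and edited in the DART and deaminase-alone conditions, making
#'   blacklist subtraction observable end to end.
#' @param n_replicates replicates per condition.
#' @param read_length read length for [simulate_alignments()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(edit_type = c("C2U", "A2I"),
                       n_genes = 60L,
                       exons_per_gene = c(1L, 4L),
                       utr5_range = c(100L, 300L),
                       cds_range = c(300L, 900L),
                       utr3_range = c(300L, 900L),
                       intron_range = c(60L, 200L),
                       gap_range = c(200L, 500L),
                       frac_minus = 0.5,
                       n_true_sites = 200L,
                       utr3_bias = 0.6,
                       coverage_mean = 50,
                       coverage_dispersion = 20,
                       dart_rate_shape = c(3, 7),
                       control_multiplier = 0.1,
                       background_rate = 0.005,
                       deaminase_rate = 0.3,
                       n_artifact_sites = 20L,
                       n_replicates = 3L,
                       read_length = 50L) {
  edit_type <- match.arg(edit_type)
  stopifnot(n_genes >= 1, n_true_sites >= 0, n_artifact_sites >= 0,
            n_replicates >= 1,
            utr3_bias >= 0, utr3_bias <= 1,
            control_multiplier >= 0, control_multiplier <= 1,
            background_rate >= 0, background_rate <= 1,
            deaminase_rate >= 0, deaminase_rate <= 1,
            coverage_mean > 0, coverage_dispersion > 0,
            all(dart_rate_shape > 0))
  structure(as.list(environment()), class = "sim_config")
}

MIN_EXON <- 60L

# split total length into n chunks each >= MIN_EXON
split_exons <- function(total, n) {
  n <- max(1L, min(n, total %/% MIN_EXON))
  extra <- total - MIN_EXON * n
  w <- runif(n)
  add <- floor(extra * w / sum(w))
  add[1] <- add[1] + (extra - sum(add))
  MIN_EXON + add
}

#' Simulate a ground-truth genome, annotation and methylation sites
#'
#' Generates a random genome and gene annotation, plants `n_true_sites`
#' methylation sites in RAC contexts on the transcript strand (for C2U
#' truth, the recorded position is the edited cytidine 1 nt 3' of the
#' methylated adenosine; for A2I it is the methylated adenosine itself)
#' and `n_artifact_sites` deaminase-alone artifact positions in the same
#' context class, and draws a per-site DART editing rate from the
#' configured Beta distribution.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; output is byte-identical under a fixed seed.
#' @param dir optional directory; when given, `genome.fa`,
#'   `annotation.gtf` and `truth.tsv` are written there.
#' @return A list of class `dart_sim_ref`: `genome` (DNAStringSet),
#'   `index` ([gene_index()]), `truth` and `artifacts` (tibbles with
#'   `contig, pos, strand, gene_id, transcript_id, region, rate`),
#'   `positions` (all exonic positions with transcript-strand base) and
#'   `config`.
#' @export
simulate_reference <- function(cfg = sim_config(), seed = 1L, dir = NULL) {
  ref <- withr::with_seed(as.integer(seed), simulate_reference_impl(cfg))
  if (!is.null(dir)) write_reference(ref, dir)
  ref
}

simulate_reference_impl <- function(cfg) {
  contigs <- c("chr_sim1", "chr_sim2")
  cursor <- setNames(rep(0L, length(contigs)), contigs)
  ex_rows <- vector("list", cfg$n_genes)
  cds_rows <- vector("list", cfg$n_genes)
  meta <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ct <- contigs[(i - 1) %% length(contigs) + 1]
    u5 <- sample(cfg$utr5_range[1]:cfg$utr5_range[2], 1)
    cl <- sample(cfg$cds_range[1]:cfg$cds_range[2], 1)
    u3 <- sample(cfg$utr3_range[1]:cfg$utr3_range[2], 1)
    total <- u5 + cl + u3
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
    widths <- split_exons(total, n_ex)
    introns <- if (length(widths) > 1) {
      sample(cfg$intron_range[1]:cfg$intron_range[2], length(widths) - 1,
             replace = TRUE)
    } else integer()
    gap <- sample(cfg$gap_range[1]:cfg$gap_range[2], 1)
    start1 <- cursor[ct] + gap + 1L
    starts <- start1 + c(0L, cumsum(widths[-length(widths)] + introns))
    ends <- starts + widths - 1L
    cursor[ct] <- ends[length(ends)]
    strand <- if (runif(1) < cfg$frac_minus) "-" else "+"
    gid <- sprintf("G%04d", i)
    tid <- sprintf("T%04d", i)
    ex_rows[[i]] <- tibble(transcript_id = tid, gene_id = gid, contig = ct,
                           strand = strand, start = starts, end = ends)
    meta[[i]] <- tibble(transcript_id = tid, u5 = u5, cl = cl, u3 = u3)
  }
  exons <- bind_rows(ex_rows)
  txmeta <- bind_rows(meta)

  idx0 <- gene_index(exons)  # noncoding pass, for coordinate mapping
  g5 <- tx_to_genomic(idx0$exons, txmeta$transcript_id, txmeta$u5 + 1L)
  g3 <- tx_to_genomic(idx0$exons, txmeta$transcript_id,
                      txmeta$u5 + txmeta$cl)
  cds <- tibble(transcript_id = txmeta$transcript_id,
                cds_start = pmin(g5, g3), cds_end = pmax(g5, g3))
  index <- gene_index(exons, cds)

  seqs <- lapply(contigs, function(ct) {
    len <- cursor[ct] + 200L
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  names(seqs) <- contigs

  # plant truth + artifact contexts (RAC on the transcript strand)
  n_plant <- cfg$n_true_sites + cfg$n_artifact_sites
  txs <- index$transcripts
  planted <- list()
  used <- lapply(setNames(txs$transcript_id, txs$transcript_id),
                 function(x) integer())
  k <- 0L
  guard <- 0L
  while (k < n_plant) {
    guard <- guard + 1L
    if (guard > 200L * max(1L, n_plant)) {
      abort("infeasible simulation config: cannot place requested sites")
    }
    j <- sample.int(nrow(txs), 1)
    tm <- txmeta[match(txs$transcript_id[j], txmeta$transcript_id), ]
    r <- runif(1)
    region <- if (r < cfg$utr3_bias) "3UTR" else
      if (r < cfg$utr3_bias + (1 - cfg$utr3_bias) * 0.75) "CDS" else "5UTR"
    bounds <- switch(region,
                     "5UTR" = c(1L, tm$u5),
                     "CDS" = c(tm$u5 + 1L, tm$u5 + tm$cl),
                     "3UTR" = c(tm$u5 + tm$cl + 1L, tm$u5 + tm$cl + tm$u3))
    t <- sample(bounds[1]:bounds[2], 1)
    # context offsets on the transcript: R-A-C with the edited base anchored
    ctx_off <- if (cfg$edit_type == "C2U") (t - 2L):t else (t - 1L):(t + 1L)
    L <- txs$exonic_len[j]
    if (ctx_off[1] < 1L || ctx_off[3] > L) next
    g <- tx_to_genomic(index$exons, rep(txs$transcript_id[j], 3), ctx_off)
    if (max(g) - min(g) != 2L) next  # context must not straddle an exon gap
    tid <- txs$transcript_id[j]
    if (any(abs(used[[tid]] - t) < 4L)) next
    used[[tid]] <- c(used[[tid]], t)
    k <- k + 1L
    planted[[k]] <- tibble(
      contig = txs$contig[j], strand = txs$strand[j], gene_id = txs$gene_id[j],
      transcript_id = tid, region = region, t_off = t,
      g_ctx1 = g[1], g_ctx2 = g[2], g_ctx3 = g[3])
  }
  planted <- bind_rows(planted)
  if (nrow(planted) == 0) {
    planted <- tibble(contig = character(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      region = character(), t_off = integer(),
                      g_ctx1 = integer(), g_ctx2 = integer(),
                      g_ctx3 = integer())
  }
  if (nrow(planted)) {
    r_base <- sample(c("A", "G"), nrow(planted), replace = TRUE)
    tstrand_ctx <- cbind(r_base, "A", "C")
    for (i in seq_len(nrow(planted))) {
      ct <- planted$contig[i]
      gpos <- c(planted$g_ctx1[i], planted$g_ctx2[i], planted$g_ctx3[i])
      bases <- tstrand_ctx[i, ]
      if (planted$strand[i] == "-") bases <- chartr("ACGT", "TGCA", bases)
      seqs[[ct]][gpos] <- bases
    }
    # edited position: the C (3rd context base) for C2U, the A for A2I;
    # tx_to_genomic is already strand-aware, so no per-strand flip here
    planted$pos <- if (cfg$edit_type == "C2U") planted$g_ctx3 else
      planted$g_ctx2
  } else {
    planted$pos <- integer()
  }

  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- contigs

  pick <- seq_len(cfg$n_true_sites)
  truth <- planted[pick, c("contig", "pos", "strand", "gene_id",
                           "transcript_id", "region"), drop = FALSE]
  truth$rate <- rbeta(nrow(truth), cfg$dart_rate_shape[1],
                      cfg$dart_rate_shape[2])
  artifacts <- planted[setdiff(seq_len(nrow(planted)), pick),
                       c("contig", "pos", "strand", "gene_id",
                         "transcript_id", "region"), drop = FALSE]
  artifacts$rate <- rep(cfg$deaminase_rate, nrow(artifacts))
  truth <- arrange(truth, .data$contig, .data$pos)
  artifacts <- arrange(artifacts, .data$contig, .data$pos)

  positions <- exonic_positions(index, genome)
  structure(list(genome = genome, index = index, truth = truth,
                 artifacts = artifacts, positions = positions, config = cfg),
            class = "dart_sim_ref")
}

#' @export
print.dart_sim_ref <- function(x, ...) {
  cat("<dart_sim_ref> ", length(x$genome), " contigs, ",
      nrow(x$index$transcripts), " genes, ", nrow(x$truth),
      " truth sites, ", nrow(x$artifacts), " artifact sites (",
      x$config$edit_type, ")\n", sep = "")
  invisible(x)
}

# every exonic position of every canonical transcript, with the
# transcript-strand base
exonic_positions <- function(index, genome) {
  ex <- canonical_exons(index)
  n <- ex$width
  out <- tibble(
    contig = rep(ex$contig, n),
    pos = unlist(Map(seq.int, ex$start, ex$end)),
    strand = rep(ex$strand, n),
    transcript_id = rep(ex$transcript_id, n))
  out$plus_base <- genome_base(genome, out$contig, out$pos)
  out$tstrand_base <- if_else(out$strand == "+", out$plus_base,
                              chartr("ACGT", "TGCA", out$plus_base))
  out
}

# per-position editing rate for one condition
position_rates <- function(ref, condition) {
  cfg <- ref$config
  p <- ref$positions
  src <- if (cfg$edit_type == "C2U") "C" else "A"
  eligible <- p$tstrand_base == src
  rate <- ifelse(eligible, cfg$background_rate, 0)
  key <- paste(p$contig, p$pos)
  it <- match(paste(ref$truth$contig, ref$truth$pos), key)
  ia <- match(paste(ref$artifacts$contig, ref$artifacts$pos), key)
  if (condition == "dart") {
    rate[it] <- rate[it] + ref$truth$rate
    rate[ia] <- rate[ia] + ref$artifacts$rate
  } else if (condition == "control") {
    rate[it] <- rate[it] + cfg$control_multiplier * ref$truth$rate
  } else if (condition == "deaminase_alone") {
    rate[ia] <- rate[ia] + ref$artifacts$rate
  } else {
    abort(paste0("unknown condition: ", condition))
  }
  pmin(rate, 1)
}

#' Simulate per-replicate pileup matrices
#'
#' At each exonic position, coverage is drawn from a negative binomial and
#' the edited-read count from a binomial with the condition's rate: the
#' site's DART rate at truth sites in the DART condition, the residual
#' `control_multiplier` times the site rate in the control, the deaminase
#' rate at artifact positions in the DART and deaminase-alone conditions,
#' and the background rate at every other eligible base. Rates combine
#' additively, capped at 1.
#'
#' @param ref a `dart_sim_ref` from [simulate_reference()].
#' @param seed integer seed (all replicates of all conditions flow from it).
#' @param conditions conditions to simulate.
#' @return A named list (per condition) of lists of `dart_pileup` tibbles,
#'   one per replicate.
#' @export
simulate_pileups <- function(ref, seed = 1L,
                             conditions = c("dart", "control",
                                            "deaminase_alone")) {
  if (!inherits(ref, "dart_sim_ref")) abort("ref must be a dart_sim_ref")
  cfg <- ref$config
  p <- ref$positions
  alt_plus <- edit_bases(cfg$edit_type, p$strand)$alt
  withr::with_seed(as.integer(seed), {
    out <- lapply(setNames(conditions, conditions), function(cond) {
      rate <- position_rates(ref, cond)
      lapply(seq_len(cfg$n_replicates), function(rep_i) {
        cov <- rnbinom(nrow(p), size = cfg$coverage_dispersion,
                       mu = cfg$coverage_mean)
        alt <- rbinom(nrow(p), cov, rate)
        ref_n <- cov - alt
        counts <- matrix(0L, nrow(p), 4,
                         dimnames = list(NULL, c("A", "C", "G", "T")))
        ridx <- cbind(seq_len(nrow(p)),
                      match(p$plus_base, c("A", "C", "G", "T")))
        aidx <- cbind(seq_len(nrow(p)),
                      match(alt_plus, c("A", "C", "G", "T")))
        counts[ridx] <- ref_n
        counts[aidx] <- counts[aidx] + alt
        keep <- cov > 0
        pileup_tbl(p$contig[keep], p$pos[keep],
                   counts[keep, "A"], counts[keep, "C"],
                   counts[keep, "G"], counts[keep, "T"],
                   sample = paste0(cond, "_rep", rep_i),
                   replicate = rep_i, condition = cond)
      })
    })
    out
  })
}

#' Simulate aligned reads as SAM files
#'
#' Single-end perfect-quality reads of fixed length tile each exon at the
#' configured mean coverage; edited bases are injected per read with the
#' same rate model as [simulate_pileups()]. Reads never span exon
#' junctions. Running [build_pileup()] on the output reproduces the pileup
#' marginals in expectation.
#'
#' @param ref a `dart_sim_ref`.
#' @param dir output directory for the SAM files.
#' @param seed integer seed; SAM bytes are identical under a fixed seed.
#' @param conditions conditions to simulate.
#' @return Named list (per condition) of character vectors of SAM paths,
#'   one per replicate.
#' @export
simulate_alignments <- function(ref, dir, seed = 1L,
                                conditions = c("dart", "control",
                                               "deaminase_alone")) {
  if (!inherits(ref, "dart_sim_ref")) abort("ref must be a dart_sim_ref")
  cfg <- ref$config
  L <- as.integer(cfg$read_length)
  if (L > min(ref$index$transcripts$exonic_len)) {
    abort("read_length exceeds the exonic length of a transcript")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- canonical_exons(ref$index)
  ex <- ex[ex$width >= L, , drop = FALSE]
  glen <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(ref$genome), "\tLN:", glen))
  qual <- strrep("I", L)
  key <- paste(ref$positions$contig, ref$positions$pos)

  withr::with_seed(as.integer(seed), {
    lapply(setNames(conditions, conditions), function(cond) {
      rate_all <- position_rates(ref, cond)
      alt_plus_all <- edit_bases(cfg$edit_type, ref$positions$strand)$alt
      vapply(seq_len(cfg$n_replicates), function(rep_i) {
        recs <- list()
        rid <- 0L
        for (e in seq_len(nrow(ex))) {
          nread <- max(1L, round(cfg$coverage_mean * ex$width[e] / L))
          starts <- sort(sample.int(ex$width[e] - L + 1L, nread,
                                    replace = TRUE)) + ex$start[e] - 1L
          seqstr <- as.character(
            Biostrings::subseq(ref$genome[[ex$contig[e]]],
                               ex$start[e], ex$end[e]))
          for (st in starts) {
            rid <- rid + 1L
            off <- st - ex$start[e] + 1L
            bases <- strsplit(substring(seqstr, off, off + L - 1L), "")[[1]]
            pidx <- match(paste(ex$contig[e], st:(st + L - 1L)), key)
            r <- rate_all[pidx]
            flip <- !is.na(r) & r > 0 & runif(L) < ifelse(is.na(r), 0, r)
            bases[flip] <- alt_plus_all[pidx[flip]]
            recs[[rid]] <- paste(
              paste0("r", cond, rep_i, "_", rid), 0L, ex$contig[e], st, 60L,
              paste0(L, "M"), "*", 0L, 0L, paste(bases, collapse = ""), qual,
              sep = "\t")
          }
        }
        path <- file.path(dir, paste0(cond, "_rep", rep_i, ".sam"))
        # records are emitted per exon in start order; enforce global order
        body <- unlist(recs)
        ord <- order(vapply(strsplit(body, "\t"), `[`, character(1), 3),
                     as.integer(vapply(strsplit(body, "\t"), `[`,
                                       character(1), 4)))
        writeLines(c(header, body[ord]), path)
        path
      }, character(1))
    })
  })
}

#' Write a simulated reference to disk
#'
#' Emits `genome.fa`, `annotation.gtf` and `truth.tsv` (plus
#' `artifacts.tsv` when artifact sites exist).
#'
#' @param ref a `dart_sim_ref`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_gtf(ref$index, file.path(dir, "annotation.gtf"))
  readr::write_tsv(ref$truth, file.path(dir, "truth.tsv"))
  if (nrow(ref$artifacts)) {
    readr::write_tsv(ref$artifacts, file.path(dir, "artifacts.tsv"))
  }
  invisible(dir)
}

#' Write a gene index as GTF
#'
#' Emits `exon` and `CDS` features with `gene_id`/`transcript_id`
#' attributes (Ensembl dialect), 1-based closed coordinates.
#'
#' @param index a [gene_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(index, path) {
  ex <- index$exons
  attr_str <- function(gid, tid) {
    paste0("gene_id \"", gid, "\"; transcript_id \"", tid, "\";")
  }
  lines <- paste(ex$contig, "dartseq", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attr_str(ex$gene_id, ex$transcript_id),
                 sep = "\t")
  txs <- index$transcripts
  cod <- txs[txs$coding, , drop = FALSE]
  if (nrow(cod)) {
    cex <- semi_join(ex, cod, by = "transcript_id") |>
      left_join(cod |> select("transcript_id", "cds_start", "cds_end"),
                by = "transcript_id") |>
      mutate(cs = pmax(.data$start, .data$cds_start),
             ce = pmin(.data$end, .data$cds_end)) |>
      filter(.data$cs <= .data$ce)
    lines <- c(lines,
               paste(cex$contig, "dartseq", "CDS", cex$cs, cex$ce, ".",
                     cex$strand, "0",
                     attr_str(cex$gene_id, cex$transcript_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
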