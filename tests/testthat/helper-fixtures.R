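# Shared fixtures and independent oracles used across the suite.

# -- SAM writing --------------------------------------------------------------

write_sam <- function(path, contig_lengths, reads) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(contig_lengths),
                     "\tLN:", contig_lengths))
  reads <- reads[order(reads$rname, reads$pos), , drop = FALSE]
  body <- paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  writeLines(c(header, body), path)
  path
}

# -- naive per-read pileup walker (oracle for build_pileup) -------------------

naive_pileup <- function(sam_path, min_bq = 25, min_mq = 10) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- new.env(parent = emptyenv())
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    mapq <- as.integer(f[5])
    if (mapq < min_mq) next
    contig <- f[3]
    rpos <- as.integer(f[4])          # reference walker
    qpos <- 1L                        # query walker
    seq <- strsplit(f[10], "")[[1]]
    qual <- utf8ToInt(f[11]) - 33L
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      kind <- sub("^[0-9]+", "", op)
      if (kind %in% c("M", "=", "X")) {
        for (j in seq_len(n)) {
          b <- seq[qpos]
          if (qual[qpos] >= min_bq && b %in% c("A", "C", "G", "T")) {
            key <- paste0(contig, ":", rpos, ":", b)
            counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          }
          rpos <- rpos + 1L
          qpos <- qpos + 1L
        }
      } else if (kind %in% c("I", "S")) {
        qpos <- qpos + n
      } else if (kind %in% c("D", "N")) {
        rpos <- rpos + n
      } else if (kind %in% c("H", "P")) {
        # consume nothing
      } else {
        stop("unknown CIGAR op: ", kind)
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) return(dartseq::pileup_tbl())
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  df <- data.frame(contig = parts[, 1], pos = as.integer(parts[, 2]),
                   base = parts[, 3],
                   n = vapply(keys, function(k) counts[[k]], integer(1)))
  wide <- stats::reshape(df, idvar = c("contig", "pos"), timevar = "base",
                         direction = "wide")
  for (b in c("A", "C", "G", "T")) {
    col <- paste0("n.", b)
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  dartseq::pileup_tbl(wide$contig, wide$pos, wide$n.A, wide$n.C,
                      wide$n.G, wide$n.T)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip container classes and ancillary attributes for content comparison
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names")]
  class(x) <- "data.frame"
  x
}

# -- hand-built two-gene annotation (one per strand) --------------------------

toy_index <- function() {
  exons <- tibble::tibble(
    transcript_id = c("TP", "TP", "TM", "TM"),
    gene_id = c("GP", "GP", "GM", "GM"),
    contig = "c1",
    strand = c("+", "+", "-", "-"),
    start = c(101L, 301L, 1001L, 1251L),
    end = c(200L, 500L, 1150L, 1400L))
  cds <- tibble::tibble(transcript_id = c("TP", "TM"),
                        cds_start = c(151L, 1051L),
                        cds_end = c(430L, 1350L))
  dartseq::gene_index(exons, cds)
}

# all positions -> strand map for the brute-force caller oracle,
# built by simple exon enumeration (independent of locate_sites)
strand_map <- function(index) {
  ex <- index$exons
  key <- unlist(mapply(function(ct, s, e) paste0(ct, ":", s:e),
                       ex$contig, ex$start, ex$end, SIMPLIFY = FALSE))
  st <- unlist(mapply(function(st, s, e) rep(st, e - s + 1L),
                      ex$strand, ex$start, ex$end, SIMPLIFY = FALSE))
  # intronic positions also carry the gene strand
  txs <- index$transcripts
  ikey <- unlist(mapply(function(ct, s, e) paste0(ct, ":", s:e),
                        txs$contig, txs$tx_start, txs$tx_end,
                        SIMPLIFY = FALSE))
  ist <- unlist(mapply(function(st, s, e) rep(st, e - s + 1L),
                       txs$strand, txs$tx_start, txs$tx_end,
                       SIMPLIFY = FALSE))
  out <- c(setNames(st, key), setNames(ist, setdiff(ikey, key)))
  out[!duplicated(names(out))]
}

# -- brute-force position-by-position caller oracle ---------------------------

brute_caller <- function(sample, control, smap, params) {
  hits <- list()
  ctl_key <- paste0(control$contig, ":", control$pos)
  for (i in seq_len(nrow(sample))) {
    key <- paste0(sample$contig[i], ":", sample$pos[i])
    strand <- smap[key]
    if (is.na(strand)) next
    if (params$edit_type == "C2U") {
      rb <- if (strand == "+") "C" else "G"
      ab <- if (strand == "+") "T" else "A"
    } else {
      rb <- if (strand == "+") "A" else "T"
      ab <- if (strand == "+") "G" else "C"
    }
    n_ref <- sample[[rb]][i]
    n_alt <- sample[[ab]][i]
    if (n_ref + n_alt < params$min_coverage) next
    if (n_alt < params$min_alt_reads) next
    ratio <- n_alt / (n_ref + n_alt)
    if (ratio < params$ratio_low || ratio > params$ratio_high) next
    j <- match(key, ctl_key)
    c_ref <- if (is.na(j)) 0L else control[[rb]][j]
    c_alt <- if (is.na(j)) 0L else control[[ab]][j]
    if (c_ref + c_alt < params$min_control_coverage) next
    c_ratio <- c_alt / (c_ref + c_alt)
    if (ratio < params$min_fold * c_ratio - 1e-9) next
    hits[[length(hits) + 1L]] <-
      data.frame(contig = sample$contig[i], pos = sample$pos[i],
                 strand = strand, n_ref = n_ref, n_alt = n_alt,
                 edit_ratio = ratio, control_ratio = c_ratio)
  }
  if (!length(hits)) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character(), n_ref = integer(),
                      n_alt = integer(), edit_ratio = double(),
                      control_ratio = double()))
  }
  out <- do.call(rbind, hits)
  out[order(out$contig, out$pos), , drop = FALSE]
}

# random pileup over the exonic (plus a little intergenic) space of an index
random_pileup <- function(index, n = 400, max_count = 40) {
  ex <- index$exons
  pos_pool <- unlist(Map(seq.int, ex$start, ex$end))
  ct_pool <- rep(ex$contig, ex$end - ex$start + 1L)
  extra <- sample(2000:2100, 20)     # intergenic in toy coordinates
  pick <- sample(length(pos_pool), min(n, length(pos_pool)))
  contig <- c(ct_pool[pick], rep(ex$contig[1], length(extra)))
  pos <- c(pos_pool[pick], extra)
  dup <- duplicated(paste(contig, pos))
  contig <- contig[!dup]; pos <- pos[!dup]
  m <- matrix(rpois(4 * length(pos), max_count / 4), ncol = 4)
  dartseq::pileup_tbl(contig, pos, m[, 1], m[, 2], m[, 3], m[, 4])
}

# -- independent IUPAC trinucleotide matcher ----------------------------------

oracle_rac_match <- function(tri) {
  tri %in% c("AAC", "GAC")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# -- exact rank-sum p by enumeration of rank assignments ----------------------

enum_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}
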