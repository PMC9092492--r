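#' Per-position nucleotide pileup matrices
#'
#' A pileup matrix is a tibble with one row per reference position that
#' received at least one counted base, and columns `contig`, `pos` (1-based),
#' `A`, `C`, `G`, `T` (number of reads whose aligned base at the position is
#' the given reference-plus-strand nucleotide) and `coverage`. Coverage
#' equals `A + C + G + T` exactly: bases below the quality cutoffs, Ns,
#' deletions and reference skips contribute to neither side. Strand
#' resolution is deferred to gene annotation downstream; counts always live
#' in reference-plus-strand space.
#'
#' @param contig,pos,A,C,G,T character/integer vectors of equal length.
#' @param sample,replicate,condition optional metadata stored as attributes;
#'   `condition` is one of `"dart"`, `"control"`, `"deaminase_alone"` or `NA`.
#' @return A tibble of class `dart_pileup`, sorted by `(contig, pos)`.
#' @export
pileup_tbl <- function(contig = character(), pos = integer(),
                       A = integer(), C = integer(),
                       G = integer(), T = integer(),
                       sample = NA_character_, replicate = NA_integer_,
                       condition = NA_character_) {
  out <- tibble(
    contig = as.character(contig), pos = as.integer(pos),
    A = as.integer(A), C = as.integer(C), G = as.integer(G), T = as.integer(T)
  )
  out$coverage <- out$A + out$C + out$G + out$T
  out <- dplyr::arrange(out, .data$contig, .data$pos)
  attr(out, "sample") <- sample
  attr(out, "replicate") <- replicate
  attr(out, "condition") <- condition
  class(out) <- c("dart_pileup", class(tibble()))
  validate_pileup(out)
}

validate_pileup <- function(x) {
  need <- c("contig", "pos", "A", "C", "G", "T", "coverage")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("pileup is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(x$A < 0 | x$C < 0 | x$G < 0 | x$T < 0)) {
    abort("pileup counts must be non-negative")
  }
  if (any(x$coverage != x$A + x$C + x$G + x$T)) {
    abort("pileup coverage must equal A + C + G + T at every position")
  }
  if (anyDuplicated(paste(x$contig, x$pos))) {
    abort("pileup has duplicate (contig, pos) records")
  }
  sorted <- dplyr::arrange(as_tibble(x), .data$contig, .data$pos)
  if (!identical(paste(sorted$contig, sorted$pos),
                 paste(x$contig, x$pos))) {
    abort("pileup records must be sorted by (contig, pos)")
  }
  x
}

#' Build a pileup matrix from aligned reads
#'
#' Counts, for every reference position, the reads whose aligned base matches
#' each nucleotide, after base- and mapping-quality cutoffs. CIGAR operations
#' follow SAM semantics (M/=/X consume reference and query, I query only,
#' D/N reference only and contribute no counts; soft clips are skipped).
#' Input must be coordinate-sorted and already duplicate-removed upstream.
#'
#' SAM input is converted to sorted BAM on the fly; BAM input must carry
#' `SO:coordinate` in its header.
#'
#' @param path a SAM or BAM file of aligned reads.
#' @param min_base_quality minimum Phred base quality for a base to be
#'   counted (default 25).
#' @param min_mapping_quality minimum mapping quality for a read to be
#'   counted (default 10).
#' @inheritParams pileup_tbl
#' @return A `dart_pileup` tibble (see [pileup_tbl()]).
#' @examples
#' sam <- system.file("extdata", "toy.sam", package = "dartseq")
#' if (nzchar(sam)) build_pileup(sam)
#' @export
build_pileup <- function(path, min_base_quality = 25, min_mapping_quality = 10,
                         sample = NA_character_, replicate = NA_integer_,
                         condition = NA_character_) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]
    so <- hdr$text[["@HD"]]
    if (!is.null(so) && !any(grepl("SO:coordinate", so, fixed = TRUE))) {
      abort(paste0("BAM is not coordinate-sorted: ", path))
    }
    if (!file.exists(paste0(bam, ".bai"))) {
      Rsamtools::indexBam(bam)
    }
  }
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapping_quality),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  res <- Rsamtools::pileup(bam, pileupParam = pp)
  res <- res[res$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (nrow(res) == 0) {
    return(pileup_tbl(sample = sample, replicate = replicate,
                      condition = condition))
  }
  wide <- as_tibble(res) |>
    mutate(contig = as.character(.data$seqnames),
           nucleotide = as.character(.data$nucleotide)) |>
    select("contig", "pos", "nucleotide", "count") |>
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)
  for (nt in c("A", "C", "G", "T")) {
    if (!nt %in% names(wide)) wide[[nt]] <- 0L
  }
  pileup_tbl(wide$contig, wide$pos, wide$A, wide$C, wide$G, wide$T,
             sample = sample, replicate = replicate, condition = condition)
}

#' Pool pileup matrices by element-wise summation
#'
#' Positions present in any input appear in the output with counts and
#' coverage summed across inputs. Used to pool control replicates before
#' computing control edit ratios.
#'
#' @param matrices a non-empty list of `dart_pileup` tibbles.
#' @return A pooled `dart_pileup` tibble.
#' @export
pool_pileups <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("pool_pileups() needs a non-empty list of pileup matrices")
  }
  matrices <- lapply(matrices, validate_pileup)
  pooled <- bind_rows(lapply(matrices, as_tibble)) |>
    group_by(.data$contig, .data$pos) |>
    summarise(across(c("A", "C", "G", "T"), sum), .groups = "drop")
  pileup_tbl(pooled$contig, pooled$pos, pooled$A, pooled$C, pooled$G, pooled$T)
}

#' Read and write pileup matrices as TSV
#'
#' Tab-separated columns `contig, pos, A, C, G, T, coverage` with a `#`
#' header line stating the 1-based coordinate convention.
#' `read_pileup(write_pileup(x))` is the identity.
#'
#' @param x a `dart_pileup` tibble.
#' @param path output (input) file path.
#' @return `write_pileup()` returns `path` invisibly; `read_pileup()` a
#'   `dart_pileup` tibble.
#' @export
write_pileup <- function(x, path) {
  x <- validate_pileup(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#contig\tpos\tA\tC\tG\tT\tcoverage\t(pos is 1-based)", con)
  if (nrow(x)) {
    lines <- paste(x$contig, x$pos, x$A, x$C, x$G, x$T, x$coverage, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) return(pileup_tbl())
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7)
  if (length(bad)) {
    abort(paste0("malformed pileup line ", lineno[bad[1]], " in ", path,
                 ": expected 7 tab-separated fields"))
  }
  m <- matrix(unlist(parts), ncol = 7, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:7, drop = FALSE], 2, as.integer))
  num <- matrix(num, ncol = 6)
  if (anyNA(num)) {
    bad <- lineno[which(rowSums(is.na(num)) > 0)[1]]
    abort(paste0("malformed pileup line ", bad, " in ", path,
                 ": non-integer field"))
  }
  out <- pileup_tbl(m[, 1], num[, 1], num[, 2], num[, 3], num[, 4], num[, 5])
  if (any(out$coverage != num[, 6])) {
    abort(paste0("malformed pileup in ", path,
                 ": coverage column does not equal A+C+G+T"))
  }
  out
}
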