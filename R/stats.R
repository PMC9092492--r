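#' Metagene profile of a site set
#'
#' Each exonic site of a coding gene contributes once at its metagene
#' coordinate ([meta_coordinate()]): 5'UTR, CDS and 3'UTR rescaled to
#' `[0,1)`, `[1,2)` and `[2,3)`. The profile reports per-bin density
#' (fraction of mapped sites; sums to 1 when any site maps). m6A-like site
#' sets peak around the stop codon (meta ~2) and the proximal 3'UTR.
#'
#' @param sites a site tibble with `contig`, `pos`.
#' @param index a [gene_index()].
#' @param bins_per_region bins per transcript region (default 50, i.e. 150
#'   bins overall).
#' @return A tibble of class `dart_metagene` with columns `bin_start`,
#'   `bin_end`, `count`, `density` and attributes `n_sites_used`,
#'   `n_sites_total`.
#' @export
metagene_profile <- function(sites, index, bins_per_region = 50L) {
  loc <- locate_sites(sites[, c("contig", "pos")], index)
  use <- loc$region %in% c("5UTR", "CDS", "3UTR")
  nb <- 3L * as.integer(bins_per_region)
  edges <- seq(0, 3, length.out = nb + 1L)
  out <- tibble(bin_start = edges[-(nb + 1L)], bin_end = edges[-1L],
                count = 0L, density = NA_real_)
  n_used <- sum(use)
  if (n_used > 0) {
    meta <- meta_coordinate(loc$contig[use], loc$pos[use], index,
                            transcript_id = loc$transcript_id[use])
    # epsilon guards against boundary meta values landing one bin low
    # through floating-point division
    bin <- pmin(floor(meta / 3 * nb + 1e-9) + 1L, nb)
    tab <- tabulate(bin, nbins = nb)
    out$count <- tab
    out$density <- tab / n_used
  }
  attr(out, "n_sites_used") <- n_used
  attr(out, "n_sites_total") <- nrow(sites)
  attr(out, "bins_per_region") <- as.integer(bins_per_region)
  class(out) <- c("dart_metagene", class(tibble()))
  out
}

#' Signed distances from edit sites to the nearest reference site
#'
#' For each edit site, the signed offset to the nearest reference site
#' (e.g. miCLIP-called m6A) on the same contig and strand within a window
#' of `window` nt. Offsets are transcript-strand aware: positive means the
#' edit site lies 3' of the reference site. Edit sites with no reference
#' site within the window are excluded and tallied.
#'
#' @param sites a site tibble with `contig`, `pos`, `strand`.
#' @param reference a tibble with `contig`, `pos`, `strand`, or a BED6
#'   path. Reference sites without strand are resolved via `index`.
#' @param index optional [gene_index()] for strand resolution.
#' @param window half-width of the window in nt (default 1000).
#' @return A tibble of class `dart_distance` with columns `offset`
#'   (`-window .. window`) and `count`, plus attributes `n_used` and
#'   `n_excluded`.
#' @export
distance_to_reference <- function(sites, reference, index = NULL,
                                  window = 1000L) {
  if (window <= 0) abort("window must be a positive number of nucleotides")
  if (is.character(reference)) reference <- read_sites_bed(reference)
  ref <- as_tibble(reference)
  if (!"strand" %in% names(ref) || all(is.na(ref$strand)) ||
      all(ref$strand == "*")) {
    if (is.null(index)) {
      abort("reference sites carry no strand and no index was supplied")
    }
    ref$strand <- locate_sites(ref[, c("contig", "pos")], index)$strand
  }
  ref <- filter(ref, .data$strand %in% c("+", "-"))
  s <- filter(as_tibble(sites), .data$strand %in% c("+", "-"))

  offsets <- rep(NA_integer_, nrow(s))
  grp_s <- paste(s$contig, s$strand)
  grp_r <- paste(ref$contig, ref$strand)
  for (g in unique(grp_s)) {
    i <- which(grp_s == g)
    rp <- sort(ref$pos[grp_r == g])
    if (!length(rp)) next
    k <- findInterval(s$pos[i], rp)
    lo <- ifelse(k >= 1, rp[pmax(k, 1)], NA_integer_)
    hi <- ifelse(k < length(rp), rp[pmin(k + 1, length(rp))], NA_integer_)
    dlo <- s$pos[i] - lo                       # >= 0, distance to 5' (genomic)
    dhi <- hi - s$pos[i]
    # nearest by absolute distance; ties resolved toward the genomic-left site
    pick_lo <- !is.na(dlo) & (is.na(dhi) | dlo <= dhi)
    d <- ifelse(pick_lo, dlo, -dhi)            # genomic signed: site - ref
    offsets[i] <- as.integer(d)
  }
  signed <- if_else(s$strand == "+", offsets, -offsets)
  inwin <- !is.na(signed) & abs(signed) <= window
  tab <- table(factor(signed[inwin], levels = seq(-window, window)))
  out <- tibble(offset = as.integer(seq(-window, window)),
                count = as.integer(tab))
  attr(out, "n_used") <- sum(inwin)
  attr(out, "n_excluded") <- nrow(s) - sum(inwin)
  class(out) <- c("dart_distance", class(tibble()))
  out
}

#' Shuffle edit sites within the exons of their transcripts
#'
#' The permutation null of the distance analysis: for each transcript
#' carrying edit sites, the same number of sites is re-placed uniformly at
#' random (without replacement) over that transcript's exonic positions.
#' Per-transcript site counts and exon containment are conserved;
#' deterministic under a fixed seed.
#'
#' @param sites a site tibble with `contig`, `pos` (and optionally
#'   `transcript_id`; resolved via `index` otherwise).
#' @param index a [gene_index()].
#' @param seed optional integer seed.
#' @return `sites` with `pos` replaced by shuffled positions, sorted by
#'   `(contig, pos)`.
#' @export
shuffle_sites <- function(sites, index, seed = NULL) {
  do_shuffle <- function() {
    s <- as_tibble(sites)
    if (!"transcript_id" %in% names(s) || anyNA(s$transcript_id)) {
      s$transcript_id <- locate_sites(s[, c("contig", "pos")],
                                      index)$transcript_id
    }
    if (anyNA(s$transcript_id)) {
      abort("some sites are not assigned to any transcript")
    }
    txs <- index$transcripts
    for (tid in unique(s$transcript_id)) {
      i <- which(s$transcript_id == tid)
      L <- txs$exonic_len[match(tid, txs$transcript_id)]
      if (is.na(L) || L < length(i)) {
        abort(paste0("transcript ", tid,
                     " has too little exonic space to place ", length(i),
                     " sites"))
      }
      off <- sample.int(L, length(i), replace = FALSE)
      s$pos[i] <- tx_to_genomic(index$exons, rep(tid, length(i)), off)
    }
    arrange(s, .data$contig, .data$pos)
  }
  if (is.null(seed)) do_shuffle() else withr::with_seed(seed, do_shuffle())
}

#' Compare two edit-ratio distributions (Wilcoxon rank-sum)
#'
#' Mann-Whitney U with midranks for ties; the p-value is exact when
#' `min(n, m) <= 8` and there are no ties, and uses the normal
#' approximation with tie and continuity corrections otherwise. ECDF
#' tables are returned for cumulative-distribution plotting.
#'
#' @param a,b non-empty numeric vectors (e.g. per-site editing
#'   percentages under two conditions).
#' @return A list of class `dart_ratio_test`: `u_statistic`, `p_value`,
#'   `n_a`, `n_b`, `method`, and `ecdf` (tibble `group`, `value`, `ecdf`).
#' @export
compare_ratio_distributions <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  ec <- bind_rows(
    tibble(group = "a", value = sort(a), ecdf = ecdf(a)(sort(a))),
    tibble(group = "b", value = sort(b), ecdf = ecdf(b)(sort(b))))
  structure(list(u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_a = length(a), n_b = length(b),
                 method = if (exact) "exact" else "normal approximation",
                 ecdf = ec),
            class = "dart_ratio_test")
}

#' @export
print.dart_ratio_test <- function(x, ...) {
  cat("Wilcoxon rank-sum (", x$method, "): U = ", x$u_statistic,
      ", p = ", signif(x$p_value, 4), " (n = ", x$n_a, " vs ", x$n_b, ")\n",
      sep = "")
  invisible(x)
}

#' Consensus and pairwise overlap of gene sets
#'
#' Used to compare methylated-transcript lists across studies: the
#' consensus contains genes present in at least `min_support` of the input
#' sets (e.g. RNAs with called m6A peaks in at least two of three
#' antibody-based studies). Identifiers are matched case-insensitively.
#'
#' @param sets a named list of character vectors of gene identifiers.
#' @param min_support minimum number of sets a gene must appear in.
#' @return A list of class `dart_overlap`: `consensus` (sorted character
#'   vector), `support` (tibble `gene`, `n_sets`), and `pairwise` (tibble
#'   `set_a`, `set_b`, `overlap`).
#' @export
gene_set_overlap <- function(sets, min_support = 2L) {
  if (!is.list(sets) || length(sets) == 0) {
    abort("sets must be a non-empty named list")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  if (min_support > length(sets)) {
    abort("min_support exceeds the number of sets")
  }
  norm <- lapply(sets, function(g) unique(toupper(as.character(g))))
  support <- tibble(gene = unlist(norm, use.names = FALSE)) |>
    count(.data$gene, name = "n_sets") |>
    arrange(.data$gene)
  consensus <- sort(support$gene[support$n_sets >= min_support])
  nm <- names(norm)
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2) else
    matrix(character(), nrow = 2)
  pairwise <- tibble(
    set_a = pairs[1, ], set_b = pairs[2, ],
    overlap = if (ncol(pairs)) {
      vapply(seq_len(ncol(pairs)), function(j) {
        length(intersect(norm[[pairs[1, j]]], norm[[pairs[2, j]]]))
      }, integer(1))
    } else integer()
  )
  structure(list(consensus = consensus, support = support,
                 pairwise = pairwise),
            class = "dart_overlap")
}

#' @export
print.dart_overlap <- function(x, ...) {
  cat("<dart_overlap> consensus of", length(x$consensus), "genes\n")
  print(x$pairwise)
  invisible(x)
}
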