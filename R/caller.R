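#' Thresholds for the edit-site caller
#'
#' Bundles every threshold of the site-calling procedure. Defaults follow
#' the standard DART-seq filtering scheme: at least 10 reads of coverage at
#' the site, an edit ratio between 5% and 95% (inclusive), an edit ratio at
#' least 1.2-fold higher than in the control sample, at least 2 edited
#' reads, and detection in at least 2 replicates.
#'
#' @param edit_type `"C2U"` (APOBEC1-style cytidine deamination, the edited
#'   cytidine immediately 3' of the methylated adenosine) or `"A2I"`
#'   (ADARcd-style adenosine deamination read out as A-to-G).
#' @param min_coverage minimum `n_ref + n_alt` in the DART sample.
#' @param ratio_low,ratio_high inclusive edit-ratio bounds.
#' @param min_fold minimum `edit_ratio / control_ratio`; a control ratio of
#'   exactly 0 (with adequate control coverage) passes by convention.
#' @param min_alt_reads minimum number of edited reads.
#' @param min_control_coverage minimum `n_ref + n_alt` in the control; sites
#'   with less control coverage are not callable (enrichment cannot be
#'   assessed).
#' @param min_replicates replicate-concordance threshold used by
#'   [merge_replicates()].
#' @param control_kind `"mut"` (editing-deficient YTHmut fusion control) or
#'   `"blocking"` (YTH-domain pre-blocking control); metadata only — the
#'   enrichment computation is identical for both.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(edit_type = c("C2U", "A2I"),
                          min_coverage = 10L,
                          ratio_low = 0.05, ratio_high = 0.95,
                          min_fold = 1.2,
                          min_alt_reads = 2L,
                          min_control_coverage = 10L,
                          min_replicates = 2L,
                          control_kind = c("mut", "blocking")) {
  edit_type <- match.arg(edit_type)
  control_kind <- match.arg(control_kind)
  if (!(ratio_low >= 0 && ratio_low < ratio_high && ratio_high <= 1)) {
    abort("need 0 <= ratio_low < ratio_high <= 1")
  }
  if (min_fold < 1) abort("min_fold must be >= 1")
  if (min_coverage < 0 || min_alt_reads < 0 || min_control_coverage < 0 ||
      min_replicates < 1) {
    abort("count thresholds must be non-negative (min_replicates >= 1)")
  }
  structure(list(edit_type = edit_type,
                 min_coverage = as.integer(min_coverage),
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 min_fold = min_fold,
                 min_alt_reads = as.integer(min_alt_reads),
                 min_control_coverage = as.integer(min_control_coverage),
                 min_replicates = as.integer(min_replicates),
                 control_kind = control_kind),
            class = "caller_params")
}

# transcript-strand ref/alt pair expressed on the reference plus strand
edit_bases <- function(edit_type, strand) {
  if (edit_type == "C2U") {
    ref <- if_else(strand == "+", "C", "G")
    alt <- if_else(strand == "+", "T", "A")
  } else {
    ref <- if_else(strand == "+", "A", "T")
    alt <- if_else(strand == "+", "G", "C")
  }
  list(ref = ref, alt = alt)
}

#' Edit ratio of a position
#'
#' The fraction of informative reads carrying the edited base:
#' `n_alt / (n_ref + n_alt)`. Reads carrying neither the reference nor the
#' edited base (unrelated mismatches, sequencing error) are excluded from
#' the denominator.
#'
#' @param n_ref,n_alt read counts of the reference and edited base.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
compute_edit_ratio <- function(n_ref, n_alt) {
  tot <- n_ref + n_alt
  if (any(tot == 0)) {
    abort("edit ratio undefined: n_ref + n_alt is 0")
  }
  n_alt / tot
}

#' Call candidate edit sites from one sample/control pileup pair
#'
#' Scans annotated, strand-resolvable positions for C-to-U (or A-to-I)
#' editing enriched over the control. A site is emitted iff all of:
#' `n_ref + n_alt >= min_coverage` in the sample; `n_alt >= min_alt_reads`;
#' `ratio_low <= edit_ratio <= ratio_high`; control `n_ref + n_alt >=
#' min_control_coverage`; and `edit_ratio >= min_fold * control_ratio`
#' (a control ratio of 0 passes). Positions outside annotated genes are not
#' callable (strand, hence the ref/alt pair, is ambiguous). When `genome`
#' is supplied, positions whose strand-corrected reference base does not
#' match the edit type's source base are additionally skipped.
#'
#' Control replicates are usually pooled with [pool_pileups()] first, which
#' maximises control coverage for the enrichment test.
#'
#' @param sample,control `dart_pileup` tibbles on the same genome.
#' @param index a [gene_index()].
#' @param params a [caller_params()].
#' @param genome optional genome as a [Biostrings::DNAStringSet] or FASTA
#'   path.
#' @return A site tibble: `contig, pos, strand, ref, alt, n_ref, n_alt,
#'   coverage, edit_ratio, control_ratio, fold, gene_id, region, motif,
#'   replicate_support, edit_type`. `fold` is `Inf` where the control ratio
#'   is 0.
#' @export
call_sites <- function(sample, control, index, params = caller_params(),
                       genome = NULL) {
  sample <- validate_pileup(sample)
  control <- validate_pileup(control)
  if (!inherits(index, "gene_index")) {
    abort("call_sites() needs an annotation gene_index")
  }
  if (!inherits(params, "caller_params")) abort("params must be caller_params")
  if (nrow(sample) && nrow(control) &&
      !length(intersect(unique(sample$contig), unique(control$contig)))) {
    abort("sample and control pileups share no contig: genome mismatch?")
  }
  empty <- tibble(contig = character(), pos = integer(), strand = character(),
                  ref = character(), alt = character(), n_ref = integer(),
                  n_alt = integer(), coverage = integer(),
                  edit_ratio = double(), control_ratio = double(),
                  fold = double(), gene_id = character(), region = character(),
                  motif = character(), replicate_support = integer(),
                  edit_type = character())
  if (nrow(sample) == 0) return(site_set(empty, params))

  loc <- locate_sites(sample[, c("contig", "pos")], index)
  x <- as_tibble(sample)
  x$strand <- loc$strand
  x$gene_id <- loc$gene_id
  x$region <- loc$region
  x <- filter(x, !is.na(.data$strand))
  if (nrow(x) == 0) return(site_set(empty, params))

  eb <- edit_bases(params$edit_type, x$strand)
  x$ref <- eb$ref
  x$alt <- eb$alt
  cnt <- as.matrix(x[, c("A", "C", "G", "T")])
  x$n_ref <- cnt[cbind(seq_len(nrow(x)), match(x$ref, c("A", "C", "G", "T")))]
  x$n_alt <- cnt[cbind(seq_len(nrow(x)), match(x$alt, c("A", "C", "G", "T")))]

  if (!is.null(genome)) {
    genome <- load_genome(genome)
    miss <- setdiff(unique(x$contig), names(genome))
    if (length(miss)) {
      abort(paste0("contig absent from genome: ", miss[1]))
    }
    x <- filter(x, genome_base(genome, .data$contig, .data$pos) == .data$ref)
  }

  ctl <- as_tibble(control)
  x <- left_join(x,
                 ctl |> select("contig", "pos", ctl_A = "A", ctl_C = "C",
                               ctl_G = "G", ctl_T = "T"),
                 by = c("contig", "pos"))
  ctlcnt <- as.matrix(x[, c("ctl_A", "ctl_C", "ctl_G", "ctl_T")])
  ctlcnt[is.na(ctlcnt)] <- 0L
  x$ctl_ref <- ctlcnt[cbind(seq_len(nrow(x)),
                            match(x$ref, c("A", "C", "G", "T")))]
  x$ctl_alt <- ctlcnt[cbind(seq_len(nrow(x)),
                            match(x$alt, c("A", "C", "G", "T")))]

  x <- filter(x,
              .data$n_ref + .data$n_alt >= params$min_coverage,
              .data$n_alt >= params$min_alt_reads,
              .data$ctl_ref + .data$ctl_alt >= params$min_control_coverage)
  if (nrow(x) == 0) return(site_set(empty, params))
  x$edit_ratio <- compute_edit_ratio(x$n_ref, x$n_alt)
  x$control_ratio <- compute_edit_ratio(x$ctl_ref, x$ctl_alt)
  # inclusive fold boundary: guard against rounding at exact equality
  x <- filter(x,
              .data$edit_ratio >= params$ratio_low,
              .data$edit_ratio <= params$ratio_high,
              .data$edit_ratio >=
                params$min_fold * .data$control_ratio - 1e-9)
  if (nrow(x) == 0) return(site_set(empty, params))
  x$fold <- if_else(x$control_ratio > 0,
                    x$edit_ratio / x$control_ratio, Inf)
  out <- x |>
    mutate(motif = NA_character_, replicate_support = 1L,
           edit_type = params$edit_type) |>
    select("contig", "pos", "strand", "ref", "alt", "n_ref", "n_alt",
           "coverage", "edit_ratio", "control_ratio", "fold", "gene_id",
           "region", "motif", "replicate_support", "edit_type") |>
    arrange(.data$contig, .data$pos)
  site_set(out, params)
}

site_set <- function(x, params = NULL) {
  key <- paste(x$contig, x$pos, x$strand, x$edit_type)
  if (anyDuplicated(key)) abort("duplicate site keys in site set")
  if (!is.null(params)) attr(x, "params") <- params
  class(x) <- unique(c("dart_sites", class(tibble())))
  x
}

site_key <- function(x) paste(x$contig, x$pos, x$strand, x$edit_type)

#' Merge per-replicate site sets by concordance
#'
#' Keeps sites called in at least `min_replicates` replicate site sets
#' (sites found in only one replicate are removed under the default of 2).
#' For retained sites, read counts are summed over the supporting
#' replicates while `edit_ratio` and `control_ratio` are the arithmetic
#' means of the per-replicate values; `replicate_support` records the
#' number of supporting replicates.
#'
#' @param site_sets list of site tibbles from [call_sites()], one per
#'   replicate, called with identical parameters.
#' @param min_replicates minimum number of replicates a site must appear in.
#' @return A merged site tibble.
#' @export
merge_replicates <- function(site_sets, min_replicates = 2L) {
  if (!is.list(site_sets) || length(site_sets) == 0) {
    abort("merge_replicates() needs a non-empty list of site sets")
  }
  et <- unique(unlist(lapply(site_sets, function(s) unique(s$edit_type))))
  if (length(et) > 1) {
    abort("cannot merge site sets with different edit types")
  }
  merged <- bind_rows(lapply(site_sets, as_tibble)) |>
    group_by(.data$contig, .data$pos, .data$strand, .data$ref, .data$alt,
             .data$edit_type) |>
    filter(n() >= min_replicates) |>
    summarise(n_ref = sum(.data$n_ref), n_alt = sum(.data$n_alt),
              coverage = sum(.data$coverage),
              edit_ratio = mean(.data$edit_ratio),
              control_ratio = mean(.data$control_ratio),
              fold = mean(.data$fold),
              gene_id = .data$gene_id[1], region = .data$region[1],
              motif = .data$motif[1],
              replicate_support = n(), .groups = "drop") |>
    select("contig", "pos", "strand", "ref", "alt", "n_ref", "n_alt",
           "coverage", "edit_ratio", "control_ratio", "fold", "gene_id",
           "region", "motif", "replicate_support", "edit_type") |>
    arrange(.data$contig, .data$pos)
  params <- attr(site_sets[[1]], "params")
  site_set(merged, params)
}
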