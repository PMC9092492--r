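load_pileup_input <- function(x) {
  if (is.data.frame(x)) return(validate_pileup(x))
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
      return(build_pileup(x))
    }
    return(read_pileup(x))
  }
  abort("pileup inputs must be tibbles or SAM/BAM/TSV paths")
}

load_sites_input <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.bed$", x, ignore.case = TRUE)) {
      s <- read_sites_bed(x)
      s$edit_type <- NA_character_
      return(s)
    }
    return(read_sites(x))
  }
  abort("site inputs must be tibbles or TSV/BED paths")
}

#' Run the full site-calling pipeline
#'
#' Orchestrates the standard analysis: per-replicate site calling against
#' the pooled control, replicate-concordance merging, RAC-motif filtering
#' (C2U only), blacklist subtraction, and site-set characterisation
#' (metagene profile and, when reference sites are given, the distance
#' histogram with its within-exon shuffle null). Every stage's site table
#' is written for auditability and the run log records parameters, input
#' checksums and per-stage site counts, which are monotone non-increasing
#' across the filtering stages.
#'
#' @param samples list of DART replicate pileups (tibbles or SAM/BAM/TSV
#'   paths).
#' @param controls list of control replicate pileups (pooled before the
#'   enrichment test). Required whenever `params$min_fold > 1`.
#' @param annotation a [gene_index()] or GTF/BED12 path.
#' @param genome a `DNAStringSet` or FASTA path (required for the motif
#'   filter).
#' @param params a [caller_params()].
#' @param blacklists optional list of deaminase-alone site tables (tibbles
#'   or TSV/BED paths); removal is by exact position key, any-replicate
#'   rule.
#' @param reference_sites optional reference m6A sites (tibble or BED
#'   path) for the distance analysis.
#' @param apply_motif_filter apply the RAC filter (default: yes for C2U,
#'   refused for A2I).
#' @param out_dir output directory.
#' @param seed integer seed (drives the shuffle null).
#' @param distance_window half-width (nt) of the distance histogram.
#' @return Invisibly, a list with the final `sites` tibble, per-stage
#'   `counts`, the `metagene` profile and (optionally) `distance` and
#'   `distance_null` histograms.
#' @export
run_pipeline <- function(samples, controls, annotation, genome = NULL,
                         params = caller_params(), blacklists = list(),
                         reference_sites = NULL,
                         apply_motif_filter = params$edit_type == "C2U",
                         out_dir = ".", seed = 1L, distance_window = 1000L) {
  if (params$edit_type == "A2I" && apply_motif_filter) {
    abort("motif filter not applicable to A2I site sets")
  }
  if (params$min_fold > 1 && (is.null(controls) || length(controls) == 0)) {
    abort("a control sample is required when min_fold > 1")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("dartseq ", as.character(utils::packageVersion("dartseq"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", seed),
    paste0("params: ", paste(names(unclass(params)), unlist(params),
                             sep = "=", collapse = " ")))

  index <- if (inherits(annotation, "gene_index")) annotation else
    read_annotation(annotation)
  if (!is.null(genome)) genome <- load_genome(genome)
  samples <- lapply(samples, load_pileup_input)
  controls <- lapply(controls, load_pileup_input)
  checksum <- function(x) {
    sum(as.double(x$coverage)) + nrow(x)  # cheap content fingerprint
  }
  log_lines <- c(log_lines,
                 paste0("input checksums: sample=",
                        paste(vapply(samples, checksum, double(1)),
                              collapse = ","),
                        " control=",
                        paste(vapply(controls, checksum, double(1)),
                              collapse = ",")))

  pooled_control <- pool_pileups(controls)
  per_rep <- lapply(samples, call_sites, control = pooled_control,
                    index = index, params = params, genome = genome)
  merged <- merge_replicates(per_rep, params$min_replicates)
  counts <- c(called = sum(vapply(per_rep, nrow, integer(1))),
              concordant = nrow(merged))
  if (!is.null(genome)) {
    merged$motif <- motif_context(merged, genome)
  }
  write_sites(merged, file.path(out_dir, "sites_concordant.tsv"))

  after_motif <- merged
  if (apply_motif_filter) {
    if (is.null(genome)) abort("motif filter needs a genome")
    after_motif <- filter_motif(merged, genome)
  }
  counts <- c(counts, motif = nrow(after_motif))
  write_sites(after_motif, file.path(out_dir, "sites_motif.tsv"))

  blacklists <- lapply(blacklists, load_sites_input)
  blacklists <- lapply(blacklists, function(b) {
    if (!"edit_type" %in% names(b) || all(is.na(b$edit_type))) {
      b$edit_type <- params$edit_type
    }
    b
  })
  final <- filter_blacklist(after_motif, blacklists)
  counts <- c(counts, blacklist = nrow(final))
  write_sites(final, file.path(out_dir, "sites_final.tsv"))
  write_sites_bed(final, file.path(out_dir, "sites_final.bed"))

  mg <- metagene_profile(final, index)
  write_stats_tsv(mg, file.path(out_dir, "metagene.tsv"))

  dist <- dist_null <- NULL
  if (!is.null(reference_sites)) {
    refs <- if (is.character(reference_sites)) {
      read_sites_bed(reference_sites)
    } else as_tibble(reference_sites)
    dist <- distance_to_reference(final, refs, index,
                                  window = distance_window)
    write_stats_tsv(dist, file.path(out_dir, "distance.tsv"))
    shuf <- shuffle_sites(final, index, seed = seed)
    dist_null <- distance_to_reference(shuf, refs, index,
                                       window = distance_window)
    write_stats_tsv(dist_null, file.path(out_dir, "distance_null.tsv"))
  }

  log_lines <- c(log_lines,
                 paste0("sites after calling (all replicates): ",
                        counts[["called"]]),
                 paste0("sites after replicate concordance: ",
                        counts[["concordant"]]),
                 paste0("sites after motif filter: ", counts[["motif"]]),
                 paste0("sites after blacklist: ", counts[["blacklist"]]))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(list(sites = final, counts = counts, metagene = mg,
                 distance = dist, distance_null = dist_null))
}
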