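#' Read and write site tables
#'
#' Tab-separated site tables with 1-based positions and a `#` comment
#' header stating the convention; `read_sites(write_sites(x))` recovers the
#' table exactly. BED output is 0-based half-open with
#' `score = round(1000 * edit_ratio)`.
#'
#' @param sites a site tibble (see [call_sites()]).
#' @param path file path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @export
write_sites <- function(sites, path) {
  body <- readr::format_tsv(as_tibble(sites))
  writeLines(c("# dartseq site table; pos is 1-based",
               strsplit(body, "\n", fixed = TRUE)[[1]]),
             path)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  out <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(
      contig = readr::col_character(), pos = readr::col_integer(),
      strand = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), n_ref = readr::col_integer(),
      n_alt = readr::col_integer(), coverage = readr::col_integer(),
      edit_ratio = readr::col_double(), control_ratio = readr::col_double(),
      fold = readr::col_double(), gene_id = readr::col_character(),
      region = readr::col_character(), motif = readr::col_character(),
      replicate_support = readr::col_integer(),
      edit_type = readr::col_character()),
    progress = FALSE)
  site_set(out)
}

#' @rdname write_sites
#' @export
write_sites_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dartseq sites; BED6, 0-based half-open", con)
  if (nrow(sites)) {
    name <- if_else(is.na(sites$gene_id), ".", sites$gene_id)
    lines <- paste(sites$contig, sites$pos - 1L, sites$pos, name,
                   round(1000 * sites$edit_ratio), sites$strand, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read single-nucleotide sites from a BED file
#'
#' For reference m6A site lists (e.g. miCLIP calls). Positions are
#' converted to the 1-based coordinate of the interval end; strand is kept
#' when present.
#'
#' @param path a BED file (at least 3 columns; strand read from column 6).
#' @return A tibble with `contig`, `pos`, `strand`.
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines)) {
    return(tibble(contig = character(), pos = integer(),
                  strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(paste0("malformed BED line ", bad[1], " in ", path))
  }
  tibble(
    contig = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 3)),
    strand = vapply(parts, function(p) {
      if (length(p) >= 6 && p[6] %in% c("+", "-")) p[6] else NA_character_
    }, character(1)))
}

#' Write a metagene profile, distance histogram or ECDF table as TSV
#'
#' @param x a `dart_metagene`, `dart_distance` or `dart_ratio_test` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(x, path) {
  tab <- if (inherits(x, "dart_ratio_test")) x$ecdf else as_tibble(x)
  readr::write_tsv(tab, path)
  invisible(path)
}
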