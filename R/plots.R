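#' Plot a metagene profile
#'
#' Per-bin site density over the rescaled transcript: 5'UTR `[0,1)`, CDS
#' `[1,2)`, 3'UTR `[2,3)`; m6A-like sets peak near the stop codon (x = 2).
#'
#' @param object a `dart_metagene` from [metagene_profile()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.dart_metagene <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(0.5, 1.5, 2.5), labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "site density",
                  title = "Metagene distribution of edit sites")
}

#' Plot a distance histogram
#'
#' Counts of edit sites at each signed offset from the nearest reference
#' site (positive = 3' of the reference on the transcript strand).
#'
#' @param object a `dart_distance` from [distance_to_reference()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.dart_distance <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "distance to nearest reference site (nt)",
                  y = "edit sites")
}

#' Plot cumulative edit-ratio distributions
#'
#' ECDFs of the two compared samples, annotated with the rank-sum p-value.
#'
#' @param object a `dart_ratio_test` from [compare_ratio_distributions()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.dart_ratio_test <- function(object, ...) {
  ggplot2::ggplot(object$ecdf,
                  ggplot2::aes(x = .data$value, y = .data$ecdf,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "edit ratio", y = "cumulative fraction",
                  subtitle = paste0("Wilcoxon rank-sum p = ",
                                    signif(object$p_value, 3)))
}

#' Tidy a rank-sum comparison
#'
#' @param x a `dart_ratio_test`.
#' @param ... ignored.
#' @return A one-row tibble with `u_statistic`, `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
tidy.dart_ratio_test <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, p_value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, method = x$method)
}

#' @rdname tidy.dart_ratio_test
#' @export
glance.dart_ratio_test <- function(x, ...) tidy(x)

#' Tidy a metagene profile
#'
#' @param x a `dart_metagene`.
#' @param ... ignored.
#' @return The per-bin tibble with region labels added.
#' @export
tidy.dart_metagene <- function(x, ...) {
  out <- as_tibble(x)
  out$region <- dplyr::case_when(out$bin_start < 1 ~ "5UTR",
                                 out$bin_start < 2 ~ "CDS",
                                 TRUE ~ "3UTR")
  out
}

#' Summarise a metagene profile
#'
#' @param x a `dart_metagene`.
#' @param ... ignored.
#' @return A one-row tibble with the number of mapped sites and the
#'   density mass per region.
#' @export
glance.dart_metagene <- function(x, ...) {
  td <- tidy(x)
  tibble(n_sites_used = attr(x, "n_sites_used"),
         n_sites_total = attr(x, "n_sites_total"),
         frac_5utr = sum(td$density[td$region == "5UTR"]),
         frac_cds = sum(td$density[td$region == "CDS"]),
         frac_3utr = sum(td$density[td$region == "3UTR"]))
}
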