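#' Per-read contact statistics
#'
#' Summarises usable (post-filter) contact records the way proximity-ligation
#' QC panels do: the distribution of mappings per read (mass at 2 for Hi-C,
#' long-tailed for Pore-C concatemers) and the distribution of alignment
#' lengths.
#'
#' @param records Tibble from [parse_alignments()] (columns `read_id`,
#'   `segment`, `mapq`, `aln_len`).
#' @return An object of class `contact_stats`: a list with tibbles
#'   `per_read` (`read_id`, `n_alignments`), `alignments_per_read`
#'   (`n_alignments`, `n_reads`) and `lengths` (`aln_len`, `n`).
#' @export
contact_stats <- function(records) {
  records <- tibble::as_tibble(records)
  per_read <- records |>
    dplyr::count(.data$read_id, name = "n_alignments")
  hist_n <- per_read |>
    dplyr::count(.data$n_alignments, name = "n_reads") |>
    dplyr::arrange(.data$n_alignments)
  lengths <- if ("aln_len" %in% names(records)) {
    records |>
      dplyr::count(.data$aln_len, name = "n") |>
      dplyr::arrange(.data$aln_len)
  } else {
    tibble::tibble(aln_len = integer(), n = integer())
  }
  structure(list(per_read = per_read, alignments_per_read = hist_n,
                 lengths = lengths),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  n_reads <- nrow(x$per_read)
  cat("<contact_stats> ", n_reads, " reads, ",
      sum(x$per_read$n_alignments), " usable alignments",
      if (n_reads > 0) {
        paste0("; mean alignments/read = ",
               signif(mean(x$per_read$n_alignments), 4))
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Signal ratio of contacts against a diploid truth
#'
#' Scores every unordered pair of mappings of one read as an edge, bins it
#' by the minimum mapping quality of the pair, and classifies it as
#' consistent when both reference contigs carry the same haplotype label of
#' the diploid truth (cis) and inconsistent when the edge crosses haplotypes
#' (trans). The signal ratio per bin is
#' `n_consistent / (n_consistent + n_inconsistent)`. Edges touching a
#' contig absent from the truth are skipped and counted. Relabelling the
#' two haplotypes globally leaves the table unchanged.
#'
#' @param records Tibble of alignments to the diploid reference (columns
#'   `read_id`, `segment`, `mapq`).
#' @param truth Tibble with columns `contig`, `haplotype` (each contig
#'   labelled exactly once), or a path to a 2-column TSV.
#' @return A tibble of class `signal_ratio_tbl` with columns `bin`
#'   (`"0"`..`"60"`, `"61+"`, and a final `"total"` row), `n_consistent`,
#'   `n_inconsistent`, `ratio`; the number of skipped edges is in
#'   `attr(, "n_skipped")`.
#' @export
signal_ratio <- function(records, truth) {
  if (is.character(truth) && length(truth) == 1L) {
    truth <- readr::read_tsv(truth, col_names = c("contig", "haplotype"),
                             col_types = "cc", progress = FALSE)
  }
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("contig", "haplotype") %in% names(truth)))
  if (anyDuplicated(truth$contig)) {
    stop("truth labels a contig more than once: ",
         paste(head(unique(truth$contig[duplicated(truth$contig)]), 5),
               collapse = ", "))
  }
  rec <- tibble::as_tibble(records)[, c("read_id", "segment", "mapq")] |>
    dplyr::mutate(.idx = dplyr::row_number())
  edges <- dplyr::inner_join(rec, rec, by = "read_id",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$.idx.x < .data$.idx.y)
  hap <- setNames(truth$haplotype, truth$contig)
  known <- edges$segment.x %in% names(hap) & edges$segment.y %in% names(hap)
  n_skipped <- sum(!known)
  edges <- edges[known, , drop = FALSE]
  binned <- edges |>
    dplyr::mutate(
      min_q = pmin(.data$mapq.x, .data$mapq.y),
      bin = ifelse(.data$min_q > 60L, "61+", as.character(.data$min_q)),
      consistent = hap[.data$segment.x] == hap[.data$segment.y]) |>
    dplyr::count(.data$bin, .data$consistent) |>
    tidyr::pivot_wider(names_from = "consistent", values_from = "n",
                       values_fill = 0L)
  for (col in c("TRUE", "FALSE")) {
    if (!col %in% names(binned)) binned[[col]] <- 0L
  }
  binned <- binned |>
    dplyr::transmute(.data$bin, n_consistent = .data$`TRUE`,
                     n_inconsistent = .data$`FALSE`) |>
    dplyr::arrange(suppressWarnings(as.integer(sub("\\+", "", .data$bin))))
  total <- tibble::tibble(bin = "total",
                          n_consistent = sum(binned$n_consistent),
                          n_inconsistent = sum(binned$n_inconsistent))
  out <- dplyr::bind_rows(binned, total) |>
    dplyr::mutate(ratio = ifelse(
      .data$n_consistent + .data$n_inconsistent > 0,
      .data$n_consistent / (.data$n_consistent + .data$n_inconsistent),
      NA_real_))
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("signal_ratio_tbl", class(out))
  out
}

#' @export
autoplot.contact_stats <- function(object, ...) {
  ggplot2::ggplot(object$alignments_per_read,
                  ggplot2::aes(x = .data$n_alignments, y = .data$n_reads)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "alignments per read", y = "reads",
                  title = "Usable mappings per proximity-ligation read") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.signal_ratio_tbl <- function(object, ...) {
  df <- dplyr::filter(object, .data$bin != "total") |>
    dplyr::mutate(min_q = suppressWarnings(
      as.integer(sub("\\+", "", .data$bin))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$min_q, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "minimum mapping quality of the pair",
                  y = "signal ratio (cis / all contacts)",
                  title = "Contact consistency vs diploid truth") +
    ggplot2::theme_minimal()
}
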