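#' Contact-parsing configuration
#'
#' @param min_mapq Minimum mapping quality for a usable record. Default 1
#'   (i.e. mapQ > 0), the usable-contact criterion used throughout.
#' @param max_alignments_per_read Reads mapping to more than this many
#'   distinct segments are skipped entirely when building the contact graph
#'   (quadratic blow-up guard for chimeric concatemers); at least 2.
#'   Default 50.
#' @param include_supplementary Keep supplementary alignments (0x800)?
#'   Default `FALSE` for phasing; Pore-C subreads aligned as supplementary
#'   records can be kept by setting `TRUE` (used by the QC module).
#' @return A list of class `contact_config`.
#' @export
contact_config <- function(min_mapq = 1L, max_alignments_per_read = 50L,
                           include_supplementary = FALSE) {
  stopifnot(min_mapq >= 0, max_alignments_per_read >= 2)
  structure(list(min_mapq = as.integer(min_mapq),
                 max_alignments_per_read = as.integer(max_alignments_per_read),
                 include_supplementary = isTRUE(include_supplementary)),
            class = "contact_config")
}

#' Parse proximity-ligation alignments into contact records
#'
#' Reads a SAM or BAM file of Hi-C / Pore-C alignments against the graph
#' segments and returns one record per usable alignment. Unmapped (0x4) and
#' secondary (0x100) records are always dropped; supplementary (0x800)
#' records are dropped unless `config$include_supplementary`. Records below
#' `min_mapq` are dropped. Hi-C mates and Pore-C subreads are unified by
#' read name, so downstream grouping is by `read_id`.
#'
#' @param alignment_file Path to a SAM or BAM file.
#' @param config A [contact_config()].
#' @param graph Optional [assembly_graph()]; records whose reference is not a
#'   graph segment are dropped with a counted warning.
#' @return Tibble with columns `read_id`, `segment`, `mapq`, `aln_len`,
#'   sorted by `read_id`.
#' @export
parse_alignments <- function(alignment_file, config = contact_config(),
                             graph = NULL) {
  if (!file.exists(alignment_file)) {
    stop("alignment file not found: ", alignment_file)
  }
  bam <- alignment_file
  if (grepl("\\.sam$", alignment_file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_file,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "flag", "rname", "mapq", "qwidth"))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  rec <- tibble::tibble(read_id = x$qname,
                        segment = as.character(x$rname),
                        mapq = as.integer(x$mapq),
                        aln_len = as.integer(x$qwidth),
                        flag = x$flag)
  if (!config$include_supplementary) {
    rec <- dplyr::filter(rec, bitwAnd(.data$flag, 2048L) == 0L)
  }
  rec <- dplyr::filter(rec, !is.na(.data$mapq), .data$mapq >= config$min_mapq)
  if (!is.null(graph)) {
    known <- rec$segment %in% graph$segments$name
    if (any(!known)) {
      warning(sum(!known), " record(s) aligned to segments absent from the ",
              "graph were dropped")
      rec <- rec[known, ]
    }
  }
  rec |>
    dplyr::select(-"flag") |>
    dplyr::arrange(.data$read_id, .data$segment)
}

#' Build a weighted contact graph from grouped contact records
#'
#' For every read with m distinct mapped segments, all choose(m, 2)
#' unordered segment pairs receive +1 weight; a Hi-C pair is the m = 2
#' special case and Pore-C concatemers accumulate contacts all-vs-all among
#' subreads. Self-contacts (all mappings on one segment) produce no edge.
#' Reads exceeding `max_alignments_per_read` distinct segments are skipped.
#'
#' @param records Tibble from [parse_alignments()] (columns `read_id`,
#'   `segment`; extra columns ignored).
#' @param config A [contact_config()].
#' @return Tibble with columns `seg_a`, `seg_b` (`seg_a < seg_b`), `weight`.
#' @export
build_contact_graph <- function(records, config = contact_config()) {
  rec <- dplyr::distinct(tibble::as_tibble(records)[, c("read_id", "segment")])
  rec <- rec |>
    dplyr::add_count(.data$read_id, name = "n_seg") |>
    dplyr::filter(.data$n_seg >= 2L,
                  .data$n_seg <= config$max_alignments_per_read) |>
    dplyr::select(-"n_seg")
  if (nrow(rec) == 0L) {
    return(tibble::tibble(seg_a = character(), seg_b = character(),
                          weight = integer()))
  }
  dplyr::inner_join(rec, rec, by = "read_id", relationship = "many-to-many") |>
    dplyr::filter(.data$segment.x < .data$segment.y) |>
    dplyr::count(seg_a = .data$segment.x, seg_b = .data$segment.y,
                 name = "weight") |>
    dplyr::mutate(weight = as.integer(.data$weight)) |>
    dplyr::arrange(.data$seg_a, .data$seg_b)
}

#' Read / write a contact graph as 3-column TSV
#'
#' @param contacts Contact graph tibble (`seg_a`, `seg_b`, `weight`).
#' @param path File path.
#' @return `read_contact_graph()` returns the tibble; `write_contact_graph()`
#'   returns `path` invisibly.
#' @export
write_contact_graph <- function(contacts, path) {
  readr::write_tsv(contacts, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(path) {
  readr::read_tsv(path, col_types = "cci", progress = FALSE) |>
    dplyr::transmute(a = pmin(.data$seg_a, .data$seg_b),
                     b = pmax(.data$seg_a, .data$seg_b),
                     weight = .data$weight) |>
    dplyr::rename(seg_a = "a", seg_b = "b") |>
    dplyr::arrange(.data$seg_a, .data$seg_b)
}
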