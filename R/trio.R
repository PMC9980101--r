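#' Trio-phasing configuration
#'
#' @param kmer_size K-mer size for parental matching; must be odd so no
#'   k-mer is its own reverse complement. Default 31.
#' @param min_votes Minimum absolute net k-mer lean to call a bubble.
#'   Default 3.
#' @param hom_threshold Minimum count in the donor parent for a k-mer to be
#'   treated as homozygous parental signal; the k-mer must be absent from
#'   the other parent. Default 2.
#' @return A list of class `trio_config`.
#' @export
trio_config <- function(kmer_size = 31L, min_votes = 3L, hom_threshold = 2L) {
  stopifnot(kmer_size >= 3, kmer_size <= 31, kmer_size %% 2 == 1,
            min_votes >= 1, hom_threshold >= 1)
  structure(list(kmer_size = as.integer(kmer_size),
                 min_votes = as.integer(min_votes),
                 hom_threshold = as.integer(hom_threshold)),
            class = "trio_config")
}

#' Read a k-mer count dump
#'
#' Plain-text `KMER<TAB>COUNT` dumps (as produced by standard k-mer
#' counters' dump commands) are the k-mer interchange format, so no external
#' counter is a hard dependency.
#'
#' @param path Path to a two-column TSV without header.
#' @return Tibble with columns `kmer`, `count`.
#' @export
read_kmer_dump <- function(path) {
  readr::read_tsv(path, col_names = c("kmer", "count"), col_types = "ci",
                  progress = FALSE)
}

#' Count canonical k-mers of a set of sequences
#'
#' @param seqs Character vector of DNA sequences.
#' @param k K-mer size.
#' @return Tibble with columns `kmer` (canonical), `count`.
#' @export
count_sequence_kmers <- function(seqs, k) {
  km <- unlist(lapply(seqs, canonical_kmers_cpp, k = as.integer(k)))
  if (length(km) == 0L) {
    return(tibble::tibble(kmer = character(), count = integer()))
  }
  tb <- table(km)
  tibble::tibble(kmer = names(tb), count = as.integer(tb)) |>
    dplyr::arrange(.data$kmer)
}

# canonicalize and aggregate a kmer/count tibble at size k
canonicalize_counts <- function(dump, k) {
  stopifnot(all(c("kmer", "count") %in% names(dump)))
  if (nrow(dump) == 0L) return(tibble::tibble(kmer = character(), count = integer()))
  if (!all(nchar(dump$kmer) == k)) {
    stop("k-mer dump contains k-mers of length != ", k,
         " (mismatched k between inputs and config)")
  }
  can <- pmin(toupper(dump$kmer), revcomp(toupper(dump$kmer)))
  tibble::tibble(kmer = can, count = dump$count) |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Build parent-unique k-mer sets
#'
#' A k-mer is paternal-unique when its count in the paternal input reaches
#' `hom_threshold` and it is absent from the maternal input (and
#' symmetrically for maternal-unique), so the two sets are disjoint by
#' construction. Inputs are canonicalized before subtraction.
#'
#' @param paternal,maternal K-mer count tibbles (`kmer`, `count`), e.g. from
#'   [read_kmer_dump()] or [count_sequence_kmers()].
#' @param config A [trio_config()].
#' @return A list of class `parent_kmer_sets` with character-vector fields
#'   `paternal_unique` and `maternal_unique` and the k-mer size `k`.
#' @export
build_parent_sets <- function(paternal, maternal, config = trio_config()) {
  k <- config$kmer_size
  pat <- canonicalize_counts(tibble::as_tibble(paternal), k)
  mat <- canonicalize_counts(tibble::as_tibble(maternal), k)
  pat_u <- pat$kmer[pat$count >= config$hom_threshold &
                      !(pat$kmer %in% mat$kmer)]
  mat_u <- mat$kmer[mat$count >= config$hom_threshold &
                      !(mat$kmer %in% pat$kmer)]
  structure(list(paternal_unique = pat_u, maternal_unique = mat_u,
                 k = k), class = "parent_kmer_sets")
}

#' @export
print.parent_kmer_sets <- function(x, ...) {
  cat("<parent_kmer_sets> k=", x$k, ": ", length(x$paternal_unique),
      " paternal-unique, ", length(x$maternal_unique),
      " maternal-unique k-mers\n", sep = "")
  invisible(x)
}

#' Vote parental origin for each bubble
#'
#' Counts canonical k-mer matches of each bubble side against each
#' parent-unique set and calls the bubble by the net lean
#' `(pat - mat on side0) - (pat - mat on side1)`: strongly positive means
#' paternal is side 0, strongly negative means paternal is side 1, and a
#' lean smaller than `min_votes` in absolute value (including ties) leaves
#' the bubble unphased. Voting is invariant to reverse-complementing a side,
#' and swapping the parents swaps every call.
#'
#' @param bubbles Bubble map tibble.
#' @param graph An [assembly_graph()] carrying side sequences.
#' @param parent_sets A [build_parent_sets()] result.
#' @param config A [trio_config()].
#' @return Tibble with one row per bubble: match counts `pat0`, `mat0`,
#'   `pat1`, `mat1`, the net `lean`, and `call` in
#'   `c("paternal_is_side0", "paternal_is_side1", "unphased")`.
#' @export
vote_bubbles <- function(bubbles, graph, parent_sets,
                         config = trio_config()) {
  stopifnot(inherits(parent_sets, "parent_kmer_sets"))
  if (parent_sets$k != config$kmer_size) {
    stop("parent sets were built at k=", parent_sets$k,
         " but config$kmer_size is ", config$kmer_size)
  }
  sides <- bubble_sides(bubbles)
  seqs <- setNames(graph$segments$sequence, graph$segments$name)
  bm <- tibble::as_tibble(bubbles)
  km_list <- lapply(seqs[bm$segment], canonical_kmers_cpp,
                    k = config$kmer_size)
  all_km <- tibble::tibble(
    bubble = rep(bm$bubble, lengths(km_list)),
    side = rep(bm$side, lengths(km_list)),
    kmer = unlist(km_list, use.names = FALSE))
  hits <- all_km |>
    dplyr::mutate(pat = .data$kmer %in% parent_sets$paternal_unique,
                  mat = .data$kmer %in% parent_sets$maternal_unique) |>
    dplyr::group_by(.data$bubble, .data$side) |>
    dplyr::summarise(pat = sum(.data$pat), mat = sum(.data$mat),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = c("pat", "mat"),
                       names_sep = "", values_fill = 0L)
  for (col in c("pat0", "pat1", "mat0", "mat1")) {
    if (!col %in% names(hits)) hits[[col]] <- 0L
  }
  res <- sides |>
    dplyr::left_join(hits, by = "bubble") |>
    dplyr::mutate(dplyr::across(c("pat0", "mat0", "pat1", "mat1"),
                                ~ tidyr::replace_na(.x, 0L)))
  res |>
    dplyr::mutate(
      lean = (.data$pat0 - .data$mat0) - (.data$pat1 - .data$mat1),
      call = dplyr::case_when(
        .data$lean >= config$min_votes ~ "paternal_is_side0",
        .data$lean <= -config$min_votes ~ "paternal_is_side1",
        TRUE ~ "unphased"))
}

#' Phase bubbles from parental k-mers
#'
#' Runs [vote_bubbles()] and converts the calls into a phase state with
#' orientation 0 when paternal is side 0. Unlike contact phasing, the trio
#' phase is globally anchored: haplotype 0 is the paternal haplotype
#' everywhere, with no global-flip ambiguity. Unphased bubbles keep
#' orientation 0 but are flagged unsupported.
#'
#' @inheritParams vote_bubbles
#' @return A `phase_fit` object (`method = "trio"`, `anchored = TRUE`); the
#'   vote table is attached as `$votes`.
#' @export
phase_by_trio <- function(bubbles, graph, parent_sets,
                          config = trio_config()) {
  votes <- vote_bubbles(bubbles, graph, parent_sets, config)
  fit_bubbles <- votes |>
    dplyr::transmute(.data$bubble, .data$side0, .data$side1,
                     orientation = ifelse(.data$call == "paternal_is_side1",
                                          1L, 0L),
                     merged_set = .data$bubble,
                     supported = .data$call != "unphased")
  fit <- new_phase_fit(fit_bubbles, method = "trio", anchored = TRUE,
                       objective = NA_real_, rounds = NULL, config = config)
  fit$votes <- votes
  fit
}
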