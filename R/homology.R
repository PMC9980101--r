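#' MinHash sketch parameters
#'
#' Parameters for homology-based bubble detection: candidate pairs are found
#' by comparing bottom-s MinHash sketches of canonical k-mer sets, then
#' refined with orientation-aware pairwise alignment.
#'
#' @param kmer_size K-mer size for sketching (>= 8). Default 22.
#' @param sketch_size Number of smallest hash values kept per sequence
#'   (>= 16). Default 128.
#' @param similarity_threshold Minimum estimated Jaccard similarity for a
#'   candidate pair, in (0, 1]. Default 0.05.
#' @param identity_threshold Minimum alignment identity for a refined bubble
#'   pair, in (0, 1]. Default 0.9.
#' @param seed Hash seed (determinism of the sketch). Default 1.
#' @return A list of class `sketch_params`.
#' @export
sketch_params <- function(kmer_size = 22, sketch_size = 128,
                          similarity_threshold = 0.05,
                          identity_threshold = 0.9, seed = 1L) {
  stopifnot(kmer_size >= 8, kmer_size <= 31, sketch_size >= 16,
            similarity_threshold > 0, similarity_threshold <= 1,
            identity_threshold > 0, identity_threshold <= 1)
  structure(list(kmer_size = as.integer(kmer_size),
                 sketch_size = as.integer(sketch_size),
                 similarity_threshold = similarity_threshold,
                 identity_threshold = identity_threshold,
                 seed = as.integer(seed)),
            class = "sketch_params")
}

new_bubble_map <- function(bubbles) {
  # bubbles: tibble(bubble, side0, side1)
  if (nrow(bubbles) == 0L) {
    return(tibble::tibble(segment = character(), bubble = integer(),
                          side = integer()))
  }
  out <- dplyr::bind_rows(
    tibble::tibble(segment = bubbles$side0, bubble = bubbles$bubble, side = 0L),
    tibble::tibble(segment = bubbles$side1, bubble = bubbles$bubble, side = 1L)
  ) |>
    dplyr::arrange(.data$bubble, .data$side)
  if (anyDuplicated(out$segment)) {
    stop("segment assigned to more than one bubble side: ",
         paste(head(unique(out$segment[duplicated(out$segment)]), 5),
               collapse = ", "))
  }
  out
}

# wide (one row per bubble) view of a bubble map
bubble_sides <- function(bubble_map) {
  bubble_map |>
    tidyr::pivot_wider(names_from = "side", values_from = "segment",
                       names_prefix = "side") |>
    dplyr::arrange(.data$bubble)
}

#' Build a bubble map from an assembler annotation table
#'
#' Accepts a sidecar annotation (segment, bubble id, side) as emitted by
#' assemblers that already phase locally, and converts it verbatim into a
#' bubble map. Bubbles with a number of members different from two are
#' dropped with a warning; a segment annotated into two bubbles is an error.
#'
#' @param graph An [assembly_graph()].
#' @param annotation Tibble (or TSV path) with columns `segment`, `bubble`,
#'   `side` (side in 0/1).
#' @return A bubble map tibble with columns `segment`, `bubble`, `side`.
#' @export
bubbles_from_annotation <- function(graph, annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- readr::read_tsv(annotation, col_names = c("segment",
                                                            "bubble", "side"),
                                  col_types = "cii", progress = FALSE)
  }
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("segment", "bubble", "side") %in% names(annotation)))
  missing <- setdiff(annotation$segment, graph$segments$name)
  if (length(missing) > 0) {
    stop("annotation references unknown segment(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (anyDuplicated(annotation$segment)) {
    stop("segment annotated into more than one bubble: ",
         paste(head(unique(annotation$segment[
           duplicated(annotation$segment)]), 5), collapse = ", "))
  }
  sizes <- dplyr::count(annotation, .data$bubble)
  bad <- sizes$bubble[sizes$n != 2L]
  if (length(bad) > 0) {
    warning(length(bad), " bubble(s) with a side count other than 2 dropped")
    annotation <- dplyr::filter(annotation, !.data$bubble %in% bad)
  }
  two_sided <- annotation |>
    dplyr::group_by(.data$bubble) |>
    dplyr::filter(dplyr::n_distinct(.data$side) == 2L) |>
    dplyr::ungroup()
  if (nrow(two_sided) < nrow(annotation)) {
    warning("bubble(s) with duplicated side labels dropped")
  }
  wide <- two_sided |>
    dplyr::arrange(.data$bubble, .data$side) |>
    dplyr::group_by(.data$bubble) |>
    dplyr::summarise(side0 = .data$segment[1L], side1 = .data$segment[2L],
                     .groups = "drop")
  new_bubble_map(wide)
}

# bottom-s sketch (sorted smallest distinct hash values) per segment
segment_sketches <- function(graph, params) {
  segs <- dplyr::filter(graph$segments, !is.na(.data$sequence),
                        .data$length >= params$kmer_size)
  sk <- lapply(segs$sequence, function(s) {
    h <- sort(unique(canonical_kmer_hashes_cpp(s, params$kmer_size,
                                               params$seed)))
    head(h, params$sketch_size)
  })
  setNames(sk, segs$name)
}

# bottom-s Jaccard estimate from two bottom-s sketches: among the s smallest
# values of the union, count those present in both
sketch_jaccard <- function(a, b, s) {
  u <- sort(unique(c(a, b)))
  u <- head(u, min(s, length(u)))
  if (length(u) == 0L) return(0)
  sum(u %in% a & u %in% b) / length(u)
}

#' Find candidate homologous segment pairs by MinHash
#'
#' Estimates the Jaccard similarity of canonical k-mer sets for every pair of
#' segments via bottom-s MinHash sketches and reports unordered pairs at or
#' above the similarity threshold. Segments shorter than the k-mer size are
#' excluded (not an error). Deterministic given the hash seed and symmetric
#' in pair order.
#'
#' @param graph An [assembly_graph()] whose segments carry sequence.
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `seg_a`, `seg_b` (`seg_a < seg_b`),
#'   `similarity`, sorted by decreasing similarity.
#' @export
sketch_candidates <- function(graph, params = sketch_params()) {
  sk <- segment_sketches(graph, params)
  nms <- sort(names(sk))
  n <- length(nms)
  if (n < 2L) {
    return(tibble::tibble(seg_a = character(), seg_b = character(),
                          similarity = numeric()))
  }
  pairs <- combn(nms, 2L)
  sim <- vapply(seq_len(ncol(pairs)), function(j) {
    sketch_jaccard(sk[[pairs[1L, j]]], sk[[pairs[2L, j]]], params$sketch_size)
  }, numeric(1))
  tibble::tibble(seg_a = pairs[1L, ], seg_b = pairs[2L, ], similarity = sim) |>
    dplyr::filter(.data$similarity >= params$similarity_threshold) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$seg_a, .data$seg_b)
}

# orientation-aware identity: global alignment of a against b and revcomp(b),
# identity = matches / alignment columns of the better strand
alignment_identity <- function(seq_a, seq_b) {
  score_one <- function(b) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(b),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 0, gapExtension = 2)
    c(identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
      columns = Biostrings::nchar(aln))
  }
  fwd <- score_one(seq_b)
  rev <- score_one(revcomp(seq_b))
  if (rev[["identity"]] > fwd[["identity"]]) {
    c(rev, strand = -1)
  } else {
    c(fwd, strand = 1)
  }
}

#' Refine candidate pairs into a bubble map by alignment
#'
#' Aligns every candidate pair on both strands; pairs with alignment identity
#' at or above the identity threshold over at least half the shorter
#' sequence's length become edges of a similarity graph, and a greedy
#' descending-identity matching (ties broken lexicographically) yields
#' disjoint two-sided bubbles.
#'
#' @param graph An [assembly_graph()].
#' @param candidates Tibble from [sketch_candidates()].
#' @param params A [sketch_params()] object.
#' @return A bubble map tibble (`segment`, `bubble`, `side`); bubble ids are
#'   assigned in lexicographic order of the smaller side name.
#' @export
refine_candidates <- function(graph, candidates, params = sketch_params()) {
  if (nrow(candidates) == 0L) return(new_bubble_map(tibble::tibble()))
  seqs <- setNames(graph$segments$sequence, graph$segments$name)
  scored <- purrr::pmap_dfr(candidates[, c("seg_a", "seg_b")],
                            function(seg_a, seg_b) {
    r <- alignment_identity(seqs[[seg_a]], seqs[[seg_b]])
    tibble::tibble(seg_a = seg_a, seg_b = seg_b,
                   identity = r[["identity"]], columns = r[["columns"]])
  })
  min_len <- pmin(nchar(seqs[scored$seg_a]), nchar(seqs[scored$seg_b]))
  edges <- scored |>
    dplyr::filter(.data$identity >= params$identity_threshold,
                  .data$columns >= min_len / 2) |>
    dplyr::arrange(dplyr::desc(.data$identity), .data$seg_a, .data$seg_b)
  used <- character()
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges$seg_a[i]; b <- edges$seg_b[i]
    if (!(a %in% used) && !(b %in% used)) {
      keep[i] <- TRUE
      used <- c(used, a, b)
    }
  }
  matched <- edges[keep, ] |>
    dplyr::mutate(side0 = pmin(.data$seg_a, .data$seg_b),
                  side1 = pmax(.data$seg_a, .data$seg_b)) |>
    dplyr::arrange(.data$side0) |>
    dplyr::mutate(bubble = dplyr::row_number())
  new_bubble_map(matched[, c("bubble", "side0", "side1")])
}

#' Detect bubbles by homology search
#'
#' Convenience wrapper running [sketch_candidates()] then
#' [refine_candidates()].
#'
#' @inheritParams sketch_candidates
#' @return A bubble map tibble.
#' @export
detect_bubbles <- function(graph, params = sketch_params()) {
  refine_candidates(graph, sketch_candidates(graph, params), params)
}
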