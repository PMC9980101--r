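#' Assembly graph objects
#'
#' An `assembly_graph` is a light container for a blunt (non-overlapping)
#' bidirected sequence graph: a tibble of segments, a tibble of oriented
#' links, and a tibble of named paths. Links are stored once in a canonical
#' form and queried symmetrically: `L a + b + 0M` and `L b - a - 0M` denote
#' the same adjacency.
#'
#' @param segments Tibble with columns `name`, `sequence`, `length`.
#' @param links Tibble with columns `from`, `from_orient`, `to`, `to_orient`.
#' @param paths Tibble with columns `path_name`, `step`, `segment`, `orient`.
#' @return An object of class `assembly_graph`.
#' @export
assembly_graph <- function(segments = NULL, links = NULL, paths = NULL) {
  nil <- function(x) is.null(x) || ncol(tibble::as_tibble(x)) == 0L
  if (nil(segments)) segments <- NULL
  if (nil(links)) links <- NULL
  if (nil(paths)) paths <- NULL
  segments <- if (is.null(segments)) {
    tibble::tibble(name = character(), sequence = character(), length = integer())
  } else {
    tibble::as_tibble(segments)
  }
  links <- if (is.null(links)) {
    tibble::tibble(from = character(), from_orient = character(),
                   to = character(), to_orient = character())
  } else {
    tibble::as_tibble(links)
  }
  paths <- if (is.null(paths)) {
    tibble::tibble(path_name = character(), step = integer(),
                   segment = character(), orient = character())
  } else {
    tibble::as_tibble(paths)
  }
  g <- structure(list(segments = segments,
                      links = canonicalize_links(links),
                      paths = paths),
                 class = "assembly_graph")
  validate_assembly_graph(g)
}

# store each link once: representation with from <= to (ties broken by the
# orientation encoding), since a link read in either direction is the same
# adjacency
canonicalize_links <- function(links) {
  if (nrow(links) == 0L) return(links)
  fwd <- paste(links$from, links$from_orient, links$to, links$to_orient)
  rev <- paste(links$to, flip_orient(links$to_orient),
               links$from, flip_orient(links$from_orient))
  use_rev <- rev < fwd
  out <- tibble::tibble(
    from = ifelse(use_rev, links$to, links$from),
    from_orient = ifelse(use_rev, flip_orient(links$to_orient), links$from_orient),
    to = ifelse(use_rev, links$from, links$to),
    to_orient = ifelse(use_rev, flip_orient(links$from_orient), links$to_orient)
  )
  dplyr::distinct(dplyr::arrange(out, .data$from, .data$to,
                                 .data$from_orient, .data$to_orient))
}

validate_assembly_graph <- function(g) {
  segs <- g$segments
  if (anyDuplicated(segs$name)) {
    stop("duplicate segment name: ",
         paste(unique(segs$name[duplicated(segs$name)]), collapse = ", "))
  }
  if (nrow(segs) > 0) {
    has_seq <- !is.na(segs$sequence)
    if (any(has_seq & segs$sequence == "")) stop("empty segment sequence")
    bad <- has_seq & grepl("[^ACGTN]", segs$sequence)
    if (any(bad)) {
      stop("segment sequence contains characters outside A/C/G/T/N: ",
           paste(head(segs$name[bad], 3), collapse = ", "))
    }
    if (any(has_seq & segs$length != nchar(segs$sequence))) {
      stop("segment length does not match sequence length")
    }
  }
  ends <- unique(c(g$links$from, g$links$to))
  missing <- setdiff(ends, segs$name)
  if (length(missing) > 0) {
    stop("dangling link endpoint(s): ", paste(head(missing, 5), collapse = ", "))
  }
  missing_p <- setdiff(unique(g$paths$segment), segs$name)
  if (length(missing_p) > 0) {
    stop("path step references unknown segment(s): ",
         paste(head(missing_p, 5), collapse = ", "))
  }
  g
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("<assembly_graph> ", nrow(x$segments), " segments, ",
      nrow(x$links), " links, ",
      dplyr::n_distinct(x$paths$path_name), " paths; ",
      sum(x$segments$length), " bp total\n", sep = "")
  invisible(x)
}

#' Read a blunt GFA1 assembly graph
#'
#' Parses S, L and P lines of a GFA1 file into an [assembly_graph()]. Only
#' blunt graphs are accepted: every L line must carry a `0M` or `*` overlap,
#' anything else is rejected, so no downstream step ever sees a nonzero
#' overlap. Sequences are uppercased on read; characters outside A/C/G/T/N
#' are an error. `S` lines with `*` sequence must carry an `LN:i:` tag.
#'
#' @param path Path to a GFA1 file.
#' @return An [assembly_graph()].
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seg_rows <- list(); link_rows <- list(); path_rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#") || startsWith(line, "H")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    type <- f[[1]]
    if (type == "S") {
      if (length(f) < 3) stop("malformed S line at line ", i)
      seq <- toupper(f[[3]])
      if (seq == "*") {
        ln <- grep("^LN:i:", f[-(1:3)], value = TRUE)
        if (length(ln) == 0) {
          stop("S line at line ", i, " has no sequence and no LN:i: tag")
        }
        len <- as.integer(sub("^LN:i:", "", ln[[1]]))
        seq <- NA_character_
      } else {
        if (grepl("[^ACGTN]", seq)) {
          stop("S line at line ", i,
               ": sequence contains characters outside A/C/G/T/N")
        }
        len <- nchar(seq)
      }
      seg_rows[[length(seg_rows) + 1L]] <-
        tibble::tibble(name = f[[2]], sequence = seq, length = len)
    } else if (type == "L") {
      if (length(f) < 6) stop("malformed L line at line ", i)
      if (!f[[3]] %in% c("+", "-") || !f[[5]] %in% c("+", "-")) {
        stop("malformed orientation on L line at line ", i)
      }
      if (!f[[6]] %in% c("0M", "*")) {
        stop("L line at line ", i, " has overlap '", f[[6]],
             "': only blunt (non-overlapping, 0M) graphs are supported")
      }
      link_rows[[length(link_rows) + 1L]] <-
        tibble::tibble(from = f[[2]], from_orient = f[[3]],
                       to = f[[4]], to_orient = f[[5]])
    } else if (type == "P") {
      if (length(f) < 3) stop("malformed P line at line ", i)
      steps <- strsplit(f[[3]], ",", fixed = TRUE)[[1]]
      orient <- stringr::str_sub(steps, -1)
      if (!all(orient %in% c("+", "-"))) {
        stop("malformed path step on P line at line ", i)
      }
      path_rows[[length(path_rows) + 1L]] <-
        tibble::tibble(path_name = f[[2]], step = seq_along(steps),
                       segment = stringr::str_sub(steps, 1, -2),
                       orient = orient)
    }
    # other record types are ignored
  }
  assembly_graph(segments = dplyr::bind_rows(seg_rows),
                 links = dplyr::bind_rows(link_rows),
                 paths = dplyr::bind_rows(path_rows))
}

#' Write an assembly graph as GFA1
#'
#' Emits a header, S lines with `LN:i:` tags, L lines with `0M` overlaps,
#' and one P line per path. The output re-parses to an isomorphic graph.
#'
#' @param graph An [assembly_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  segs <- graph$segments
  if (nrow(segs) > 0) {
    writeLines(paste("S", segs$name,
                     ifelse(is.na(segs$sequence), "*", segs$sequence),
                     paste0("LN:i:", segs$length), sep = "\t"), con)
  }
  if (nrow(graph$links) > 0) {
    l <- graph$links
    writeLines(paste("L", l$from, l$from_orient, l$to, l$to_orient, "0M",
                     sep = "\t"), con)
  }
  if (nrow(graph$paths) > 0) {
    p <- graph$paths |>
      dplyr::arrange(.data$path_name, .data$step) |>
      dplyr::group_by(.data$path_name) |>
      dplyr::summarise(steps = paste0(.data$segment, .data$orient,
                                      collapse = ","),
                       .groups = "drop")
    writeLines(paste("P", p$path_name, p$steps, "*", sep = "\t"), con)
  }
  invisible(path)
}

# directed step table: one row per traversal step (seg read in `orient`
# continues onto `to` read in `to_orient`); every stored link yields the step
# and its reverse-complement mirror
step_table <- function(graph) {
  l <- graph$links
  if (nrow(l) == 0L) {
    return(tibble::tibble(seg = character(), orient = character(),
                          to = character(), to_orient = character()))
  }
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(seg = l$from, orient = l$from_orient,
                   to = l$to, to_orient = l$to_orient),
    tibble::tibble(seg = l$to, orient = flip_orient(l$to_orient),
                   to = l$from, to_orient = flip_orient(l$from_orient))
  ))
}

# sequence of a segment as traversed in `orient`
oriented_sequence <- function(graph, segment, orient) {
  seq <- graph$segments$sequence[match(segment, graph$segments$name)]
  if (anyNA(seq)) stop("segment without sequence: ",
                       paste(segment[is.na(seq)], collapse = ", "))
  ifelse(orient == "+", seq, revcomp(seq))
}

#' Write haplotype FASTA files from unzipped chains
#'
#' Materializes the two haplotypes of every unzipped chain fragment as FASTA
#' records, concatenating oriented segment sequences (minus-orientation steps
#' contribute their reverse complement). Record names are
#' `<chain_id>.<hap_index>` with `hap_index` 0/1 (fragmented chains get
#' `<chain_id>.f<k>.<hap_index>`). Segments of the graph that are in no
#' haplotype path are written to a third, unphased FASTA, so the three files
#' partition the assembly.
#'
#' @param hap_paths Haplotype path tibble from [unzip_chains()].
#' @param graph The [assembly_graph()] carrying the sequences.
#' @param out_prefix Output path prefix; writes `<prefix>.hap0.fasta`,
#'   `<prefix>.hap1.fasta` and `<prefix>.unphased.fasta`.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_haplotype_fasta <- function(hap_paths, graph, out_prefix) {
  stopifnot(inherits(graph, "assembly_graph"))
  paths <- hap_paths |>
    dplyr::mutate(rec = ifelse(.data$fragment == 1L &
                                 !.data$chain_fragmented,
                               paste0(.data$chain_id, ".", .data$haplotype),
                               paste0(.data$chain_id, ".f", .data$fragment,
                                      ".", .data$haplotype)))
  seqs <- paths |>
    dplyr::arrange(.data$rec, .data$step) |>
    dplyr::group_by(.data$rec, .data$haplotype) |>
    dplyr::summarise(seq = paste0(oriented_sequence(graph, .data$segment,
                                                    .data$orient),
                                  collapse = ""),
                     .groups = "drop")
  files <- c(hap0 = paste0(out_prefix, ".hap0.fasta"),
             hap1 = paste0(out_prefix, ".hap1.fasta"),
             unphased = paste0(out_prefix, ".unphased.fasta"))
  for (h in 0:1) {
    s <- dplyr::filter(seqs, .data$haplotype == h)
    x <- Biostrings::DNAStringSet(setNames(s$seq, s$rec))
    Biostrings::writeXStringSet(x, files[[h + 1L]], width = 80L)
  }
  leftover <- setdiff(graph$segments$name, unique(hap_paths$segment))
  lo <- dplyr::filter(graph$segments, .data$name %in% leftover,
                      !is.na(.data$sequence))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(lo$sequence, lo$name)),
    files[["unphased"]], width = 80L)
  invisible(files)
}
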