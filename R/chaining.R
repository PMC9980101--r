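#' Classify graph nodes for diploid bubble chains
#'
#' Labels every segment as `"diploid"`, `"hom_in_chain"` or `"other"`.
#' A bubble side is diploid when, on each of its two sides (the two
#' traversal directions of the bidirected graph), it has at most two direct
#' neighbours and its set of two-hop neighbours -- the other segments
#' entering its neighbours at the same end, i.e. its siblings -- contains
#' nothing but its bubble partner; its partner must satisfy the mirrored
#' condition. A non-bubble segment is homozygous-in-chain when each side is
#' either a graph end or attaches exactly the two sides of one diploid
#' bubble, and at least one side is non-empty. Everything else (tangles,
#' isolated segments) is `"other"` and excluded from chains.
#'
#' @param graph An [assembly_graph()].
#' @param bubbles Bubble map tibble.
#' @return Tibble with columns `segment`, `label`.
#' @export
classify_nodes <- function(graph, bubbles) {
  segs <- graph$segments$name
  steps <- step_table(graph)
  bm <- tibble::as_tibble(bubbles)
  partner <- setNames(
    c(bm$segment[match(paste(bm$bubble, 1L - bm$side),
                       paste(bm$bubble, bm$side))]),
    bm$segment)
  # neighbours and entrant groups
  nb_key <- paste(steps$seg, steps$orient)
  nbrs <- split(steps$to, nb_key)
  ent <- split(steps$seg, paste(steps$to, steps$to_orient))
  sibling_set <- function(s, o) {
    st <- steps[steps$seg == s & steps$orient == o, , drop = FALSE]
    if (nrow(st) == 0L) return(character())
    setdiff(unique(unlist(ent[paste(st$to, st$to_orient)],
                          use.names = FALSE)), s)
  }
  side_ok <- function(s) {
    m <- partner[[s]]
    for (o in c("+", "-")) {
      nn <- unique(nbrs[[paste(s, o)]])
      if (length(nn) > 2L) return(FALSE)
      sib <- sibling_set(s, o)
      if (length(setdiff(sib, m)) > 0L) return(FALSE)
    }
    TRUE
  }
  ok <- vapply(bm$segment, side_ok, logical(1))
  names(ok) <- bm$segment
  both_ok <- ok & ok[partner[bm$segment]]
  diploid <- bm$segment[both_ok]
  bubble_of <- setNames(bm$bubble, bm$segment)
  hom_ok <- function(s) {
    any_side <- FALSE
    for (o in c("+", "-")) {
      nn <- unique(nbrs[[paste(s, o)]])
      if (length(nn) == 0L) next
      any_side <- TRUE
      if (length(nn) != 2L) return(FALSE)
      if (!all(nn %in% diploid)) return(FALSE)
      b <- unique(bubble_of[nn])
      if (length(b) != 1L) return(FALSE)
    }
    any_side
  }
  homs <- setdiff(segs, bm$segment)
  hom_lab <- vapply(homs, hom_ok, logical(1))
  tibble::tibble(segment = segs) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$segment %in% diploid ~ "diploid",
      .data$segment %in% homs[hom_lab] ~ "hom_in_chain",
      TRUE ~ "other"))
}

#' Find diploid bubble chains
#'
#' Traverses the subgraph of labelled nodes into maximal chains of
#' alternating homozygous segments and heterozygous bubble pairs. Chains
#' terminate at unlabelled (`"other"`) nodes, graph ends, or topology
#' changes; every labelled node lands in at most one chain and isolated
#' bubbles form chains of one element. Chain ids are deterministic:
#' `chain_<smallest member segment name>`.
#'
#' @param graph An [assembly_graph()].
#' @param labels Tibble from [classify_nodes()].
#' @param bubbles Bubble map tibble.
#' @return Tibble with one row per segment occurrence, columns `chain_id`,
#'   `element` (position along the chain), `kind` (`"hom"`/`"het"`),
#'   `bubble` (NA for homs), `segment`, `side`, `orient`.
#' @export
find_chains <- function(graph, labels, bubbles) {
  steps <- step_table(graph)
  bm <- tibble::as_tibble(bubbles)
  dip <- labels$segment[labels$label == "diploid"]
  hom <- labels$segment[labels$label == "hom_in_chain"]
  # elements: whole bubbles with both sides diploid, plus chain homs
  bub_ok <- bm |>
    dplyr::group_by(.data$bubble) |>
    dplyr::filter(all(.data$segment %in% dip)) |>
    dplyr::ungroup()
  elem_of <- c(setNames(paste0("b", bub_ok$bubble), bub_ok$segment),
               setNames(paste0("h", hom), hom))
  if (length(elem_of) == 0L) return(empty_chain_tbl())
  elem_segs <- split(names(elem_of), unname(elem_of))
  labelled <- names(elem_of)
  est <- steps[steps$seg %in% labelled & steps$to %in% labelled, ,
               drop = FALSE]
  est <- est[elem_of[est$seg] != elem_of[est$to], , drop = FALSE]
  edges <- unique(tibble::tibble(
    a = pmin(elem_of[est$seg], elem_of[est$to]),
    b = pmax(elem_of[est$seg], elem_of[est$to])))
  adj <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  elems <- sort(unique(unname(elem_of)))
  # connected components over elements
  comp <- setNames(rep(NA_integer_, length(elems)), elems)
  cid <- 0L
  for (e in elems) {
    if (!is.na(comp[[e]])) next
    cid <- cid + 1L
    queue <- e
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[cur]])) next
      comp[[cur]] <- cid
      queue <- c(queue, setdiff(adj[[cur]] %||% character(), names(comp)[!is.na(comp)]))
    }
  }
  out <- list()
  for (k in seq_len(cid)) {
    members <- names(comp)[comp == k]
    deg <- vapply(members, function(e) length(adj[[e]] %||% character()),
                  integer(1))
    if (any(deg > 2L)) next  # branching tangle that slipped the labels
    min_seg <- function(e) min(elem_segs[[e]])
    ends <- members[deg <= 1L]
    start <- if (length(ends) > 0L) {
      ends[order(vapply(ends, min_seg, character(1)))][[1L]]
    } else {  # cycle: break deterministically
      members[order(vapply(members, min_seg, character(1)))][[1L]]
    }
    # walk the path
    walk <- start
    prev <- NA_character_
    cur <- start
    repeat {
      nxt <- setdiff(adj[[cur]] %||% character(), prev)
      nxt <- setdiff(nxt, walk)
      if (length(nxt) == 0L) break
      nxt <- sort(nxt)[[1L]]
      walk <- c(walk, nxt)
      prev <- cur
      cur <- nxt
    }
    chain_id <- paste0("chain_",
                       min(vapply(walk, min_seg, character(1))))
    out[[length(out) + 1L]] <-
      orient_chain(walk, elem_segs, bm, steps, chain_id)
  }
  if (length(out) == 0L) return(empty_chain_tbl())
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chain_id, .data$element, .data$side)
}

empty_chain_tbl <- function() {
  tibble::tibble(chain_id = character(), element = integer(),
                 kind = character(), bubble = integer(), segment = character(),
                 side = integer(), orient = character())
}

# assign per-segment traversal orientation along an element walk
orient_chain <- function(walk, elem_segs, bm, steps, chain_id) {
  side_of <- setNames(bm$side, bm$segment)
  bubble_of <- setNames(bm$bubble, bm$segment)
  rows <- list()
  prev_segs <- NULL; prev_orients <- NULL
  for (i in seq_along(walk)) {
    e <- walk[[i]]
    segs <- sort(elem_segs[[e]])
    is_het <- startsWith(e, "b")
    orients <- vapply(segs, function(s) {
      o <- NA_character_
      if (i > 1L) {
        st <- steps[steps$seg %in% prev_segs & steps$to == s, , drop = FALSE]
        st <- st[st$orient == prev_orients[match(st$seg, prev_segs)], ,
                 drop = FALSE]
        if (nrow(st) > 0L) o <- sort(st$to_orient)[[1L]]
      }
      if (is.na(o) && i < length(walk)) {
        nxt <- elem_segs[[walk[[i + 1L]]]]
        st <- steps[steps$seg == s & steps$to %in% nxt, , drop = FALSE]
        if (nrow(st) > 0L) o <- sort(st$orient)[[1L]]
      }
      if (is.na(o)) o <- "+"
      o
    }, character(1))
    rows[[i]] <- tibble::tibble(
      chain_id = chain_id, element = i,
      kind = if (is_het) "het" else "hom",
      bubble = if (is_het) unname(bubble_of[segs]) else NA_integer_,
      segment = segs,
      side = if (is_het) unname(side_of[segs]) else NA_integer_,
      orient = unname(orients))
    prev_segs <- segs; prev_orients <- orients
  }
  dplyr::bind_rows(rows)
}

#' Unzip bubble chains into haplotype paths
#'
#' Haplotype h of a chain takes side h of every phased heterozygous pair and
#' duplicates every homozygous segment into both haplotypes. A chain
#' containing an unphased (unsupported) bubble is split at that bubble and
#' both fragments are unzipped; the unresolved sides are excluded. Every
#' consecutive pair of steps in an emitted path is verified to correspond to
#' a link of the input graph; a missing link also splits the fragment.
#'
#' @param chains Tibble from [find_chains()].
#' @param phase A `phase_fit` or a tidy phase tibble with columns `segment`,
#'   `haplotype`, `bubble`, `supported`.
#' @param graph The [assembly_graph()] (for link-fidelity checks).
#' @return Tibble with columns `chain_id`, `fragment`, `chain_fragmented`,
#'   `haplotype`, `step`, `segment`, `orient`.
#' @export
unzip_chains <- function(chains, phase, graph) {
  ph <- if (inherits(phase, "phase_fit")) phase$segments else
    tibble::as_tibble(phase)
  hap_of <- setNames(ph$haplotype, ph$segment)
  supported <- setNames(ph$supported, ph$segment)
  steps <- step_table(graph)
  step_key <- c(paste(steps$seg, steps$orient, steps$to, steps$to_orient))
  rows <- list()
  for (ch in split(chains, chains$chain_id)) {
    ch <- dplyr::arrange(ch, .data$element, .data$side)
    frag <- 1L
    hap_steps <- list(`0` = list(), `1` = list())
    n_frag_rows <- function() length(hap_steps[["0"]]) +
      length(hap_steps[["1"]])
    flush <- function() {
      for (h in c("0", "1")) {
        st <- hap_steps[[h]]
        if (length(st) > 0L) {
          rows[[length(rows) + 1L]] <<- tibble::tibble(
            chain_id = ch$chain_id[[1L]], fragment = frag,
            haplotype = as.integer(h), step = seq_along(st),
            segment = vapply(st, `[[`, character(1), 1L),
            orient = vapply(st, `[[`, character(1), 2L))
        }
      }
      hap_steps <<- list(`0` = list(), `1` = list())
    }
    push <- function(h, seg, orient) {
      st <- hap_steps[[h]]
      if (length(st) > 0L) {
        last <- st[[length(st)]]
        key <- paste(last[[1L]], last[[2L]], seg, orient)
        if (!key %in% step_key) {
          # no backing link: split here
          flush()
          frag <<- frag + 1L
        }
      }
      hap_steps[[h]][[length(hap_steps[[h]]) + 1L]] <<- c(seg, orient)
    }
    for (el in split(ch, ch$element)) {
      if (el$kind[[1L]] == "hom") {
        push("0", el$segment[[1L]], el$orient[[1L]])
        push("1", el$segment[[1L]], el$orient[[1L]])
      } else {
        segs <- el$segment
        phased <- all(segs %in% names(hap_of)) &&
          all(supported[segs]) &&
          length(unique(hap_of[segs])) == 2L
        if (!phased) {
          if (n_frag_rows() > 0L) {
            flush()
            frag <- frag + 1L
          }
          next
        }
        for (j in seq_along(segs)) {
          push(as.character(hap_of[[segs[[j]]]]), segs[[j]], el$orient[[j]])
        }
      }
    }
    flush()
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(chain_id = character(), fragment = integer(),
                          chain_fragmented = logical(), haplotype = integer(),
                          step = integer(), segment = character(),
                          orient = character()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::mutate(chain_fragmented = dplyr::n_distinct(.data$fragment) > 1L) |>
    dplyr::ungroup() |>
    dplyr::select("chain_id", "fragment", "chain_fragmented", "haplotype",
                  "step", "segment", "orient") |>
    dplyr::arrange(.data$chain_id, .data$fragment, .data$haplotype,
                   .data$step)
}

#' Summarise unzipped chains
#'
#' @param chains Tibble from [find_chains()].
#' @param hap_paths Tibble from [unzip_chains()].
#' @param graph The [assembly_graph()].
#' @return Tibble with columns `chain_id`, `n_bubbles`, `n_homs`, `hap0_bp`,
#'   `hap1_bp`.
#' @export
chain_summary <- function(chains, hap_paths, graph) {
  len_of <- setNames(graph$segments$length, graph$segments$name)
  counts <- chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      n_bubbles = dplyr::n_distinct(.data$bubble, na.rm = TRUE),
      n_homs = sum(.data$kind == "hom"), .groups = "drop")
  bp <- hap_paths |>
    dplyr::mutate(bp = len_of[.data$segment]) |>
    dplyr::group_by(.data$chain_id, .data$haplotype) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "haplotype", values_from = "bp",
                       names_prefix = "hap", values_fill = 0) |>
    dplyr::rename_with(~ paste0(.x, "_bp"), dplyr::starts_with("hap"))
  for (col in c("hap0_bp", "hap1_bp")) {
    if (!col %in% names(bp)) bp[[col]] <- 0
  }
  dplyr::left_join(counts, bp, by = "chain_id") |>
    dplyr::mutate(dplyr::across(c("hap0_bp", "hap1_bp"),
                                ~ tidyr::replace_na(.x, 0)))
}

#' Add haplotype paths to a graph as P lines
#'
#' @param graph An [assembly_graph()].
#' @param hap_paths Tibble from [unzip_chains()].
#' @return A new [assembly_graph()] whose `paths` are the haplotype walks,
#'   named like the FASTA records of [write_haplotype_fasta()].
#' @export
graph_with_haplotype_paths <- function(graph, hap_paths) {
  p <- hap_paths |>
    dplyr::mutate(path_name = ifelse(!.data$chain_fragmented,
                                     paste0(.data$chain_id, ".",
                                            .data$haplotype),
                                     paste0(.data$chain_id, ".f",
                                            .data$fragment, ".",
                                            .data$haplotype))) |>
    dplyr::select("path_name", "step", "segment", "orient")
  assembly_graph(segments = graph$segments, links = graph$links, paths = p)
}
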