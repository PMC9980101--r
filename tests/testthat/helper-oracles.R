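# Independent oracles and small fixture builders. Everything here is
# deliberately written from first principles (plain loops, substring
# k-mers, exhaustive enumeration) so it shares no code path with the
# package internals it checks.

r_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical k-mer set via substring extraction (N windows skipped)
r_canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, 1:(n - k + 1), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  unique(pmin(km, r_revcomp(km)))
}

exact_jaccard <- function(seq_a, seq_b, k) {
  a <- r_canonical_kmer_set(seq_a, k)
  b <- r_canonical_kmer_set(seq_b, k)
  if (length(a) == 0L && length(b) == 0L) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_at_rate <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(runif(length(b)) < rate)
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

# build a graph from segment sequences and "a + b +" link strings
mk_graph <- function(seqs, links = character(), paths = NULL) {
  lt <- if (length(links) > 0) {
    parts <- strsplit(links, " ", fixed = TRUE)
    tibble::tibble(from = vapply(parts, `[[`, "", 1L),
                   from_orient = vapply(parts, `[[`, "", 2L),
                   to = vapply(parts, `[[`, "", 3L),
                   to_orient = vapply(parts, `[[`, "", 4L))
  } else NULL
  assembly_graph(
    segments = tibble::tibble(name = names(seqs), sequence = unname(seqs),
                              length = nchar(unname(seqs))),
    links = lt, paths = paths)
}

mk_bubbles <- function(...) {
  # mk_bubbles(c("a","b"), c("c","d")) -> bubble map
  pairs <- list(...)
  dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
    tibble::tibble(segment = pairs[[i]], bubble = i, side = 0:1)
  }))
}

mk_contacts <- function(...) {
  # mk_contacts("a b 5", "a c 2")
  parts <- strsplit(c(...), " ", fixed = TRUE)
  tibble::tibble(seg_a = vapply(parts, `[[`, "", 1L),
                 seg_b = vapply(parts, `[[`, "", 2L),
                 weight = as.integer(vapply(parts, `[[`, "", 3L)))
}

# score a phase state directly from the four-contact definition: an edge
# whose endpoints land on the same haplotype counts +w, across haplotypes
# -w; edges touching non-bubble segments or within one bubble are ignored
score_state_oracle <- function(orientation, bubbles, contacts) {
  side_of <- setNames(bubbles$side, bubbles$segment)
  bub_of <- setNames(bubbles$bubble, bubbles$segment)
  total <- 0
  for (i in seq_len(nrow(contacts))) {
    x <- contacts$seg_a[i]; y <- contacts$seg_b[i]
    if (!(x %in% names(bub_of)) || !(y %in% names(bub_of))) next
    bx <- bub_of[[x]]; by <- bub_of[[y]]
    if (bx == by) next
    hap_x <- if (side_of[[x]] == orientation[[as.character(bx)]]) 0 else 1
    hap_y <- if (side_of[[y]] == orientation[[as.character(by)]]) 0 else 1
    total <- total + if (hap_x == hap_y) contacts$weight[i] else
      -contacts$weight[i]
  }
  total
}

# exhaustive maximum of the phasing objective over all 2^B orientation
# assignments (B <= 15 or so)
brute_force_optimum <- function(bubbles, contacts) {
  bids <- sort(unique(bubbles$bubble))
  B <- length(bids)
  side_of <- setNames(bubbles$side, bubbles$segment)
  bub_idx <- setNames(match(bubbles$bubble, bids), bubbles$segment)
  n_states <- 2^B
  states <- matrix(0L, nrow = n_states, ncol = B)
  for (j in seq_len(B)) {
    states[, j] <- as.integer(bitwAnd(0:(n_states - 1), bitwShiftL(1L, j - 1L)) > 0L)
  }
  total <- numeric(n_states)
  for (i in seq_len(nrow(contacts))) {
    x <- contacts$seg_a[i]; y <- contacts$seg_b[i]
    if (!(x %in% names(bub_idx)) || !(y %in% names(bub_idx))) next
    jx <- bub_idx[[x]]; jy <- bub_idx[[y]]
    if (jx == jy) next
    same_side <- side_of[[x]] == side_of[[y]]
    equal_orient <- states[, jx] == states[, jy]
    total <- total + ifelse(equal_orient == same_side, contacts$weight[i],
                            -contacts$weight[i])
  }
  max(total)
}

# random phasing instance: B bubbles, random contact weights between
# random bubble sides (each pair of bubbles linked with prob p_edge)
random_instance <- function(B, p_edge = 0.4, max_w = 10L) {
  segs <- paste0("s", seq_len(2L * B))
  bubbles <- tibble::tibble(segment = segs,
                            bubble = rep(seq_len(B), each = 2L),
                            side = rep(0:1, B))
  rows <- list()
  for (a in seq_len(B - 1L)) {
    for (b in (a + 1L):B) {
      if (runif(1) > p_edge) next
      for (sa in 0:1) for (sb in 0:1) {
        if (runif(1) < 0.5) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            seg_a = segs[2L * a - 1L + sa], seg_b = segs[2L * b - 1L + sb],
            weight = sample.int(max_w, 1L))
        }
      }
    }
  }
  contacts <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(seg_a = character(), seg_b = character(),
                   weight = integer())
  list(bubbles = bubbles, contacts = contacts)
}

# literal per-node checker of the strict diploid-chain rules: the link list
# is first transcribed into its traversal steps (a link read in either
# direction), then every rule is checked with plain loops
naive_all_steps <- function(links) {
  flip <- function(x) ifelse(x == "+", "-", "+")
  rows <- list()
  for (i in seq_len(nrow(links))) {
    f <- links$from[i]; fo <- links$from_orient[i]
    t <- links$to[i]; to <- links$to_orient[i]
    rows[[length(rows) + 1L]] <- data.frame(
      seg = c(f, t), o = c(fo, flip(to)),
      to = c(t, f), toor = c(to, flip(fo)))
  }
  unique(do.call(rbind, c(rows,
                          list(data.frame(seg = character(), o = character(),
                                          to = character(),
                                          toor = character())))))
}

naive_classify <- function(graph, bubbles) {
  st <- naive_all_steps(graph$links)
  segs <- graph$segments$name
  bub_of <- setNames(bubbles$bubble, bubbles$segment)
  partner <- vapply(bubbles$segment, function(s) {
    b <- bubbles[bubbles$bubble == bub_of[[s]] & bubbles$segment != s, ]
    b$segment[[1L]]
  }, character(1))
  steps_of <- function(s, o) st[st$seg == s & st$o == o, , drop = FALSE]
  side_pass <- function(s) {
    p <- partner[[s]]
    for (o in c("+", "-")) {
      my <- steps_of(s, o)
      if (length(unique(my$to)) > 2L) return(FALSE)
      twohop <- character()
      for (i in seq_len(nrow(my))) {
        # who else enters this neighbour at the same end?
        ent <- st[st$to == my$to[i] & st$toor == my$toor[i], "seg"]
        twohop <- union(twohop, setdiff(ent, s))
      }
      if (length(setdiff(twohop, p)) > 0L) return(FALSE)
    }
    TRUE
  }
  pass <- vapply(bubbles$segment, side_pass, logical(1))
  diploid <- bubbles$segment[pass & pass[partner[bubbles$segment]]]
  lab <- setNames(rep("other", length(segs)), segs)
  lab[diploid] <- "diploid"
  for (s in setdiff(segs, bubbles$segment)) {
    ok <- FALSE; bad <- FALSE
    for (o in c("+", "-")) {
      nbrs <- unique(steps_of(s, o)$to)
      if (length(nbrs) == 0L) next
      if (length(nbrs) != 2L || !all(nbrs %in% diploid) ||
          length(unique(bub_of[nbrs])) != 1L) {
        bad <- TRUE
      } else {
        ok <- TRUE
      }
    }
    if (ok && !bad) lab[s] <- "hom_in_chain"
  }
  tibble::tibble(segment = segs, label = unname(lab[segs]))
}

# random 30-node graph with some planted bubbles and arbitrary extra links
random_messy_graph <- function(n_nodes = 30L, n_bubbles = 5L,
                               n_links = 25L) {
  segs <- setNames(vapply(seq_len(n_nodes), function(i) rand_seq(40L),
                          character(1)),
                   sprintf("n%02d", seq_len(n_nodes)))
  bubbles <- tibble::tibble(
    segment = names(segs)[seq_len(2L * n_bubbles)],
    bubble = rep(seq_len(n_bubbles), each = 2L),
    side = rep(0:1, n_bubbles))
  links <- tibble::tibble(
    from = sample(names(segs), n_links, TRUE),
    from_orient = sample(c("+", "-"), n_links, TRUE),
    to = sample(names(segs), n_links, TRUE),
    to_orient = sample(c("+", "-"), n_links, TRUE)) |>
    dplyr::filter(.data$from != .data$to)
  g <- assembly_graph(
    segments = tibble::tibble(name = names(segs), sequence = unname(segs),
                              length = nchar(unname(segs))),
    links = links)
  list(graph = g, bubbles = bubbles)
}

# truth groups (one per chain) for per-block phase-error scoring
chain_groups <- function(sim) {
  sim$chains |>
    dplyr::filter(.data$kind == "het") |>
    dplyr::transmute(.data$bubble, group = .data$chain)
}

# unordered side-pair keys of a bubble map, for recall comparisons
bubble_pairs_key <- function(bm) {
  wide <- bm |>
    dplyr::arrange(.data$bubble, .data$side) |>
    dplyr::group_by(.data$bubble) |>
    dplyr::summarise(key = paste(sort(.data$segment), collapse = "|"),
                     .groups = "drop")
  wide$key
}

# "seg orient to to_orient" keys of every traversal step of a graph
step_keys_of <- function(graph) {
  st <- naive_all_steps(graph$links)
  paste(st$seg, st$o, st$to, st$toor)
}
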