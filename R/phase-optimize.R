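#' Sampler configuration for contact-based phasing
#'
#' Controls the stochastic max-cut optimizer: per round, `n_samples`
#' independent greedy optimizations are run from random phase states, the
#' distribution of relative orientations across samples is accumulated, and
#' the most consistent bubble pairs are merged into rigid sets before the
#' next round. After round r no merged set can exceed 2^r bubbles.
#'
#' @param n_samples Greedy restarts per round. Default 30.
#' @param n_rounds Merge rounds. Default 10.
#' @param merge_fraction Fraction of the most consistent mergeable bubble
#'   pairs merged per round, in (0, 1]. Default 0.5.
#' @param seed Integer seed; every sample draws an independent sub-seed from
#'   it, so results do not depend on execution order or thread count.
#' @param n_threads Number of worker processes for the independent samples.
#'   Results are identical for any value. Default 1.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 30L, n_rounds = 10L,
                           merge_fraction = 0.5, seed = 1L, n_threads = 1L) {
  stopifnot(n_samples >= 1, n_rounds >= 1,
            merge_fraction > 0, merge_fraction <= 1, n_threads >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_rounds = as.integer(n_rounds),
                 merge_fraction = merge_fraction,
                 seed = as.integer(seed),
                 n_threads = as.integer(n_threads)),
            class = "sampler_config")
}

#' Bubble-pair contact couplings
#'
#' Collapses a contact graph onto bubble pairs. For two bubbles a and b with
#' contact weights w(x, y) between their sides, the coupling is
#' `s = (w(a0,b0) + w(a1,b1)) - (w(a0,b1) + w(a1,b0))`: positive when
#' contacts favour pairing equal sides, negative when they favour opposite
#' sides. Contacts with a segment outside any bubble, and contacts between
#' the two sides of one bubble, contribute nothing.
#'
#' @param bubbles Bubble map tibble (`segment`, `bubble`, `side`).
#' @param contacts Contact graph tibble (`seg_a`, `seg_b`, `weight`).
#' @return Tibble with columns `bubble_a`, `bubble_b` (`bubble_a <
#'   bubble_b`) and `s`; one row per bubble pair sharing at least one
#'   contact edge.
#' @export
contact_couplings <- function(bubbles, contacts) {
  bm <- tibble::as_tibble(bubbles)
  x <- contacts |>
    dplyr::inner_join(bm, by = c(seg_a = "segment")) |>
    dplyr::inner_join(bm, by = c(seg_b = "segment"),
                      suffix = c("_a", "_b")) |>
    dplyr::filter(.data$bubble_a != .data$bubble_b)
  if (nrow(x) == 0L) {
    return(tibble::tibble(bubble_a = integer(), bubble_b = integer(),
                          s = numeric()))
  }
  x |>
    dplyr::mutate(
      lo = pmin(.data$bubble_a, .data$bubble_b),
      hi = pmax(.data$bubble_a, .data$bubble_b),
      sgn = ifelse(.data$side_a == .data$side_b, 1, -1)) |>
    dplyr::group_by(bubble_a = .data$lo, bubble_b = .data$hi) |>
    dplyr::summarise(s = sum(.data$sgn * .data$weight), .groups = "drop") |>
    dplyr::arrange(.data$bubble_a, .data$bubble_b)
}

#' Score one bubble pair under given orientations
#'
#' Of the four possible contacts between two bubbles, only those linking
#' sides in matching phases score positively: with haplotype 0 of bubble a
#' being its side `orient_a` (and likewise for b), the score is
#' `(w(a_h0,b_h0) + w(a_h1,b_h1)) - (w(a_h0,b_h1) + w(a_h1,b_h0))`. It is
#' antisymmetric under flipping exactly one orientation.
#'
#' @param bubbles Bubble map tibble.
#' @param contacts Contact graph tibble.
#' @param bubble_a,bubble_b Bubble ids.
#' @param orient_a,orient_b Orientations in 0/1.
#' @return Integer score.
#' @export
pair_score <- function(bubbles, contacts, bubble_a, bubble_b,
                       orient_a, orient_b) {
  stopifnot(orient_a %in% 0:1, orient_b %in% 0:1, bubble_a != bubble_b)
  coup <- contact_couplings(
    dplyr::filter(bubbles, .data$bubble %in% c(bubble_a, bubble_b)), contacts)
  s <- if (nrow(coup) == 0L) 0 else coup$s[[1L]]
  if (orient_a == orient_b) s else -s
}

#' Total phasing objective of a phase state
#'
#' Sum of [pair_score()] over all bubble pairs sharing at least one contact
#' edge. Invariant under a global flip of all orientations.
#'
#' @param state Tibble with columns `bubble`, `orientation` (0/1) covering
#'   all bubbles.
#' @param bubbles Bubble map tibble.
#' @param contacts Contact graph tibble.
#' @return Numeric objective value.
#' @export
total_objective <- function(state, bubbles, contacts) {
  coup <- contact_couplings(bubbles, contacts)
  if (nrow(coup) == 0L) return(0)
  sig <- setNames(1 - 2 * state$orientation, state$bubble)
  sum(coup$s * sig[as.character(coup$bubble_a)] *
        sig[as.character(coup$bubble_b)])
}

# compressed sparse rows for the symmetric set-level coupling graph;
# i, j are 1-based node indices, w their weights (each undirected edge once)
build_csr <- function(n, i, j, w) {
  di <- c(i, j); dj <- c(j, i); dw <- c(w, w)
  o <- order(di, dj)
  di <- di[o]; dj <- dj[o]; dw <- dw[o]
  start <- c(0L, cumsum(tabulate(di, nbins = n)))
  list(start = as.integer(start), idx = as.integer(dj - 1L), w = as.numeric(dw))
}

# run one greedy sweep-to-convergence on the set-level problem under a given
# sub-seed; returns sigma in {-1, +1} per set
run_greedy_sample <- function(n_sets, csr, sub_seed) {
  withr::with_seed(sub_seed, {
    sigma0 <- sample(c(-1L, 1L), n_sets, replace = TRUE)
    greedy_sweep_cpp(sigma0, csr$start, csr$idx, csr$w)
  })
}

#' One greedy optimization pass over a phase state
#'
#' Visits merged sets in random order (ambient RNG), flipping any set whose
#' flip strictly increases [total_objective()], and repeats until a full
#' sweep makes no flip. The returned state is 1-flip-optimal and the
#' objective never decreases during the pass. Zero-gain flips are not taken.
#'
#' @param state Tibble with columns `bubble`, `orientation` and optionally
#'   `merged_set` (bubbles sharing a `merged_set` id flip together, keeping
#'   their relative orientations).
#' @param bubbles Bubble map tibble.
#' @param contacts Contact graph tibble.
#' @return The improved state tibble (same columns as the input).
#' @export
greedy_pass <- function(state, bubbles, contacts) {
  state <- tibble::as_tibble(state)
  if (!"merged_set" %in% names(state)) state$merged_set <- state$bubble
  coup <- contact_couplings(bubbles, contacts)
  sets <- sort(unique(state$merged_set))
  si <- match(state$merged_set, sets)
  # orientation of each bubble relative to its set's first-listed member
  rep_orient <- state$orientation[match(sets, state$merged_set)]
  rel <- ifelse(state$orientation == rep_orient[si], 1, -1)
  sigma <- ifelse(rep_orient == 0, 1L, -1L)
  ai <- match(coup$bubble_a, state$bubble)
  bi <- match(coup$bubble_b, state$bubble)
  jw <- coup$s * rel[ai] * rel[bi]
  keep <- si[ai] != si[bi]
  csr <- build_csr(length(sets), si[ai][keep], si[bi][keep], jw[keep])
  sigma <- greedy_sweep_cpp(as.integer(sigma), csr$start, csr$idx, csr$w)
  state$orientation <- as.integer(ifelse(sigma[si] * rel == 1, 0L, 1L))
  state
}

#' Sample the distribution of relative bubble orientations
#'
#' Runs `n_samples` independent greedy optimizations from uniformly random
#' phase states (each under a sub-seed derived from `config$seed`) and, for
#' every bubble pair sharing a contact edge, tallies across samples whether
#' the two bubbles came out in the same or opposite orientation. The tallies
#' are bitwise identical for any `n_threads`.
#'
#' @param bubbles Bubble map tibble.
#' @param contacts Contact graph tibble.
#' @param config A [sampler_config()].
#' @return Tibble with columns `bubble_a`, `bubble_b`, `n_same`,
#'   `n_opposite` (`n_same + n_opposite == n_samples`).
#' @export
sample_orientations <- function(bubbles, contacts, config = sampler_config()) {
  bids <- sort(unique(bubbles$bubble))
  coup <- contact_couplings(bubbles, contacts)
  csr <- build_csr(length(bids), match(coup$bubble_a, bids),
                   match(coup$bubble_b, bids), coup$s)
  sig <- sample_sigma_matrix(length(bids), csr, config, round = 1L)
  tally_pairs(coup, match(coup$bubble_a, bids), match(coup$bubble_b, bids),
              sig)
}

# matrix of greedy-converged states, one column per sample
sample_sigma_matrix <- function(n_sets, csr, config, round) {
  seeds <- vapply(seq_len(config$n_samples),
                  function(k) derive_seed(config$seed, round, k), integer(1))
  runner <- function(sd) run_greedy_sample(n_sets, csr, sd)
  cols <- if (config$n_threads > 1L) {
    parallel::mclapply(seeds, runner, mc.cores = config$n_threads)
  } else {
    lapply(seeds, runner)
  }
  matrix(unlist(cols), nrow = n_sets, ncol = config$n_samples)
}

tally_pairs <- function(coup, ai, bi, sig) {
  if (nrow(coup) == 0L) {
    return(tibble::tibble(bubble_a = integer(), bubble_b = integer(),
                          n_same = integer(), n_opposite = integer()))
  }
  prod <- sig[ai, , drop = FALSE] * sig[bi, , drop = FALSE]
  tibble::tibble(bubble_a = coup$bubble_a, bubble_b = coup$bubble_b,
                 n_same = as.integer(rowSums(prod == 1)),
                 n_opposite = as.integer(rowSums(prod == -1)))
}

#' Phase bubbles by sampled greedy max-cut with consistency merging
#'
#' The full contact-phasing optimizer: for each round, greedy optimizations
#' from random states are sampled, the orientation distribution over bubble
#' pairs is accumulated, and the most consistent pairs are merged into rigid
#' sets (each set participating in at most one merge per round, so after
#' round r the largest set has at most 2^r bubbles). The final state is the
#' best-objective sample of the last round. Phase is meaningful up to a
#' global flip.
#'
#' @param bubbles Bubble map tibble.
#' @param contacts Contact graph tibble.
#' @param config A [sampler_config()].
#' @return A `phase_fit` object; see [tidy.phase_fit()] for the per-segment
#'   haplotype table.
#' @export
phase_by_contacts <- function(bubbles, contacts, config = sampler_config()) {
  sides <- bubble_sides(bubbles)
  bids <- sides$bubble
  B <- length(bids)
  coup <- contact_couplings(bubbles, contacts)
  ai <- match(coup$bubble_a, bids)
  bi <- match(coup$bubble_b, bids)
  set_id <- seq_len(B)       # index of the set's representative bubble
  rel <- rep(1, B)           # orientation relative to the representative
  log_rows <- vector("list", config$n_rounds)
  best_v <- rep(1, B)
  best_obj <- 0
  for (r in seq_len(config$n_rounds)) {
    sets <- sort(unique(set_id))
    si <- match(set_id, sets)
    jw <- coup$s * rel[ai] * rel[bi]
    keep <- si[ai] != si[bi]
    csr <- build_csr(length(sets), si[ai][keep], si[bi][keep], jw[keep])
    sig_sets <- sample_sigma_matrix(length(sets), csr, config, round = r)
    v <- sig_sets[si, , drop = FALSE] * rel            # bubble-level states
    obj <- if (nrow(coup) > 0L) {
      as.numeric(coup$s %*% (v[ai, , drop = FALSE] * v[bi, , drop = FALSE]))
    } else {
      rep(0, config$n_samples)
    }
    k_best <- which.max(obj)
    best_v <- v[, k_best]
    best_obj <- obj[k_best]
    n_merged <- 0L
    if (nrow(coup) > 0L) {
      tl <- tally_pairs(coup, ai, bi, v)
      tl <- tl |>
        dplyr::mutate(delta = abs(.data$n_same - .data$n_opposite),
                      depth = .data$n_same + .data$n_opposite,
                      sa = set_id[ai], sb = set_id[bi]) |>
        dplyr::filter(.data$sa != .data$sb) |>
        dplyr::arrange(dplyr::desc(.data$delta), dplyr::desc(.data$depth),
                       .data$bubble_a, .data$bubble_b)
      n_top <- ceiling(config$merge_fraction * nrow(tl))
      touched <- integer(0)
      for (e in seq_len(min(n_top, nrow(tl)))) {
        a <- match(tl$bubble_a[e], bids); b <- match(tl$bubble_b[e], bids)
        pa <- set_id[a]; pb <- set_id[b]
        if (pa == pb || pa %in% touched || pb %in% touched) next
        m <- if (tl$n_same[e] >= tl$n_opposite[e]) 1 else -1
        flip <- m * rel[a] * rel[b]
        members <- set_id == pb
        rel[members] <- rel[members] * flip
        set_id[members] <- pa
        touched <- c(touched, pa, pb)
        n_merged <- n_merged + 1L
      }
    }
    largest <- max(tabulate(set_id, nbins = B))
    if (largest > 2^r) {
      stop("internal error: merged set of size ", largest,
           " exceeds 2^r after round ", r)
    }
    log_rows[[r]] <- tibble::tibble(round = r, best_objective = best_obj,
                                    n_merged = n_merged,
                                    largest_set = largest)
  }
  orientation <- as.integer(ifelse(best_v == 1, 0L, 1L))
  supported <- bids %in% c(coup$bubble_a, coup$bubble_b)
  fit_bubbles <- sides |>
    dplyr::mutate(orientation = orientation,
                  merged_set = bids[set_id],
                  supported = supported)
  new_phase_fit(fit_bubbles, method = "contacts", anchored = FALSE,
                objective = best_obj,
                rounds = dplyr::bind_rows(log_rows), config = config)
}

new_phase_fit <- function(fit_bubbles, method, anchored, objective = NA_real_,
                          rounds = NULL, config = NULL) {
  segments <- dplyr::bind_rows(
    tibble::tibble(segment = fit_bubbles$side0, side = 0L,
                   bubble = fit_bubbles$bubble),
    tibble::tibble(segment = fit_bubbles$side1, side = 1L,
                   bubble = fit_bubbles$bubble)) |>
    dplyr::left_join(fit_bubbles[, c("bubble", "orientation", "merged_set",
                                     "supported")], by = "bubble") |>
    dplyr::mutate(haplotype = ifelse(.data$side == .data$orientation, 0L, 1L)) |>
    dplyr::select("segment", "haplotype", "bubble", "merged_set",
                  "supported") |>
    dplyr::arrange(.data$bubble, .data$haplotype)
  structure(list(bubbles = fit_bubbles, segments = segments,
                 objective = objective, method = method, anchored = anchored,
                 rounds = rounds, config = config),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit> method=", x$method, ": ", nrow(x$bubbles), " bubbles (",
      sum(x$bubbles$supported), " supported), objective=", x$objective,
      if (x$anchored) ", globally anchored" else ", phase up to global flip",
      "\n", sep = "")
  invisible(x)
}

#' Write / read the phase table
#'
#' The phase table is a TSV with one row per bubble side: `segment`,
#' `haplotype` (0/1), `bubble`, `merged_set`, `supported`.
#'
#' @param fit A `phase_fit` object (or its [tidy()] tibble).
#' @param path File path.
#' @return `path` invisibly, or the tibble for the reader.
#' @export
write_phase_table <- function(fit, path) {
  tab <- if (inherits(fit, "phase_fit")) fit$segments else fit
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_phase_table
#' @export
read_phase_table <- function(path) {
  readr::read_tsv(path, col_types = "ciiil", progress = FALSE)
}
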