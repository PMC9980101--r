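#' Synthetic diploid fixture configuration
#'
#' Conditions for the seeded generator of diploid assembly graphs, contact
#' reads and trio k-mer sets. Defaults describe the standard simulation used
#' throughout the package's closed-loop tests: 10 chains of 20 bubbles
#' (200 bubbles), 1 kbp segments at 1% heterozygous divergence, 20 contact
#' reads per adjacent bubble pair with geometric distance decay, signal
#' ratio 0.95, Pore-C concatemers with Poisson(8) subreads, and a
#' high/low mapping-quality mixture so mapQ filtering is exercised.
#'
#' @param n_chains Number of bubble chains. Default 10.
#' @param bubbles_per_chain Bubbles per chain. Default 20.
#' @param het_divergence Substitution fraction between the two sides of a
#'   bubble. Default 0.01.
#' @param segment_bp Segment length in bp. Default 1000.
#' @param contacts_per_pair Reads anchored at each adjacent bubble pair.
#'   Default 20.
#' @param signal_ratio Probability that a contact endpoint stays on the
#'   read's haplotype (cis); must exceed 0.5 or the truth is
#'   unidentifiable. Default 0.95.
#' @param subread_mode `"porec"` (Poisson-distributed subreads, all-vs-all
#'   contacts) or `"hic"` (exactly two endpoints per read).
#' @param porec_mean Mean subreads per Pore-C concatemer. Default 8.
#' @param tangle_rate Probability that an interior homozygous node gets a
#'   tangle branch, splitting its chain. Default 0.
#' @param max_pair_distance Maximum bubble-pair distance receiving Hi-C
#'   reads; a pair at distance d gets `contacts_per_pair / 2^(d-1)` reads.
#'   Default 3.
#' @param p_low_mapq Fraction of records drawn at `mapq_low` instead of
#'   `mapq_high`. Default 0.1.
#' @param mapq_high,mapq_low The two mapping-quality components. Defaults
#'   60 and 0.
#' @param prob_flip Probability a segment is stored reverse-complemented
#'   relative to its traversal, exercising orientation handling. Default 0.2.
#' @param parent_coverage Multiplier applied to parental k-mer counts,
#'   emulating read-derived counting depth. Default 30.
#' @param seed Integer seed; everything the generator emits is a pure
#'   function of this configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chains = 10L, bubbles_per_chain = 20L,
                       het_divergence = 0.01, segment_bp = 1000L,
                       contacts_per_pair = 20L, signal_ratio = 0.95,
                       subread_mode = c("porec", "hic"), porec_mean = 8,
                       tangle_rate = 0, max_pair_distance = 3L,
                       p_low_mapq = 0.1, mapq_high = 60L, mapq_low = 0L,
                       prob_flip = 0.2, parent_coverage = 30L, seed = 1L) {
  subread_mode <- match.arg(subread_mode)
  stopifnot(n_chains >= 1, bubbles_per_chain >= 1, segment_bp >= 1,
            contacts_per_pair >= 1, signal_ratio > 0.5, signal_ratio <= 1,
            het_divergence >= 0, het_divergence <= 1,
            tangle_rate >= 0, tangle_rate <= 1, porec_mean > 0,
            max_pair_distance >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 bubbles_per_chain = as.integer(bubbles_per_chain),
                 het_divergence = het_divergence,
                 segment_bp = as.integer(segment_bp),
                 contacts_per_pair = as.integer(contacts_per_pair),
                 signal_ratio = signal_ratio,
                 subread_mode = subread_mode,
                 porec_mean = porec_mean,
                 tangle_rate = tangle_rate,
                 max_pair_distance = as.integer(max_pair_distance),
                 p_low_mapq = p_low_mapq,
                 mapq_high = as.integer(mapq_high),
                 mapq_low = as.integer(mapq_low),
                 prob_flip = prob_flip,
                 parent_coverage = as.integer(parent_coverage),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a Bernoulli(rate) set of positions, always to a different base
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(runif(length(bases)) < rate)
  for (i in idx) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate a diploid assembly graph with planted bubble chains
#'
#' Builds chains of alternating homozygous segments and heterozygous bubble
#' pairs (hom--het--hom topology), with bubble sides as mutated copies at
#' `het_divergence`, random storage orientations, and optional tangle
#' branches that split chains. Deterministic per seed. Truth (bubble map,
#' per-segment haplotype, per-bubble orientation, chain fragments) is
#' emitted alongside so every downstream test is closed-loop.
#'
#' @param config A [sim_config()].
#' @return A list of class `diploid_sim` with fields `graph`
#'   ([assembly_graph()]), `bubbles` (truth bubble map), `phase`
#'   (tibble `segment`, `haplotype`, `bubble`, `supported`),
#'   `bubble_phase` (tibble `bubble`, `orientation`), `chains` (truth chain
#'   fragments: `chain`, `fragment`, `pos`, `kind`, `segment`, `bubble`),
#'   `config`.
#' @export
simulate_diploid_graph <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    seg_rows <- list(); link_rows <- list()
    bub_rows <- list(); phase_rows <- list(); chain_rows <- list()
    bubble_id <- 0L
    for (cc in seq_len(config$n_chains)) {
      nb <- config$bubbles_per_chain
      hom_names <- sprintf("c%02d_h%03d", cc, 0:nb)
      hom_orient <- sample(c("+", "-"), nb + 1L, replace = TRUE,
                           prob = c(1 - config$prob_flip, config$prob_flip))
      for (j in 0:nb) {
        g <- random_dna(config$segment_bp)
        stored <- if (hom_orient[j + 1L] == "+") g else revcomp(g)
        seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
          name = hom_names[j + 1L], sequence = stored,
          length = nchar(stored))
      }
      chain_bubbles <- integer(nb)
      for (i in seq_len(nb)) {
        bubble_id <- bubble_id + 1L
        chain_bubbles[i] <- bubble_id
        hap0_seq <- random_dna(config$segment_bp)
        hap1_seq <- mutate_sequence(hap0_seq, config$het_divergence)
        a_name <- sprintf("c%02d_b%03d_a", cc, i)
        b_name <- sprintf("c%02d_b%03d_b", cc, i)
        a_is_hap0 <- runif(1) < 0.5
        orients <- sample(c("+", "-"), 2L, replace = TRUE,
                          prob = c(1 - config$prob_flip, config$prob_flip))
        seqs <- if (a_is_hap0) c(hap0_seq, hap1_seq) else
          c(hap1_seq, hap0_seq)
        for (w in 1:2) {
          nm <- c(a_name, b_name)[w]
          stored <- if (orients[w] == "+") seqs[w] else revcomp(seqs[w])
          seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
            name = nm, sequence = stored, length = nchar(stored))
          link_rows[[length(link_rows) + 1L]] <- tibble::tibble(
            from = hom_names[i], from_orient = hom_orient[i],
            to = nm, to_orient = orients[w])
          link_rows[[length(link_rows) + 1L]] <- tibble::tibble(
            from = nm, from_orient = orients[w],
            to = hom_names[i + 1L], to_orient = hom_orient[i + 1L])
        }
        bub_rows[[length(bub_rows) + 1L]] <- tibble::tibble(
          bubble = bubble_id, side0 = a_name, side1 = b_name)
        phase_rows[[length(phase_rows) + 1L]] <- tibble::tibble(
          segment = c(a_name, b_name),
          haplotype = if (a_is_hap0) c(0L, 1L) else c(1L, 0L),
          bubble = bubble_id)
      }
      # tangle branches on interior homs: an extra segment entering the hom
      # makes the upstream bubble and both flanking homs fail the strict
      # diploid-chain rules, splitting the chain
      tangled <- integer(0)
      if (nb >= 2L && config$tangle_rate > 0) {
        cand <- seq_len(nb - 1L)
        tangled <- cand[runif(length(cand)) < config$tangle_rate]
        for (j in tangled) {
          t_name <- sprintf("c%02d_t%03d", cc, j)
          seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
            name = t_name, sequence = random_dna(config$segment_bp),
            length = config$segment_bp)
          link_rows[[length(link_rows) + 1L]] <- tibble::tibble(
            from = t_name, from_orient = "+",
            to = hom_names[j + 1L], to_orient = hom_orient[j + 1L])
        }
      }
      # truth chain fragments: positions 1,3,5,... are homs 0..nb, even
      # positions are bubbles; a tangle at hom j removes the hom, the
      # upstream bubble and the upstream hom
      n_pos <- 2L * nb + 1L
      removed <- logical(n_pos)
      for (j in tangled) {
        removed[c(2L * j - 1L, 2L * j, 2L * j + 1L)] <- TRUE
      }
      frag <- cumsum(removed)  # fragment index for surviving runs
      pos <- seq_len(n_pos)
      keep <- !removed
      is_hom <- pos %% 2L == 1L
      seg_vec <- rep(NA_character_, n_pos)
      seg_vec[is_hom] <- hom_names[(pos[is_hom] + 1L) %/% 2L]
      bub_vec <- rep(NA_integer_, n_pos)
      bub_vec[!is_hom] <- chain_bubbles[pos[!is_hom] %/% 2L]
      chain_rows[[length(chain_rows) + 1L]] <- tibble::tibble(
        chain = cc,
        fragment = match(frag[keep], sort(unique(frag[keep]))),
        pos = pos[keep],
        kind = ifelse(is_hom[keep], "hom", "het"),
        segment = seg_vec[keep],
        bubble = bub_vec[keep])
    }
    bubbles <- new_bubble_map(dplyr::bind_rows(bub_rows))
    phase <- dplyr::bind_rows(phase_rows) |>
      dplyr::mutate(supported = TRUE)
    bubble_phase <- phase |>
      dplyr::inner_join(bubbles, by = c("segment", "bubble")) |>
      dplyr::filter(.data$side == 0L) |>
      dplyr::transmute(.data$bubble, orientation = .data$haplotype) |>
      dplyr::arrange(.data$bubble)
    graph <- assembly_graph(segments = dplyr::bind_rows(seg_rows),
                            links = dplyr::bind_rows(link_rows))
    structure(list(graph = graph, bubbles = bubbles, phase = phase,
                   bubble_phase = bubble_phase,
                   chains = dplyr::bind_rows(chain_rows), config = config),
              class = "diploid_sim")
  })
}

#' @export
print.diploid_sim <- function(x, ...) {
  cat("<diploid_sim> ", x$config$n_chains, " chains, ",
      nrow(x$bubbles) / 2L, " bubbles, ", nrow(x$graph$segments),
      " segments (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate proximity-ligation contact records on a planted graph
#'
#' Emits reads whose endpoints follow the planted haplotypes: each read
#' carries a true haplotype, its anchor endpoint lies on that haplotype, and
#' every further endpoint stays cis with probability `signal_ratio`. Hi-C
#' mode emits exactly two endpoints per read, with pairs at bubble distance
#' d receiving `contacts_per_pair / 2^(d-1)` reads (geometric distance
#' decay); Pore-C mode anchors `contacts_per_pair` concatemers per adjacent
#' pair and draws Poisson subread counts over consecutive bubbles. Mapping
#' qualities come from the two-component high/low mixture of the
#' configuration.
#'
#' @param sim A [simulate_diploid_graph()] result.
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @param seed Optional override of `config$seed` for the read-level
#'   randomness (the graph seed stays untouched).
#' @return Tibble of contact records (`read_id`, `segment`, `mapq`,
#'   `aln_len`) plus attribute `truth`: tibble (`contig`, `haplotype`) for
#'   the heterozygous segments.
#' @export
simulate_contacts <- function(sim, config = sim$config, seed = NULL) {
  stopifnot(inherits(sim, "diploid_sim"))
  seed <- seed %||% derive_seed(config$seed, 7L)
  seg_of <- sim$phase  # segment, haplotype, bubble
  seg_lookup <- setNames(seg_of$segment,
                         paste(seg_of$bubble, seg_of$haplotype))
  pick_seg <- function(bubble, hap) seg_lookup[paste(bubble, hap)]
  withr::with_seed(seed, {
    out <- list()
    read_n <- 0L
    for (cc in seq_len(config$n_chains)) {
      pref <- sprintf("c%02d_b", cc)
      bubs <- sort(unique(
        sim$bubbles$bubble[startsWith(sim$bubbles$segment, pref)]))
      nb <- length(bubs)
      if (nb < 2L) next
      if (config$subread_mode == "hic") {
        for (d in seq_len(min(config$max_pair_distance, nb - 1L))) {
          n_reads <- round(config$contacts_per_pair / 2^(d - 1))
          if (n_reads < 1L) next
          for (i in seq_len(nb - d)) {
            for (k in seq_len(n_reads)) {
              read_n <- read_n + 1L
              hap <- sample(0:1, 1L)
              hap2 <- if (runif(1) < config$signal_ratio) hap else 1L - hap
              out[[length(out) + 1L]] <- tibble::tibble(
                read_id = sprintf("r%07d", read_n),
                segment = unname(c(pick_seg(bubs[i], hap),
                                   pick_seg(bubs[i + d], hap2))))
            }
          }
        }
      } else {
        for (i in seq_len(nb - 1L)) {
          for (k in seq_len(config$contacts_per_pair)) {
            m <- rpois(1L, config$porec_mean)
            if (m < 1L) next
            m <- min(m, nb)
            start <- max(1L, min(i, nb - m + 1L))
            idx <- start:(start + m - 1L)
            read_n <- read_n + 1L
            hap <- sample(0:1, 1L)
            haps <- c(hap, ifelse(runif(m - 1L) < config$signal_ratio,
                                  hap, 1L - hap))
            out[[length(out) + 1L]] <- tibble::tibble(
              read_id = sprintf("r%07d", read_n),
              segment = unname(pick_seg(bubs[idx], haps)))
          }
        }
      }
    }
    rec <- dplyr::bind_rows(out)
    n <- nrow(rec)
    rec$mapq <- ifelse(runif(n) < config$p_low_mapq,
                       config$mapq_low, config$mapq_high)
    rec$mapq <- as.integer(rec$mapq)
    rec$aln_len <- as.integer(pmax(50L, round(rnorm(n, 300, 75))))
    truth <- sim$phase |>
      dplyr::transmute(contig = .data$segment,
                       haplotype = as.character(.data$haplotype))
    attr(rec, "truth") <- truth
    rec
  })
}

#' Serialize contact records as SAM
#'
#' Writes a minimal but valid SAM file against the graph segments (one
#' `@SQ` header line per segment, one primary alignment line per record
#' with a trivial full-match CIGAR), enough to exercise the real
#' alignment-parsing path.
#'
#' @param records Tibble from [simulate_contacts()].
#' @param graph The [assembly_graph()] whose segments are the references.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, graph, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  segs <- graph$segments
  writeLines(paste0("@SQ\tSN:", segs$name, "\tLN:", segs$length), con)
  # alignments must not run past the reference end
  ref_len <- setNames(segs$length, segs$name)
  alen <- pmin(records$aln_len, ref_len[records$segment])
  writeLines(paste(records$read_id, 0L, records$segment, 1L, records$mapq,
                   paste0(alen, "M"), "*", 0L, 0L,
                   strrep("A", alen), "*", sep = "\t"), con)
  invisible(path)
}

#' Simulate parental k-mer sets for a planted trio
#'
#' Assigns each chain's two haplotypes to the two parents at random, builds
#' each parent's transmitted genome (homozygous segments plus its
#' haplotype's bubble sides), and counts canonical 31-mers scaled by
#' `parent_coverage`. K-mers from shared homozygous segments cancel in the
#' subtraction, so parent-unique k-mers arise only from planted divergent
#' sites; at zero divergence both unique sets are empty.
#'
#' @param sim A [simulate_diploid_graph()] result.
#' @param config A [trio_config()] (k-mer size and thresholds).
#' @param seed Optional override for the parent-assignment randomness.
#' @return A list with `paternal`, `maternal` (k-mer count tibbles),
#'   `bubble_parent` (truth: `bubble`, `paternal_side`), and
#'   `parent_of_hap0` (per chain).
#' @export
simulate_trio_kmers <- function(sim, config = trio_config(), seed = NULL) {
  stopifnot(inherits(sim, "diploid_sim"))
  seed <- seed %||% derive_seed(sim$config$seed, 11L)
  withr::with_seed(seed, {
    parent_of_hap0 <- sample(c("pat", "mat"), sim$config$n_chains,
                             replace = TRUE)
    seqs <- setNames(sim$graph$segments$sequence, sim$graph$segments$name)
    pat_seqs <- character(); mat_seqs <- character()
    hom_segs <- setdiff(sim$graph$segments$name, sim$bubbles$segment)
    hom_segs <- hom_segs[!grepl("_t", hom_segs)]
    pat_seqs <- c(pat_seqs, seqs[hom_segs])
    mat_seqs <- c(mat_seqs, seqs[hom_segs])
    het <- sim$phase |>
      dplyr::mutate(chain = as.integer(sub("^c(\\d+)_.*$", "\\1",
                                           .data$segment)))
    het$pat_hap <- ifelse(parent_of_hap0[het$chain] == "pat", 0L, 1L)
    pat_seqs <- c(pat_seqs,
                  seqs[het$segment[het$haplotype == het$pat_hap]])
    mat_seqs <- c(mat_seqs,
                  seqs[het$segment[het$haplotype != het$pat_hap]])
    cov <- sim$config$parent_coverage
    pat <- count_sequence_kmers(pat_seqs, config$kmer_size) |>
      dplyr::mutate(count = .data$count * cov)
    mat <- count_sequence_kmers(mat_seqs, config$kmer_size) |>
      dplyr::mutate(count = .data$count * cov)
    bubble_parent <- het |>
      dplyr::filter(.data$haplotype == .data$pat_hap) |>
      dplyr::inner_join(sim$bubbles, by = c("segment", "bubble")) |>
      dplyr::transmute(.data$bubble, paternal_side = .data$side) |>
      dplyr::arrange(.data$bubble)
    list(paternal = pat, maternal = mat, bubble_parent = bubble_parent,
         parent_of_hap0 = parent_of_hap0)
  })
}

#' Write a k-mer count dump
#'
#' @param kmers Tibble (`kmer`, `count`).
#' @param path Output path (`KMER<TAB>COUNT`, no header).
#' @return `path`, invisibly.
#' @export
write_kmer_dump <- function(kmers, path) {
  readr::write_tsv(kmers, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
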