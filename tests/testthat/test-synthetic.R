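test_that("the generator is deterministic per seed, down to bytes on disk", {
  cfg <- sim_config(n_chains = 2L, bubbles_per_chain = 4L, segment_bp = 100L,
                    tangle_rate = 0.3, seed = 99L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the sequences
  sim_a <- simulate_diploid_graph(cfg)
  sim_b <- simulate_diploid_graph(sim_config(n_chains = 2L,
                                             bubbles_per_chain = 4L,
                                             segment_bp = 100L,
                                             tangle_rate = 0.3,
                                             seed = 100L))
  expect_false(identical(sim_a$graph$segments$sequence,
                         sim_b$graph$segments$sequence))
})

test_that("planted chains classify as expected by construction", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 3L, segment_bp = 80L,
               seed = 2L))
  lab <- classify_nodes(sim$graph, sim$bubbles)
  expect_true(all(lab$label[lab$segment %in% sim$bubbles$segment] ==
                    "diploid"))
  expect_true(all(lab$label[!lab$segment %in% sim$bubbles$segment] ==
                    "hom_in_chain"))
})

test_that("homology search re-detects nearly all planted bubbles at 1% divergence", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 2L, bubbles_per_chain = 15L, segment_bp = 500L,
               het_divergence = 0.01, seed = 71L))
  bm <- detect_bubbles(sim$graph, sketch_params())
  truth_pairs <- sim$bubbles |>
    bubble_pairs_key()
  got_pairs <- bm |>
    bubble_pairs_key()
  expect_gte(mean(truth_pairs %in% got_pairs), 0.99)
})

test_that("tangles strictly increase the chain count", {
  for (seed in 1:10) {
    base <- simulate_diploid_graph(
      sim_config(n_chains = 2L, bubbles_per_chain = 10L, segment_bp = 60L,
                 tangle_rate = 0, seed = seed))
    tangled <- simulate_diploid_graph(
      sim_config(n_chains = 2L, bubbles_per_chain = 10L, segment_bp = 60L,
                 tangle_rate = 0.25, seed = seed))
    n_base <- dplyr::n_distinct(paste(base$chains$chain,
                                      base$chains$fragment))
    n_tang <- dplyr::n_distinct(paste(tangled$chains$chain,
                                      tangled$chains$fragment))
    if (any(grepl("_t", tangled$graph$segments$name))) {
      expect_gt(n_tang, n_base)
    } else {
      expect_equal(n_tang, n_base)
    }
  }
})

test_that("the truth chain table matches what chain detection finds", {
  for (seed in c(5L, 6L)) {
    sim <- simulate_diploid_graph(
      sim_config(n_chains = 2L, bubbles_per_chain = 8L, segment_bp = 60L,
                 tangle_rate = 0.25, seed = seed))
    ch <- find_chains(sim$graph, classify_nodes(sim$graph, sim$bubbles),
                      sim$bubbles)
    # same number of chains, and the same sets of member segments
    frag_key <- function(df) {
      segs <- c(stats::na.omit(df$segment),
                sim$bubbles$segment[sim$bubbles$bubble %in%
                                      stats::na.omit(df$bubble)])
      paste(sort(segs), collapse = ",")
    }
    truth_frags <- sim$chains |>
      dplyr::group_by(chain, fragment) |>
      dplyr::group_map(~ frag_key(.x)) |>
      unlist()
    got_frags <- ch |>
      dplyr::group_by(chain_id) |>
      dplyr::summarise(key = paste(sort(segment), collapse = ","),
                       .groups = "drop")
    expect_setequal(got_frags$key, truth_frags)
  }
})

test_that("zero divergence leaves both parental unique sets empty", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 3L, segment_bp = 200L,
               het_divergence = 0, seed = 13L))
  trio <- simulate_trio_kmers(sim)
  ps <- build_parent_sets(trio$paternal, trio$maternal, trio_config())
  expect_equal(length(ps$paternal_unique), 0L)
  expect_equal(length(ps$maternal_unique), 0L)
  fit <- phase_by_trio(sim$bubbles, sim$graph, ps, trio_config())
  expect_false(any(fit$bubbles$supported))
})

test_that("Hi-C mode emits exactly two mappings per read", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 6L, segment_bp = 60L,
               subread_mode = "hic", seed = 23L))
  rec <- simulate_contacts(sim)
  st <- contact_stats(rec)
  expect_equal(st$alignments_per_read$n_alignments, 2L)
})

test_that("simulated SAM exercises the real parsing path end to end", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 4L, segment_bp = 100L,
               seed = 41L))
  rec <- simulate_contacts(sim)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(rec, sim$graph, sam)
  parsed <- parse_alignments(sam, contact_config(min_mapq = 0L), sim$graph)
  expect_equal(nrow(parsed), nrow(rec))
  expect_equal(build_contact_graph(parsed), build_contact_graph(rec),
               ignore_attr = TRUE)
})
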