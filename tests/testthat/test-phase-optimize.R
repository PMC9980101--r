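test_that("pair scores follow the four-contact sign structure", {
  bubbles <- mk_bubbles(c("a0", "a1"), c("b0", "b1"))
  contacts <- mk_contacts("a0 b0 5", "a1 b1 3")
  expect_equal(pair_score(bubbles, contacts, 1L, 2L, 0L, 0L), 8)
  expect_equal(pair_score(bubbles, contacts, 1L, 2L, 0L, 1L), -8)
  expect_equal(pair_score(bubbles, contacts, 1L, 2L, 1L, 1L), 8)
  # all four weights equal: uninformative pair
  eq <- mk_contacts("a0 b0 2", "a0 b1 2", "a1 b0 2", "a1 b1 2")
  for (oa in 0:1) for (ob in 0:1) {
    expect_equal(pair_score(bubbles, eq, 1L, 2L, oa, ob), 0)
  }
})

test_that("the total objective matches the first-principles scorer and is flip-invariant", {
  expect_equal(total_objective(
    tibble::tibble(bubble = 1:2, orientation = c(0L, 0L)),
    mk_bubbles(c("a0", "a1"), c("b0", "b1")),
    tibble::tibble(seg_a = character(), seg_b = character(),
                   weight = integer())), 0)
  for (seed in 1:10) {
    withr::with_seed(seed, inst <- random_instance(B = 5L))
    state <- withr::with_seed(seed, tibble::tibble(
      bubble = 1:5, orientation = sample(0:1, 5L, TRUE)))
    obj <- total_objective(state, inst$bubbles, inst$contacts)
    oracle <- score_state_oracle(
      setNames(state$orientation, state$bubble), inst$bubbles,
      inst$contacts)
    expect_equal(obj, oracle)
    flipped <- dplyr::mutate(state, orientation = 1L - orientation)
    expect_equal(total_objective(flipped, inst$bubbles, inst$contacts), obj)
  }
})

test_that("greedy passes are monotone and stop at 1-flip-optimal states", {
  bubbles <- mk_bubbles(c("a0", "a1"), c("b0", "b1"))
  contacts <- mk_contacts("a0 b0 5", "a1 b1 3")
  anti <- tibble::tibble(bubble = 1:2, orientation = c(0L, 1L))
  expect_equal(total_objective(anti, bubbles, contacts), -8)
  res <- withr::with_seed(1, greedy_pass(anti, bubbles, contacts))
  expect_equal(total_objective(res, bubbles, contacts), 8)

  for (seed in 1:15) {
    withr::with_seed(seed, {
      inst <- random_instance(B = 8L)
      state <- tibble::tibble(bubble = 1:8,
                              orientation = sample(0:1, 8L, TRUE))
      res <- greedy_pass(state, inst$bubbles, inst$contacts)
    })
    before <- total_objective(state, inst$bubbles, inst$contacts)
    after <- total_objective(res, inst$bubbles, inst$contacts)
    expect_gte(after, before)
    # no single flip improves the result
    for (b in 1:8) {
      one <- dplyr::mutate(res, orientation = ifelse(
        bubble == b, 1L - orientation, orientation))
      expect_lte(total_objective(one, inst$bubbles, inst$contacts), after)
    }
  }
})

test_that("a state at the exhaustive optimum is returned unchanged", {
  withr::with_seed(4, inst <- random_instance(B = 6L))
  best <- brute_force_optimum(inst$bubbles, inst$contacts)
  # find one optimal state by enumeration
  for (code in 0:(2^6 - 1)) {
    o <- as.integer(bitwAnd(bitwShiftR(code, 0:5), 1L))
    st <- tibble::tibble(bubble = 1:6, orientation = o)
    if (total_objective(st, inst$bubbles, inst$contacts) == best) break
  }
  res <- withr::with_seed(2, greedy_pass(st, inst$bubbles, inst$contacts))
  expect_equal(res$orientation, st$orientation)
})

test_that("restarted greedy reaches the exhaustive optimum on most 10-bubble instances", {
  hits <- 0L
  n_inst <- 40L
  for (seed in seq_len(n_inst)) {
    withr::with_seed(seed, inst <- random_instance(B = 10L))
    best <- brute_force_optimum(inst$bubbles, inst$contacts)
    reached <- withr::with_seed(1000L + seed, {
      max(vapply(1:50, function(k) {
        st <- tibble::tibble(bubble = 1:10,
                             orientation = sample(0:1, 10L, TRUE))
        total_objective(greedy_pass(st, inst$bubbles, inst$contacts),
                        inst$bubbles, inst$contacts)
      }, numeric(1)))
    })
    if (reached == best) hits <- hits + 1L
  }
  expect_gte(hits / n_inst, 0.9)
})

test_that("orientation sampling pins consistent pairs and leaves unlinked pairs near 50/50", {
  bubbles <- mk_bubbles(c("a0", "a1"), c("b0", "b1"), c("c0", "c1"))
  contacts <- mk_contacts("a0 b0 20", "a1 b1 20", "c0 c1 1")
  cfg <- sampler_config(n_samples = 100L, seed = 5L)
  tal <- sample_orientations(bubbles, contacts, cfg)
  ab <- dplyr::filter(tal, bubble_a == 1L, bubble_b == 2L)
  expect_equal(ab$n_same, 100L)
  expect_equal(ab$n_same + ab$n_opposite, 100L)

  # bubble 3 shares no contacts with 1 or 2: no tally rows, and direct
  # sampling of an uncoupled pair splits roughly binomially
  expect_false(3L %in% c(tal$bubble_a, tal$bubble_b))
  b2 <- mk_bubbles(c("x0", "x1"), c("y0", "y1"))
  c2 <- mk_contacts("x0 y0 1", "x0 y1 1")  # zero net coupling
  tal2 <- sample_orientations(b2, c2, sampler_config(n_samples = 100L,
                                                     seed = 9L))
  expect_lt(abs(tal2$n_same / 100 - 0.5), 0.2)
})

test_that("sampling and the full optimizer are reproducible and thread-invariant", {
  withr::with_seed(8, inst <- random_instance(B = 8L))
  cfg1 <- sampler_config(n_samples = 12L, n_rounds = 3L, seed = 77L,
                         n_threads = 1L)
  cfg8 <- sampler_config(n_samples = 12L, n_rounds = 3L, seed = 77L,
                         n_threads = 2L)
  t1 <- sample_orientations(inst$bubbles, inst$contacts, cfg1)
  t8 <- sample_orientations(inst$bubbles, inst$contacts, cfg8)
  expect_identical(t1, t8)
  f1 <- phase_by_contacts(inst$bubbles, inst$contacts, cfg1)
  f8 <- phase_by_contacts(inst$bubbles, inst$contacts, cfg8)
  expect_identical(f1$bubbles, f8$bubbles)
  expect_identical(f1$objective, f8$objective)
  # insertion order of the bubble map does not matter
  shuf <- withr::with_seed(3, inst$bubbles[sample(nrow(inst$bubbles)), ])
  f_shuf <- phase_by_contacts(shuf, inst$contacts, cfg1)
  expect_equal(dplyr::arrange(f_shuf$bubbles, bubble),
               dplyr::arrange(f1$bubbles, bubble))
})

test_that("merged sets respect the 2^r cap and merging is logged per round", {
  withr::with_seed(12, inst <- random_instance(B = 12L, p_edge = 0.6))
  cfg <- sampler_config(n_samples = 10L, n_rounds = 5L, seed = 2L)
  fit <- phase_by_contacts(inst$bubbles, inst$contacts, cfg)
  expect_equal(nrow(fit$rounds), 5L)
  expect_true(all(fit$rounds$largest_set <= 2^fit$rounds$round))
  expect_lte(fit$rounds$largest_set[1L], 2L)
})

test_that("a single-sample single-round run degenerates to one greedy pass", {
  withr::with_seed(14, inst <- random_instance(B = 6L))
  cfg <- sampler_config(n_samples = 1L, n_rounds = 1L, seed = 5L)
  fit <- phase_by_contacts(inst$bubbles, inst$contacts, cfg)
  # result is 1-flip-optimal
  st <- dplyr::transmute(fit$bubbles, bubble, orientation)
  base <- total_objective(st, inst$bubbles, inst$contacts)
  expect_equal(base, fit$objective)
  for (b in 1:6) {
    one <- dplyr::mutate(st, orientation = ifelse(bubble == b,
                                                  1L - orientation,
                                                  orientation))
    expect_lte(total_objective(one, inst$bubbles, inst$contacts), base)
  }
})

test_that("bubbles without contacts are flagged unsupported", {
  bubbles <- mk_bubbles(c("a0", "a1"), c("b0", "b1"), c("z0", "z1"))
  contacts <- mk_contacts("a0 b0 4")
  fit <- phase_by_contacts(bubbles, contacts,
                           sampler_config(n_samples = 5L, n_rounds = 2L,
                                          seed = 1L))
  expect_equal(fit$bubbles$supported, c(TRUE, TRUE, FALSE))
})

test_that("tidy, glance and the phase table round-trip expose the fit", {
  withr::with_seed(6, inst <- random_instance(B = 4L))
  fit <- phase_by_contacts(inst$bubbles, inst$contacts,
                           sampler_config(n_samples = 5L, n_rounds = 2L,
                                          seed = 3L))
  td <- tidy(fit)
  expect_setequal(td$segment, inst$bubbles$segment)
  gl <- glance(fit)
  expect_equal(gl$n_bubbles, 4L)
  expect_equal(gl$method, "contacts")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phase_table(fit, f)
  expect_equal(read_phase_table(f), td)
  expect_s3_class(autoplot(fit), "ggplot")
})
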