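# hand-written SAM with the flag combinations the parser must honour
write_test_sam <- function(path) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:a\tLN:100",
    "@SQ\tSN:b\tLN:100",
    "@SQ\tSN:c\tLN:100",
    # proper Hi-C pair, mapq 60
    "r1\t0\ta\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r1\t0\tb\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    # mapq 0 record (dropped at min_mapq 1)
    "r2\t0\ta\t1\t0\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r2\t0\tc\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    # unmapped mate of r3 (flag 4): only one usable record remains
    "r3\t0\tb\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    # secondary (256) and supplementary (2048) records
    "r4\t0\ta\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r4\t256\tb\t1\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t2048\tc\t1\t60\t50M\t*\t0\t0\t*\t*"
  ), path)
}

test_that("alignment parsing honours flags and the mapQ threshold", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam)
  rec <- parse_alignments(sam, contact_config(min_mapq = 1L))
  expect_setequal(rec$read_id, c("r1", "r2", "r3", "r4"))
  # r1 keeps both mates, grouped by read name
  expect_equal(sum(rec$read_id == "r1"), 2L)
  # the mapq-0 record of r2 is dropped (usable contacts require mapQ > 0)
  expect_equal(rec$segment[rec$read_id == "r2"], "c")
  # unmapped mate contributes nothing
  expect_equal(sum(rec$read_id == "r3"), 1L)
  # secondary and supplementary dropped by default
  expect_equal(rec$segment[rec$read_id == "r4"], "a")
  # supplementary kept on request, secondary never
  rec_s <- parse_alignments(sam, contact_config(min_mapq = 1L,
                                                include_supplementary = TRUE))
  expect_setequal(rec_s$segment[rec_s$read_id == "r4"], c("a", "c"))
})

test_that("records aligned to segments outside the graph are dropped with a warning", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam)
  g <- mk_graph(c(a = "ACGT", b = "GGCC"))  # no segment c
  expect_warning(rec <- parse_alignments(sam, contact_config(), g),
                 "dropped")
  expect_false("c" %in% rec$segment)
})

test_that("contact graph accumulates all-vs-all pairs per read", {
  # a Hi-C pair gives one edge of weight 1
  rec <- tibble::tibble(read_id = c("r1", "r1"), segment = c("a", "b"))
  cg <- build_contact_graph(rec)
  expect_equal(cg, tibble::tibble(seg_a = "a", seg_b = "b", weight = 1L))

  # a Pore-C read over 4 distinct segments gives all C(4,2) = 6 pairs
  rec4 <- tibble::tibble(read_id = "p", segment = c("a", "b", "c", "d"))
  cg4 <- build_contact_graph(rec4)
  expect_equal(nrow(cg4), 6L)
  expect_true(all(cg4$weight == 1L))

  # all subreads on one segment: no self-loop edge
  rec1 <- tibble::tibble(read_id = "q", segment = rep("a", 5L))
  expect_equal(nrow(build_contact_graph(rec1)), 0L)

  # a Pore-C read with exactly two mapped segments equals a Hi-C pair
  recp <- tibble::tibble(read_id = "x", segment = c("a", "b", "b"))
  expect_equal(build_contact_graph(recp), cg)
})

test_that("contact weights are additive over record batches", {
  withr::with_seed(5, {
    segs <- paste0("s", 1:6)
    batch <- function(n, off) tibble::tibble(
      read_id = paste0("r", off + rep(1:n, each = 2L)),
      segment = sample(segs, 2L * n, TRUE))
    b1 <- batch(40L, 0L); b2 <- batch(30L, 100L)
    merged <- build_contact_graph(dplyr::bind_rows(b1, b2))
    summed <- dplyr::bind_rows(build_contact_graph(b1),
                               build_contact_graph(b2)) |>
      dplyr::group_by(seg_a, seg_b) |>
      dplyr::summarise(weight = sum(weight), .groups = "drop") |>
      dplyr::arrange(seg_a, seg_b)
    expect_equal(merged, summed)
  })
})

test_that("raising min_mapq never increases any edge weight", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 5L, segment_bp = 120L,
               seed = 3L))
  rec <- simulate_contacts(sim)
  weights_at <- function(q) {
    build_contact_graph(dplyr::filter(rec, mapq >= q)) |>
      dplyr::rename(!!paste0("w", q) := weight)
  }
  cmp <- dplyr::left_join(weights_at(0L), weights_at(30L),
                          by = c("seg_a", "seg_b")) |>
    dplyr::mutate(w30 = tidyr::replace_na(w30, 0L))
  expect_true(all(cmp$w30 <= cmp$w0))
})

test_that("reads over the alignment cap are skipped entirely", {
  rec <- tibble::tibble(read_id = "big", segment = paste0("s", 1:10))
  expect_equal(nrow(build_contact_graph(
    rec, contact_config(max_alignments_per_read = 5L))), 0L)
  expect_equal(nrow(build_contact_graph(
    rec, contact_config(max_alignments_per_read = 10L))), 45L)
})

test_that("contact graphs round-trip through the TSV interchange format", {
  cg <- mk_contacts("a b 5", "a c 2", "b c 7")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_graph(cg, f)
  expect_equal(read_contact_graph(f), cg)
})
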