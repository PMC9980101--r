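# canonical hom -- (het pair) -- hom fixture
clean_chain_graph <- function() {
  g <- mk_graph(c(h1 = "AATT", b0 = "CCCC", b1 = "CGCC", h2 = "GGAA",
                  c0 = "TTTT", c1 = "TATT", h3 = "ACAC"),
                c("h1 + b0 +", "h1 + b1 +", "b0 + h2 +", "b1 + h2 +",
                  "h2 + c0 +", "h2 + c1 +", "c0 + h3 +", "c1 + h3 +"))
  list(graph = g, bubbles = mk_bubbles(c("b0", "b1"), c("c0", "c1")))
}

test_that("clean chains classify as diploid bubbles and in-chain homs", {
  fx <- clean_chain_graph()
  lab <- classify_nodes(fx$graph, fx$bubbles)
  lab <- setNames(lab$label, lab$segment)
  expect_equal(unname(lab[c("b0", "b1", "c0", "c1")]), rep("diploid", 4L))
  expect_equal(unname(lab[c("h1", "h2", "h3")]), rep("hom_in_chain", 3L))
})

test_that("a bubble side with three neighbours on one side is excluded", {
  g <- mk_graph(c(b0 = "CCCC", b1 = "GGGG", x = "AAAA", y = "TTTT",
                  z = "ACGT", h = "TGCA"),
                c("h + b0 +", "h + b1 +",
                  "b0 + x +", "b0 + y +", "b0 + z +"))
  bm <- mk_bubbles(c("b0", "b1"))
  lab <- classify_nodes(g, bm)
  expect_equal(lab$label[lab$segment == "b0"], "other")
  expect_equal(lab$label[lab$segment == "b1"], "other")
})

test_that("classification agrees with the literal brute-force checker on random graphs", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      fx <- random_messy_graph(n_nodes = 30L, n_bubbles = 6L, n_links = 28L)
    })
    got <- classify_nodes(fx$graph, fx$bubbles)
    want <- naive_classify(fx$graph, fx$bubbles)
    expect_equal(dplyr::arrange(got, segment), dplyr::arrange(want, segment),
                 info = paste("seed", seed))
  }
})

test_that("chains traverse hom-het alternation and isolated bubbles stand alone", {
  fx <- clean_chain_graph()
  ch <- find_chains(fx$graph, classify_nodes(fx$graph, fx$bubbles),
                    fx$bubbles)
  expect_equal(dplyr::n_distinct(ch$chain_id), 1L)
  expect_equal(max(ch$element), 5L)  # h1, bubble, h2, bubble, h3
  expect_equal(sum(ch$kind == "hom"), 3L)
  expect_equal(sum(ch$kind == "het") / 2L, 2L)

  g1 <- mk_graph(c(x0 = "AC", x1 = "GT"))
  b1 <- mk_bubbles(c("x0", "x1"))
  ch1 <- find_chains(g1, classify_nodes(g1, b1), b1)
  expect_equal(dplyr::n_distinct(ch1$chain_id), 1L)
  expect_equal(max(ch1$element), 1L)
  expect_equal(ch1$kind, c("het", "het"))
})

test_that("five bubbles with four interior homs form one nine-element chain", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 5L, segment_bp = 80L,
               seed = 21L))
  # drop the terminal homs to match the bare 5-bubble / 4-hom topology
  keep <- setdiff(sim$graph$segments$name, c("c01_h000", "c01_h005"))
  g <- assembly_graph(
    segments = dplyr::filter(sim$graph$segments, name %in% keep),
    links = dplyr::filter(sim$graph$links, from %in% keep, to %in% keep))
  ch <- find_chains(g, classify_nodes(g, sim$bubbles), sim$bubbles)
  expect_equal(dplyr::n_distinct(ch$chain_id), 1L)
  expect_equal(max(ch$element), 9L)
})

test_that("a tangle interrupts a chain into two chains", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 1L, bubbles_per_chain = 6L, segment_bp = 80L,
               seed = 9L))
  g <- sim$graph
  # plant a tangle branch entering hom 3 the way the generator would
  hom <- "c01_h003"
  hom_or <- unique(
    g$links$to_orient[g$links$to == hom &
                        startsWith(g$links$from, "c01_b003")])
  tangle_links <- tibble::tibble(from = "tangle", from_orient = "+",
                                 to = hom, to_orient = hom_or[[1L]])
  g2 <- assembly_graph(
    segments = dplyr::bind_rows(g$segments,
                                tibble::tibble(name = "tangle",
                                               sequence = "ACGTACGT",
                                               length = 8L)),
    links = dplyr::bind_rows(g$links, tangle_links))
  ch <- find_chains(g2, classify_nodes(g2, sim$bubbles), sim$bubbles)
  expect_equal(dplyr::n_distinct(ch$chain_id), 2L)
  expect_false(any(ch$segment == "tangle"))
  # hand enumeration: bubble 3, hom 2 and hom 3 drop out
  expect_false(any(ch$segment %in%
                     c("c01_b003_a", "c01_b003_b", "c01_h002", "c01_h003")))
})

test_that("unzipping duplicates homs, splits unphased bubbles and conserves bases", {
  fx <- clean_chain_graph()
  ch <- find_chains(fx$graph, classify_nodes(fx$graph, fx$bubbles),
                    fx$bubbles)
  phase <- tibble::tibble(segment = c("b0", "b1", "c0", "c1"),
                          haplotype = c(0L, 1L, 1L, 0L),
                          bubble = c(1L, 1L, 2L, 2L), supported = TRUE)
  hp <- unzip_chains(ch, phase, fx$graph)
  path_of <- function(h) hp$segment[hp$haplotype == h][order(hp$step[hp$haplotype == h])]
  expect_equal(path_of(0L), c("h1", "b0", "h2", "c1", "h3"))
  expect_equal(path_of(1L), c("h1", "b1", "h2", "c0", "h3"))
  # conservation: unzipped bp == 2 * hom bp + both het side bp
  len <- setNames(fx$graph$segments$length, fx$graph$segments$name)
  expect_equal(sum(len[hp$segment]),
               2L * sum(len[c("h1", "h2", "h3")]) +
                 sum(len[c("b0", "b1", "c0", "c1")]))

  # unsupported second bubble splits the chain; its sides are excluded
  phase2 <- dplyr::mutate(phase, supported = bubble != 2L)
  hp2 <- unzip_chains(ch, phase2, fx$graph)
  expect_true(all(hp2$chain_fragmented))
  expect_equal(sort(unique(hp2$fragment)), 1:2)
  expect_false(any(hp2$segment %in% c("c0", "c1")))
})

test_that("every emitted haplotype step is backed by an input link", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 2L, bubbles_per_chain = 6L, segment_bp = 80L,
               seed = 33L))
  ch <- find_chains(sim$graph, classify_nodes(sim$graph, sim$bubbles),
                    sim$bubbles)
  hp <- unzip_chains(ch, sim$phase, sim$graph)
  st <- naive_all_steps(sim$graph$links)
  step_keys <- paste(st$seg, st$o, st$to, st$toor)
  walks <- split(hp, list(hp$chain_id, hp$fragment, hp$haplotype),
                 drop = TRUE)
  for (w in walks) {
    w <- w[order(w$step), ]
    if (nrow(w) < 2L) next
    for (i in seq_len(nrow(w) - 1L)) {
      expect_true(paste(w$segment[i], w$orient[i], w$segment[i + 1L],
                        w$orient[i + 1L]) %in% step_keys)
    }
  }
})

test_that("unzipped haplotype NG50 never falls below that of the raw phased segments", {
  sim <- simulate_diploid_graph(
    sim_config(n_chains = 3L, bubbles_per_chain = 6L, segment_bp = 120L,
               seed = 44L))
  ch <- find_chains(sim$graph, classify_nodes(sim$graph, sim$bubbles),
                    sim$bubbles)
  hp <- unzip_chains(ch, sim$phase, sim$graph)
  len <- setNames(sim$graph$segments$length, sim$graph$segments$name)
  genome <- sum(sim$graph$segments$length)
  raw_ng <- ngx(len[sim$bubbles$segment], genome)
  unz <- hp |>
    dplyr::group_by(chain_id, fragment, haplotype) |>
    dplyr::summarise(bp = sum(len[segment]), .groups = "drop")
  expect_gte(ngx(unz$bp, genome), raw_ng)
})

test_that("chain summaries report bubbles, homs and per-haplotype bases", {
  fx <- clean_chain_graph()
  ch <- find_chains(fx$graph, classify_nodes(fx$graph, fx$bubbles),
                    fx$bubbles)
  phase <- tibble::tibble(segment = c("b0", "b1", "c0", "c1"),
                          haplotype = c(0L, 1L, 0L, 1L),
                          bubble = c(1L, 1L, 2L, 2L), supported = TRUE)
  hp <- unzip_chains(ch, phase, fx$graph)
  cs <- chain_summary(ch, hp, fx$graph)
  expect_equal(cs$n_bubbles, 2L)
  expect_equal(cs$n_homs, 3L)
  expect_equal(cs$hap0_bp, cs$hap1_bp)
  expect_equal(cs$hap0_bp, 4L * 3L + 4L * 2L)  # 3 homs + 2 het sides, 4 bp each
})
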