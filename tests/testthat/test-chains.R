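test_that("bubbles sharing an endpoint node link into one chain", {
  # two diamonds sharing m: s..m..t
  g <- g_from(c("s", "a", "b", "m", "c", "d", "t"),
              c("s R a L 0", "s R b L 0", "a R m L 0", "b R m L 0",
                "m R c L 0", "m R d L 0", "c R t L 0", "d R t L 0"))
  b <- detect_bubbles(g)
  ch <- bubble_chains(b, g)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$length_in_bubbles, 2)
  expect_equal(ch[[1]]$ends, c("s", "t"))
})

test_that("an isolated bubble forms a chain of length one", {
  g <- diamond_graph()
  ch <- bubble_chains(detect_bubbles(g), g)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$length_in_bubbles, 1)
  expect_equal(ch[[1]]$id, 1)
})

test_that("an endpoint shared by three bubbles breaks the chain", {
  # a well-formed superbubble decomposition can attach at most one bubble per
  # node side, so a triple-shared endpoint cannot arise from detect_bubbles();
  # the chain builder still has to refuse to thread a chain through one.
  # Fabricate three diamonds fanning off node m on a graph that carries all
  # the needed edges.
  g <- g_from(c("x", "p", "q", "m", "c", "d", "y", "e", "f", "z"),
              c("x R p L 0", "x R q L 0", "p R m L 0", "q R m L 0",
                "m R c L 0", "m R d L 0", "c R y L 0", "d R y L 0",
                "m R e L 0", "m R f L 0", "e R z L 0", "f R z L 0"))
  mk <- function(sn, ss, tn, ts, interior) {
    structure(list(source = list(node = sn, side = ss),
                   sink = list(node = tn, side = ts),
                   interior = interior, type = "simple",
                   parent = NA_integer_), class = "gfab_bubble")
  }
  fake <- structure(list(bubbles = list(
    mk("m", "L", "x", "R", c("p", "q")),
    mk("m", "R", "y", "L", c("c", "d")),
    mk("m", "R", "z", "L", c("e", "f"))
  ), n_nodes = bdg_size(g)), class = "gfab_bubbles")
  ch <- bubble_chains(fake, g)
  expect_length(ch, 3)
  expect_true(all(vapply(ch, `[[`, integer(1), "length_in_bubbles") == 1))
})

test_that("the figure-style chain reports one simple + one super with a nested simple", {
  g <- fig_chain_graph()
  b <- detect_bubbles(g)
  ch <- bubble_chains(b, g)
  rep <- detection_report(g, b, ch)
  expect_equal(rep$counts$simple_bubbles, 2)
  expect_equal(rep$counts$superbubbles, 1)
  expect_equal(rep$counts$insertion_bubbles, 0)
  expect_equal(rep$counts$nested_simple_bubbles, 1)
  expect_equal(rep$counts$chains, 1)
  expect_equal(rep$counts$longest_chain_in_bubbles, 2)
  # nested bubble is reported inside its parent, not as a chain member
  expect_length(ch, 1)
  expect_equal(ch[[1]]$length_in_bubbles, 2)
  cj <- rep$chains[[1]]
  types <- vapply(cj$bubbles, `[[`, "", "type")
  expect_setequal(types, c("simple", "super"))
  super <- cj$bubbles[[which(types == "super")]]
  expect_length(super$nested, 1)
  expect_equal(super$nested[[1]]$type, "simple")
})

test_that("chain lengths in bases follow the longest-branch-walk convention", {
  # diamond with unequal branches, blunt edges: span = |s| + max(|a|,|b|) + |t|
  g <- g_from(c("s", "a", "b", "t"),
              c("s R a L 0", "s R b L 0", "a R t L 0", "b R t L 0"),
              seqs = c("AAAA", "CCCCCC", "GG", "TTT"))
  ch <- bubble_chains(detect_bubbles(g), g)
  expect_equal(ch[[1]]$length_in_bases, 4 + 6 + 3)
  # shared endpoint counted once across two bubbles
  g2 <- g_from(c("s", "a", "b", "m", "c", "d", "t"),
               c("s R a L 0", "s R b L 0", "a R m L 0", "b R m L 0",
                 "m R c L 0", "m R d L 0", "c R t L 0", "d R t L 0"),
               seqs = c("AAAA", "C", "CC", "GGG", "T", "TT", "AA"))
  ch2 <- bubble_chains(detect_bubbles(g2), g2)
  expect_equal(ch2[[1]]$length_in_bases, (4 + 2 + 3) + (3 + 2 + 2) - 3)
})

test_that("chain bookkeeping invariants hold on fixture graphs", {
  fx <- make_diploid_graph(seq_length = 700, k = 9, n_snps = 5, seed = 42)
  b <- detect_bubbles(fx$graph)
  ch <- bubble_chains(b, fx$graph)
  top <- sum(vapply(b$bubbles, function(x) is.na(x$parent), logical(1)))
  expect_equal(sum(vapply(ch, `[[`, integer(1), "length_in_bubbles")), top)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$length_in_bubbles, 5)
})

test_that("reports are JSON-serializable, byte-stable and tag nodes by chain", {
  g <- fig_chain_graph()
  b <- detect_bubbles(g)
  ch <- bubble_chains(b, g)
  rep <- detection_report(g, b, ch)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep, f1)
  write_report(detection_report(g, detect_bubbles(g), bubble_chains(b, g)), f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_named(parsed, c("chains", "counts"))
  expect_equal(parsed$counts$simple_bubbles, 2)
  # every node of the graph is in chain 1 here
  expect_true(all(rep$node_chain == 1))
  tags <- chain_tags(rep)
  expect_equal(tags[["x"]], "BC:i:1")
  # nodes outside any chain get BC:i:0
  g0 <- g_from(c("p", "q"), "p R q L 0")
  rep0 <- detection_report(g0, detect_bubbles(g0), bubble_chains(detect_bubbles(g0), g0))
  expect_true(all(rep0$node_chain == 0))
})

test_that("an empty graph yields an all-zero report", {
  g <- bdgraph(data.frame(id = character()))
  rep <- detection_report(g, detect_bubbles(g), bubble_chains(detect_bubbles(g), g))
  expect_true(all(unlist(rep$counts) == 0))
  expect_length(rep$chains, 0)
})
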