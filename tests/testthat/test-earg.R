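test_that("breakpoint routing follows the left parent strictly left of x", {
  fx <- arg_fixtures(fig2_breakpoint = 5)
  e <- fx$fig2
  id <- function(l) node_id(e, l)
  left <- earg_tree_at(e, 2)
  right <- earg_tree_at(e, 7)
  expect_equal(left$parent_of[[as.character(id("d"))]], id("e"))
  expect_equal(right$parent_of[[as.character(id("d"))]], id("f"))
  # a position exactly at the breakpoint routes rightwards ([0,b) vs [b,L))
  at_b <- earg_tree_at(e, 5)
  expect_equal(at_b$parent_of[[as.character(id("d"))]], id("f"))
  expect_error(earg_tree_at(e, 10), "0 <= x < L")
})

test_that("an eARG without recombination has the same tree everywhere", {
  ev <- data.frame(id = 1:5,
                   kind = c("sample", "sample", "sample",
                            "common-ancestor", "common-ancestor"),
                   breakpoint = NA, time = c(0, 0, 0, 1, 2))
  ed <- data.frame(child = c(1, 2, 4, 3), parent = c(4, 4, 5, 5),
                   side = "only")
  e <- earg(10, ev, ed)
  f0 <- earg_tree_at(e, 0)
  for (x in c(2.5, 5, 9.9)) {
    expect_true(argkit:::forest_equal(f0, earg_tree_at(e, x)))
  }
  # conversion of a plain binary tree: every edge annotated [0, L)
  g <- earg_to_garg(e)
  expect_true(all(g$edges$left == 0 & g$edges$right == 10))
  res <- convert_and_resolve(e)
  expect_setequal(res$garg$nodes$id, 1:5)
  expect_true(forests_identical(trees(g, mode = "coalescent-only"),
                                trees(res$garg, mode = "coalescent-only")))
})

test_that("conversion annotates recombination edges with [0,x) and [x,L)", {
  fx <- arg_fixtures()
  e <- fx$fig3
  g <- earg_to_garg(e)
  id <- function(l) node_id(e, l)
  rows <- g$edges[g$edges$child == id("g"), ]
  rows <- rows[order(rows$left), ]
  expect_equal(rows$left, c(0, 5))
  expect_equal(rows$right, c(5, 10))
  expect_equal(rows$parent, c(id("h"), id("j")))
  # node-for-node copy: same ids, times, 17 nodes
  expect_setequal(g$nodes$id, e$events$id)
  expect_equal(nrow(g$nodes), 17L)
  expect_equal(sum(g$nodes$is_sample), 3L)
})

test_that("conversion is injective: distinct eARGs give distinct annotated gARGs", {
  set.seed(23)
  seen_in <- character(0)
  seen_out <- character(0)
  for (rep in 1:20) {
    e <- random_earg(3, L = 10, p_recomb = 0.4)
    key_in <- paste(paste(e$edges$child, e$edges$parent, e$edges$side,
                          collapse = ";"),
                    paste(e$events$kind, e$events$breakpoint, collapse = ";"))
    if (key_in %in% seen_in) next  # identical draws are not a counterexample
    g <- earg_to_garg(e)
    key_out <- paste(g$edges$child, g$edges$parent, g$edges$left,
                     g$edges$right, collapse = ";")
    expect_false(key_out %in% seen_out)
    seen_in <- c(seen_in, key_in)
    seen_out <- c(seen_out, key_out)
  }
})

test_that("event-graph tracing and converted-gARG trees agree at every position", {
  set.seed(24)
  for (rep in 1:30) {
    e <- random_earg(sample(3:5, 1), L = 10, p_recomb = 0.35)
    expect_length(validate_earg(e), 0)
    g <- earg_to_garg(e)
    bps <- sort(unique(c(0, e$events$breakpoint[!is.na(e$events$breakpoint)], e$L)))
    mids <- (bps[-1] + bps[-length(bps)]) / 2
    for (x in mids) {
      expect_true(argkit:::forest_equal(earg_tree_at(e, x), tree_at(g, x)))
    }
    # and the sample-resolved gARG preserves the coalescent-only trees
    res <- convert_and_resolve(e)
    for (x in mids) {
      fa <- argkit:::reduce_forest(earg_tree_at(e, x))
      fb <- argkit:::reduce_forest(tree_at(res$garg, x))
      expect_true(argkit:::forest_equal(fa, fb))
    }
  }
})

test_that("a gene conversion equals two recombinations joined by a zero-length edge", {
  # direct gARG: child 1 inherits the tract [3,6) from donor 6, the rest
  # from 5; both coalesce with sample 2 in 7
  nodes <- data.frame(id = c(1, 2, 5, 6, 7),
                      is_sample = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      time = c(0, 0, 2, 2, 3))
  g_direct <- garg(10, nodes, data.frame(
    child = c(1, 1, 1, 2, 5, 6),
    parent = c(5, 6, 5, 7, 7, 7),
    left = c(0, 3, 6, 0, 0, 0),
    right = c(3, 6, 10, 10, 10, 10)))
  # eARG: recombination at 3 (node 3), then immediately at 6 (node 4);
  # the [3,6) tract routes to 6, both flanks to 5
  ev <- data.frame(
    id = c(1, 2, 3, 4, 5, 6, 7),
    kind = c("sample", "sample", "recombination", "recombination",
             "common-ancestor", "common-ancestor", "common-ancestor"),
    breakpoint = c(NA, NA, 3, 6, NA, NA, NA),
    time = c(0, 0, 1, 1.5, 2, 2, 3))
  ed <- data.frame(
    child = c(1, 3, 3, 4, 4, 2, 5, 6),
    parent = c(3, 5, 4, 6, 5, 7, 7, 7),
    side = c("only", "left", "right", "left", "right", "only", "only", "only"))
  e <- earg(10, ev, ed)
  expect_length(validate_earg(e), 0)
  res <- convert_and_resolve(e, retain_recombinations = FALSE)
  # node 5 receives the two-interval set {[0,3), [6,10)} either way
  am5 <- ancestral_material(res$garg, 5)
  expect_true(argkit:::iset_equal(am5, interval_set(c(0, 6), c(3, 10))))
  expect_true(forests_identical(trees(g_direct, mode = "coalescent-only"),
                                trees(res$garg, mode = "coalescent-only")))
})

test_that("malformed event tables are rejected with named violations", {
  ev <- data.frame(id = 1:3, kind = c("sample", "recombination", "common-ancestor"),
                   breakpoint = c(NA, NA, 4), time = 0:2)
  ed <- data.frame(child = c(1, 2), parent = c(2, 3), side = c("only", "only"))
  v <- validate_earg(earg(10, ev, ed))
  expect_true(any(grepl("lacks a breakpoint", v)))
  expect_true(any(grepl("left and one right", v)))
  expect_true(any(grepl("carries a breakpoint", v)))
})
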