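test_that("the pedigree example yields three local trees at the right breakpoints", {
  fx <- arg_fixtures()
  g <- fx$fig1
  lts <- trees(g)
  expect_length(lts$forests, 3L)
  expect_equal(vapply(lts$forests, `[[`, numeric(1), "left"), c(0, 2, 7))
  expect_equal(vapply(lts$forests, `[[`, numeric(1), "right"), c(2, 7, 10))

  id <- function(l) node_id(g, l)
  f4 <- tree_at(g, 4)
  expect_equal(f4$parent_of[[as.character(id("a"))]], id("f"))
  expect_equal(f4$parent_of[[as.character(id("c"))]], id("f"))
  expect_equal(f4$parent_of[[as.character(id("b"))]], id("g"))
  expect_equal(f4$parent_of[[as.character(id("d"))]], id("h"))
  f0 <- tree_at(g, 0)
  expect_equal(f0$parent_of[[as.character(id("a"))]], id("e"))
  # all samples reach their MRCA in n, in every region
  for (f in lts$forests) {
    roots <- names(f$parent_of)[is.na(f$parent_of)]
    expect_equal(roots, as.character(id("n")))
  }
  expect_error(tree_at(g, 10), "0 <= x < L")
  expect_error(tree_at(g, -1), "0 <= x < L")
})

test_that("a single-edge gARG gives one forest; empty sample regions give roots", {
  g <- garg(10, data.frame(id = 1:2, is_sample = c(TRUE, FALSE), time = 0:1),
            data.frame(child = 1, parent = 2, left = 0, right = 10))
  lts <- trees(g)
  expect_length(lts$forests, 1L)
  expect_equal(lts$forests[[1]]$parent_of[["1"]], 2L)
  expect_true(is.na(lts$forests[[1]]$parent_of[["2"]]))
})

test_that("sequential sweep equals the point-wise oracle on random simulations", {
  set.seed(31)
  n_forests <- integer(0)
  for (rep in 1:25) {
    sim <- simulate_wf(sample(2:5, 1), sample(3:7, 1), L = 10,
                       recomb_rate = stats::runif(1, 0, 2), seed = 1000 + rep)
    g <- sim$garg
    lts <- trees(g)
    for (f in lts$forests) {
      expect_true(argkit:::forest_equal(f, tree_at(g, (f$left + f$right) / 2)))
    }
    # forest count bounded by interior edge endpoints + 1
    interior <- unique(c(g$edges$left, g$edges$right))
    interior <- interior[interior > 0 & interior < g$L]
    expect_lte(length(lts$forests), length(interior) + 1L)
    n_forests <- c(n_forests, length(lts$forests))
  }
  expect_gt(max(n_forests), 1L)  # the draws actually exercised recombination
})

test_that("coalescent-only forests have no unary internal nodes", {
  set.seed(5)
  for (rep in 1:8) {
    sim <- simulate_wf(3, 6, L = 10, recomb_rate = 1, seed = 500 + rep)
    lts <- trees(sim$garg, mode = "coalescent-only")
    for (f in lts$forests) {
      internal <- setdiff(as.integer(names(f$parent_of)), f$samples)
      kids <- table(f$parent_of[!is.na(f$parent_of)])
      for (u in internal) {
        expect_gte(kids[[as.character(u)]], 2L)
      }
    }
  }
})

test_that("pairwise MRCA per region matches the worked example and is symmetric", {
  fx <- arg_fixtures()
  g <- fx$fig1
  id <- function(l) node_id(g, l)
  lts <- trees(g)
  m_ac <- pairwise_mrca(lts, id("a"), id("c"))
  expect_equal(m_ac$mrca[m_ac$left == 2 & m_ac$right == 7], id("f"))
  m_ca <- pairwise_mrca(lts, id("c"), id("a"))
  expect_equal(m_ac$mrca, m_ca$mrca)
  # (u, u) coalesces in u itself on every interval
  m_uu <- pairwise_mrca(lts, id("b"), id("b"))
  expect_true(all(m_uu$mrca == id("b")))
  expect_error(pairwise_mrca(lts, 999L, id("a")), "not present")
})

test_that("pairwise MRCA equals brute-force path intersection on simulations", {
  set.seed(77)
  for (rep in 1:5) {
    sim <- simulate_wf(3, 6, L = 10, recomb_rate = 1, seed = 700 + rep)
    g <- sim$garg
    lts <- trees(g)
    pair <- sample(g$samples, 2)
    m <- pairwise_mrca(lts, pair[1], pair[2])
    for (i in seq_len(nrow(m))) {
      f <- tree_at(g, (m$left[i] + m$right[i]) / 2)
      expect_equal(m$mrca[i], forest_mrca(f, pair[1], pair[2]))
    }
  }
})

test_that("Newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  fx <- arg_fixtures()
  lts <- trees(fx$fig1, mode = "coalescent-only")
  lines <- export_newick(lts)
  expect_length(lines, 3L)
  for (i in seq_along(lines)) {
    nwk <- strsplit(lines[i], "\t")[[1]][3]
    tr <- ape::read.tree(text = nwk)
    expect_s3_class(tr, "phylo")
    expect_setequal(tr$tip.label, as.character(fx$fig1$samples))
    # the [2,7) tree pairs a with c
    if (i == 2) {
      a <- as.character(node_id(fx$fig1, "a"))
      c_ <- as.character(node_id(fx$fig1, "c"))
      dm <- ape::cophenetic.phylo(tr)
      expect_lt(dm[a, c_], max(dm))
    }
  }
  # single-edge graph: degenerate one-line export
  g <- garg(10, data.frame(id = 1:2, is_sample = c(TRUE, FALSE), time = 0:1),
            data.frame(child = 1, parent = 2, left = 0, right = 10))
  l1 <- export_newick(trees(g))
  expect_length(l1, 1L)
  expect_match(l1, "\\(1:1\\)2;")
})
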