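levels_all <- c("resolve-only", "prune-singly-connected",
                "prune-unary-everywhere", "full")

test_that("resolving the converted event ARG drops the grand MRCA and the non-ancestral breakpoint edge", {
  fx <- arg_fixtures()
  e <- fx$fig3
  res <- convert_and_resolve(e)
  g <- res$garg
  id <- function(l) node_id(e, l)
  # grand MRCA q is gone: the genome fully coalesces in k and p first
  expect_false(id("q") %in% g$nodes$id)
  expect_false(id("j") %in% g$nodes$id)
  # the recombination at position 5 (node g) fell in non-ancestral material:
  # its right-hand edge toward j is removed
  rem <- res$report$removed_edges
  expect_true(any(rem$child == id("g") & rem$parent == id("j")))
  # g itself survives, carrying only left-of-breakpoint material
  expect_true(id("g") %in% g$nodes$id)
  expect_true(argkit:::iset_equal(ancestral_material(g, id("g")),
                                  interval_set(0, 2)))
  # full coalescence happens in k over [0,3) and p over [3,10)
  anc <- argkit:::ancestry_tables(g, g$samples)
  expect_true(argkit:::iset_equal(anc[[as.character(id("k"))]]$all,
                                  interval_set(0, 3)))
  expect_true(argkit:::iset_equal(anc[[as.character(id("p"))]]$all,
                                  interval_set(3, 10)))
})

test_that("simplification is idempotent at every level", {
  fx <- arg_fixtures()
  inputs <- list(fx$fig1, fx$fig5, earg_to_garg(fx$fig3))
  for (g in inputs) {
    for (lev in levels_all) {
      r1 <- simplify_garg(g, level = lev)$garg
      r2 <- simplify_garg(r1, level = lev)$garg
      expect_identical(r1$nodes, r2$nodes)
      expect_identical(r1$edges, r2$edges)
    }
  }
})

test_that("resolved edges carry no non-ancestral material, at any level", {
  set.seed(13)
  for (rep in 1:6) {
    sim <- simulate_wf(3, 5, L = 10, recomb_rate = 1, seed = 130 + rep)
    for (lev in levels_all) {
      out <- simplify_garg(sim$garg, level = lev)$garg
      anc <- argkit:::ancestry_tables(out, out$samples)
      for (i in seq_len(nrow(out$edges))) {
        extra <- interval_subtract(
          interval_set(out$edges$left[i], out$edges$right[i]),
          anc[[as.character(out$edges$child[i])]]$path)
        expect_equal(nrow(extra), 0L)
      }
    }
  }
})

test_that("samples always survive with full ancestral material; counts shrink with level", {
  set.seed(14)
  for (rep in 1:5) {
    sim <- simulate_wf(3, 5, L = 10, recomb_rate = 1, seed = 140 + rep)
    n_nodes <- integer(0); n_pairs <- integer(0)
    for (lev in levels_all) {
      out <- simplify_garg(sim$garg, level = lev)$garg
      expect_true(all(sim$garg$samples %in% out$nodes$id))
      for (s in out$samples) {
        expect_true(argkit:::iset_equal(ancestral_material(out, s),
                                        interval_set(0, out$L)))
      }
      n_nodes <- c(n_nodes, nrow(out$nodes))
      n_pairs <- c(n_pairs, nrow(unique(out$edges[, c("child", "parent")])))
    }
    expect_true(all(diff(n_nodes) <= 0))
    # edge counts shrink through the pruning levels; the final per-locus
    # bypass can split a child's attachment across ancestors, so it is
    # excluded (the locally-unary form is the more edge-compact encoding)
    expect_true(all(diff(n_pairs[1:3]) <= 0))
  }
})

test_that("simplification never changes the restricted local trees", {
  set.seed(15)
  for (rep in 1:10) {
    sim <- simulate_wf(sample(2:4, 1), sample(4:6, 1), L = 10,
                       recomb_rate = stats::runif(1, 0.3, 1.5),
                       seed = 150 + rep)
    ref <- trees(sim$garg, mode = "coalescent-only")
    for (lev in levels_all) {
      out <- simplify_garg(sim$garg, level = lev)$garg
      expect_true(forests_identical(ref, trees(out, mode = "coalescent-only")))
    }
  }
})

test_that("the four precision levels prune the simulated-ARG example as depicted", {
  fx <- arg_fixtures()
  g <- fx$fig5
  id <- function(l) node_id(g, l)
  removed_at <- function(lev) {
    nm <- simplify_garg(g, level = lev)$report$node_map
    as.integer(names(nm)[is.na(nm)])
  }
  r_a <- removed_at("resolve-only")
  # only the node above the MRCA disappears at resolution
  expect_setequal(r_a, id("q"))
  r_b <- removed_at("prune-singly-connected")
  # the diamond j-l/m-n collapses: the parallel pass-through pair l, m goes
  expect_true(all(id(c("l", "m")) %in% r_b))
  expect_false(any(id(c("n", "r", "j")) %in% r_b))
  r_c <- removed_at("prune-unary-everywhere")
  # nodes that never host a coalescence go at level C, in particular n and r
  expect_true(all(id(c("n", "r")) %in% r_c))
  # h and i are locally unary but coalescent elsewhere: they stay
  expect_false(any(id(c("h", "i")) %in% r_c))
  # level D: every surviving node-interval pair has >= 2 children
  out_d <- simplify_garg(g, level = "full")$garg
  for (f in trees(out_d, mode = "as-stored")$forests) {
    internal <- setdiff(as.integer(names(f$parent_of)), f$samples)
    kids <- table(f$parent_of[!is.na(f$parent_of)])
    for (u in internal) expect_gte(kids[[as.character(u)]], 2L)
  }
})

test_that("coalescence spans match the pedigree example and the tree oracle", {
  fx <- arg_fixtures()
  g <- fx$fig1
  sp <- coalescence_spans(g)
  f_id <- as.character(node_id(g, "f"))
  # a ([2,10)) and c ([0,7)) meet in f over [2,7)
  expect_true(argkit:::iset_equal(sp[[f_id]]$coalescent, interval_set(2, 7)))
  expect_true(argkit:::iset_equal(sp[[f_id]]$ancestral, interval_set(0, 10)))
  expect_equal(sp[[f_id]]$fraction, 0.5)
  # sample leaves have no children, hence empty coalescent span
  for (s in g$samples) {
    expect_equal(nrow(sp[[as.character(s)]]$coalescent), 0L)
    expect_equal(sp[[as.character(s)]]$fraction, 0)
  }
  # oracle: coalescent loci are exactly those where the node has >= 2
  # children in the local tree
  set.seed(16)
  sim <- simulate_wf(3, 5, L = 10, recomb_rate = 1, seed = 160)
  gs <- sim$garg
  sps <- coalescence_spans(gs)
  lts <- trees(gs)
  for (f in lts$forests) {
    mid <- (f$left + f$right) / 2
    kids <- table(f$parent_of[!is.na(f$parent_of)])
    for (u in names(sps)) {
      in_span <- interval_contains(sps[[u]]$coalescent, mid)
      n_kids <- if (u %in% names(kids)) kids[[u]] else 0L
      expect_equal(in_span, n_kids >= 2L)
    }
  }
})

test_that("retained nodes survive and densified ids are contiguous in time order", {
  fx <- arg_fixtures()
  e <- fx$fig3
  g <- earg_to_garg(e)
  rec <- e$events$id[e$events$kind == "recombination"]
  res <- simplify_garg(g, level = "full", retain_nodes = rec,
                       densify_ids = TRUE)
  out <- res$garg
  # retained recombination nodes survive even under full simplification
  kept_old <- as.integer(names(res$report$node_map)[!is.na(res$report$node_map)])
  expect_true(all(rec %in% kept_old))
  expect_setequal(out$nodes$id, seq_len(nrow(out$nodes)) - 1L)
  expect_true(all(diff(out$nodes$time[order(out$nodes$id)]) >= 0))
  expect_error(simplify_garg(g, samples = integer(0)), "nonempty")
  expect_error(simplify_garg(g, samples = 999L), "unknown sample")
})
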