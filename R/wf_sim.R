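#' Prospective Wright-Fisher gARG recorder
#'
#' Forward-time simulation of a closed diploid Wright-Fisher population that
#' records the full gARG exhaustively, generation by generation, embedded in
#' the pedigree it generates. Each non-founder genome picks a parent
#' individual uniformly at random from the previous generation (independent
#' draws per genome; selfing is possible), the number of crossovers in the
#' meiosis is Poisson with mean `recomb_rate`, crossover positions are
#' uniform on `(0, L)`, and the inherited genome alternates between the
#' parent's two genomes starting from a fair-coin phase. Edges record
#' exactly the inherited intervals, so every non-founder's edges tile
#' `[0, L)`.
#'
#' The random-number stream is consumed in a fixed, documented order per
#' generation (parent choices, crossover counts, crossover positions, then
#' phases, genomes enumerated individual-major), so a seed reproduces node
#' and edge tables exactly. Periodic simplification (every
#' `simplify_interval` generations, with respect to the current generation)
#' removes ancestry that can no longer be reached from the population,
#' without affecting the random stream or the final genealogy of the
#' samples.
#'
#' @param n_diploids Diploid individuals per generation (constant).
#' @param n_generations Number of generations simulated after the founders.
#' @param L Genome length.
#' @param recomb_rate Expected crossovers per genome per meiosis.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param simplify_interval Generations between periodic full
#'   simplifications; 0 (default) records everything.
#' @return A list with `garg` (final-generation genomes flagged as samples;
#'   node time is generations before present, so founders are oldest) and
#'   `pedigree`, a data frame with one row per individual: `generation`
#'   (0 = founders), `individual`, `genome1`, `genome2` (node ids) and
#'   `parent1`, `parent2` (parent individual index in the previous
#'   generation for each genome; `NA` for founders).
#' @examples
#' sim <- simulate_wf(4, 5, L = 10, recomb_rate = 1, seed = 1)
#' sim$garg
#' @export
simulate_wf <- function(n_diploids, n_generations, L = 100, recomb_rate = 1.0,
                        seed = NULL, simplify_interval = 0) {
  stopifnot(n_diploids >= 1, n_generations >= 1, L > 0, recomb_rate >= 0,
            simplify_interval >= 0)
  n_diploids <- as.integer(n_diploids)
  n_generations <- as.integer(n_generations)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_gen_genomes <- 2L * n_diploids
  node_id_v <- seq_len(n_gen_genomes)           # founders
  node_time <- rep(as.numeric(n_generations), n_gen_genomes)
  next_id <- n_gen_genomes + 1L

  e_child <- list(); e_parent <- list(); e_left <- list(); e_right <- list()
  n_chunks <- 0L
  removed_nodes <- integer(0)

  ped <- data.frame(
    generation = 0L, individual = seq_len(n_diploids),
    genome1 = seq(1L, n_gen_genomes, by = 2L),
    genome2 = seq(2L, n_gen_genomes, by = 2L),
    parent1 = NA_integer_, parent2 = NA_integer_
  )

  cur_genomes <- matrix(seq_len(n_gen_genomes), nrow = 2L)  # [genome, individual]

  build_garg <- function(sample_ids) {
    nid <- node_id_v
    keep <- !(nid %in% removed_nodes)
    garg(L,
         data.frame(id = nid[keep], is_sample = nid[keep] %in% sample_ids,
                    time = node_time[keep]),
         data.frame(child = unlist(e_child), parent = unlist(e_parent),
                    left = unlist(e_left), right = unlist(e_right)),
         samples = sample_ids)
  }

  ped_chunks <- list(ped)

  for (t in seq_len(n_generations)) {
    # RNG draw order per generation (genomes enumerated individual-major,
    # genome 1 then genome 2 within an individual): parent choices,
    # crossover counts, crossover positions (grouped per genome, in genome
    # order), phases
    par_ind <- sample.int(n_diploids, n_gen_genomes, replace = TRUE)
    ks <- stats::rpois(n_gen_genomes, recomb_rate)
    pos_all <- stats::runif(sum(ks), 0, L)
    phases <- sample.int(2L, n_gen_genomes, replace = TRUE)

    child_ids <- next_id:(next_id + n_gen_genomes - 1L)
    next_id <- next_id + n_gen_genomes
    node_id_v <- c(node_id_v, child_ids)
    node_time <- c(node_time, rep(as.numeric(n_generations - t), n_gen_genomes))

    pos_group <- rep.int(seq_len(n_gen_genomes), ks)
    ord <- order(pos_group, pos_all)
    pos_sorted <- pos_all[ord]
    nseg <- ks + 1L
    seg_genome <- rep.int(seq_len(n_gen_genomes), nseg)
    # per genome: bounds are (0, sorted positions, L)
    n_rows <- sum(nseg)
    lefts <- numeric(n_rows)
    rights <- numeric(n_rows)
    first_of_genome <- cumsum(c(1L, nseg))[seq_len(n_gen_genomes)]
    last_of_genome <- cumsum(nseg)
    lefts[first_of_genome] <- 0
    if (length(pos_sorted) > 0) {
      lefts[setdiff(seq_len(n_rows), first_of_genome)] <- pos_sorted
      rights[setdiff(seq_len(n_rows), last_of_genome)] <- pos_sorted
    }
    rights[last_of_genome] <- L
    seg_rank <- sequence(nseg)
    which_side <- ((phases[seg_genome] - 1L + seg_rank - 1L) %% 2L) + 1L
    parent_genome <- cur_genomes[cbind(which_side, par_ind[seg_genome])]

    keep <- lefts < rights  # guard against coincident crossover positions
    n_chunks <- n_chunks + 1L
    e_child[[n_chunks]] <- child_ids[seg_genome[keep]]
    e_parent[[n_chunks]] <- parent_genome[keep]
    e_left[[n_chunks]] <- lefts[keep]
    e_right[[n_chunks]] <- rights[keep]

    new_genomes <- matrix(child_ids, nrow = 2L)
    gen_parent <- matrix(par_ind, nrow = 2L)
    ped_chunks[[t + 1L]] <- data.frame(
      generation = t, individual = seq_len(n_diploids),
      genome1 = new_genomes[1L, ], genome2 = new_genomes[2L, ],
      parent1 = gen_parent[1L, ], parent2 = gen_parent[2L, ]
    )
    cur_genomes <- new_genomes

    if (simplify_interval > 0 && t %% simplify_interval == 0L && t < n_generations) {
      g <- build_garg(sort(as.integer(cur_genomes)))
      res <- simplify_garg(g, samples = sort(as.integer(cur_genomes)),
                           level = "full")
      kept <- res$garg$nodes$id
      removed_nodes <- setdiff(node_id_v, kept)
      ed <- res$garg$edges
      e_child <- list(ed$child); e_parent <- list(ed$parent)
      e_left <- list(ed$left); e_right <- list(ed$right)
      n_chunks <- 1L
    }
  }

  samples <- sort(as.integer(cur_genomes))
  list(garg = build_garg(samples), pedigree = do.call(rbind, ped_chunks))
}

#' Equivalence of periodic and final-only simplification
#'
#' Runs the Wright-Fisher recorder twice with the same seed, once recording
#' everything (`simplify_interval = 0`) and once simplifying every `k`
#' generations, fully simplifies both final gARGs with respect to the
#' sampled generation, and compares their local tree sequences.
#'
#' @param n_diploids,n_generations,L,recomb_rate,seed As in [simulate_wf()].
#' @param k Simplification interval for the periodic run (`> 0`).
#' @return `"PASS"` if the two fully simplified gARGs have identical local
#'   tree sequences (same intervals, same parent maps), else `"FAIL"`.
#' @export
periodic_simplify_equivalence <- function(n_diploids, n_generations, L = 100,
                                          recomb_rate = 1.0, seed = 1, k = 1) {
  stopifnot(k > 0)
  a <- simulate_wf(n_diploids, n_generations, L, recomb_rate, seed,
                   simplify_interval = 0)
  b <- simulate_wf(n_diploids, n_generations, L, recomb_rate, seed,
                   simplify_interval = k)
  fa <- simplify_garg(a$garg, level = "full")$garg
  fb <- simplify_garg(b$garg, level = "full")$garg
  ta <- trees(fa, mode = "coalescent-only")
  tb <- trees(fb, mode = "coalescent-only")
  same <- length(ta$forests) == length(tb$forests) &&
    all(vapply(seq_along(ta$forests), function(i) {
      x <- ta$forests[[i]]; y <- tb$forests[[i]]
      isTRUE(all.equal(c(x$left, x$right), c(y$left, y$right))) &&
        forest_equal(x, y)
    }, logical(1)))
  if (same) "PASS" else "FAIL"
}
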