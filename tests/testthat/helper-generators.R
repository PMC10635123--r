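# Generators and independent oracles shared across test files.

# Loci covered by an interval set, evaluated on the midpoints of the unit
# grid cells of [0, L): the brute-force membership oracle for the interval
# algebra.
grid_membership <- function(iset, L = 100) {
  pts <- seq_len(L) - 0.5
  vapply(pts, function(p) interval_contains(iset, p), logical(1))
}

# Random canonical interval set on the integer grid [0, L).
random_iset <- function(L = 100, max_intervals = 4) {
  k <- sample.int(max_intervals + 1L, 1L) - 1L
  if (k == 0) return(interval_set())
  out <- interval_set()
  for (i in seq_len(k)) {
    l <- sample.int(L, 1L) - 1L
    r <- l + sample.int(L - l, 1L)
    out <- interval_union(out, interval_set(l, r))
  }
  out
}

# Random valid eARG built pastwards: lineage "slots" are (node, side) pairs
# awaiting a parent; common-ancestor events merge two slots, recombination
# events split one slot in two. Terminates with a single root.
random_earg <- function(n_samples = 4, L = 10, p_recomb = 0.3, max_recomb = 6) {
  ids <- seq_len(n_samples)
  ev <- data.frame(id = ids, kind = "sample", breakpoint = NA_real_,
                   time = 0, metadata = letters[ids])
  edges <- data.frame(child = integer(0), parent = integer(0),
                      side = character(0))
  slots <- data.frame(node = ids, side = "only")
  next_id <- n_samples + 1L
  t <- 0
  n_rec <- 0L
  while (nrow(slots) > 1L) {
    t <- t + 1
    if (n_rec < max_recomb && stats::runif(1) < p_recomb) {
      i <- sample.int(nrow(slots), 1L)
      r <- next_id; next_id <- next_id + 1L
      ev <- rbind(ev, data.frame(id = r, kind = "recombination",
                                 breakpoint = stats::runif(1, 0, L), time = t,
                                 metadata = ""))
      edges <- rbind(edges, data.frame(child = slots$node[i], parent = r,
                                       side = slots$side[i]))
      slots <- rbind(slots[-i, ], data.frame(node = c(r, r),
                                             side = c("left", "right")))
      n_rec <- n_rec + 1L
    } else {
      ij <- sample.int(nrow(slots), 2L)
      w <- next_id; next_id <- next_id + 1L
      ev <- rbind(ev, data.frame(id = w, kind = "common-ancestor",
                                 breakpoint = NA_real_, time = t,
                                 metadata = ""))
      edges <- rbind(edges, data.frame(child = slots$node[ij],
                                       parent = w, side = slots$side[ij]))
      slots <- rbind(slots[-ij, ], data.frame(node = w, side = "only"))
    }
  }
  earg(L, ev, edges)
}

# Midpoints of the elementary intervals of a local tree sequence.
forest_midpoints <- function(lts) {
  vapply(lts$forests, function(f) (f$left + f$right) / 2, numeric(1))
}

# Root-ward path of a node in a forest.
rootward_path <- function(f, u) {
  path <- as.integer(u)
  p <- f$parent_of[[as.character(u)]]
  while (!is.na(p)) {
    path <- c(path, p)
    p <- f$parent_of[[as.character(p)]]
  }
  path
}

# First common node on the two root-ward paths from u and v; NA if disjoint.
forest_mrca <- function(f, u, v) {
  up <- rootward_path(f, u)
  p <- as.integer(v)
  repeat {
    if (p %in% up) return(p)
    p <- f$parent_of[[as.character(p)]]
    if (is.na(p)) return(NA_integer_)
  }
}

forests_identical <- function(a, b) {
  length(a$forests) == length(b$forests) &&
    all(vapply(seq_along(a$forests), function(i) {
      x <- a$forests[[i]]; y <- b$forests[[i]]
      isTRUE(all.equal(c(x$left, x$right), c(y$left, y$right))) &&
        argkit:::forest_equal(x, y)
    }, logical(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
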