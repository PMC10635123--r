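#' Local genealogical forest at one genome position
#'
#' Point-wise recovery of the genealogy at position `x`: starting from the
#' samples, every edge whose inheritance intervals contain `x` is followed
#' pastwards, and the reached nodes form the forest. This is a deliberately
#' direct implementation, independent of the sequential sweep in [trees()],
#' so the two can cross-check each other.
#'
#' Nodes carrying no ancestral material at `x` are excluded. Regions where
#' the sample lineages have not fully coalesced yield a forest with several
#' roots rather than a single tree.
#'
#' @param g A `garg`.
#' @param x A genome position with `0 <= x < L`.
#' @param samples Sample node ids; defaults to `g$samples`.
#' @return A `local_forest`: interval (degenerate, `[x, x]`), a `parent_of`
#'   map (named by node id; `NA` marks roots) and the sample set.
#' @export
tree_at <- function(g, x, samples = g$samples) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x >= g$L) {
    stop("position x must satisfy 0 <= x < L")
  }
  samples <- as.integer(samples)
  unknown <- setdiff(samples, g$nodes$id)
  if (length(unknown) > 0) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  ed <- g$edges
  at_x <- ed[ed$left <= x & x < ed$right, , drop = FALSE]
  parent_at_x <- function(node) {
    p <- unique(at_x$parent[at_x$child == node])
    if (length(p) > 1) {
      stop("node ", node, " has multiple parents at position ", x,
           " (overlapping parental inheritance)")
    }
    if (length(p) == 0) NA_integer_ else as.integer(p)
  }
  parent_of <- integer(0)
  queue <- samples
  seen <- integer(0)
  while (length(queue) > 0) {
    u <- queue[1L]
    queue <- queue[-1L]
    if (u %in% seen) next
    seen <- c(seen, u)
    p <- parent_at_x(u)
    parent_of[[as.character(u)]] <- p
    if (!is.na(p) && !(p %in% seen)) queue <- c(queue, p)
  }
  new_local_forest(x, x, parent_of, samples)
}

new_local_forest <- function(left, right, parent_of, samples) {
  parent_of <- parent_of[order(as.integer(names(parent_of)))]
  structure(list(left = left, right = right, parent_of = parent_of,
                 samples = sort(as.integer(samples))),
            class = "local_forest")
}

#' @export
print.local_forest <- function(x, ...) {
  roots <- names(x$parent_of)[is.na(x$parent_of)]
  cat(sprintf("local forest on [%s, %s): %d nodes, %d root(s): %s\n",
              format(x$left), format(x$right), length(x$parent_of),
              length(roots), paste(roots, collapse = ", ")))
  invisible(x)
}

forest_equal <- function(a, b) {
  identical(names(a$parent_of), names(b$parent_of)) &&
    isTRUE(all(a$parent_of == b$parent_of | (is.na(a$parent_of) & is.na(b$parent_of))))
}

# Bypass nodes that are unary within this forest: keep samples, nodes with
# >= 2 children, and anything in keep_extra; reattach kept children to their
# nearest kept ancestor.
reduce_forest <- function(f, keep_extra = integer(0)) {
  po <- f$parent_of
  ids <- as.integer(names(po))
  nkids <- table(factor(po[!is.na(po)], levels = ids))
  keep <- ids[ids %in% f$samples | as.integer(nkids) >= 2L | ids %in% keep_extra]
  new_po <- integer(0)
  for (u in keep) {
    p <- po[[as.character(u)]]
    while (!is.na(p) && !(p %in% keep)) {
      p <- po[[as.character(p)]]
    }
    new_po[[as.character(u)]] <- p
  }
  new_local_forest(f$left, f$right, new_po, f$samples)
}

#' Sequence of local trees along the genome
#'
#' Recovers the ordered sequence of local forests that partition `[0, L)`,
#' by a left-to-right sweep over the sorted edge endpoints: at each
#' breakpoint the edges ending there are removed and the edges starting
#' there inserted (removals first, so the one-parent-per-locus invariant
#' holds mid-sweep). Edges are first clipped to the ancestral material of
#' their child node, so non-ancestral lineages never appear. Adjacent
#' identical forests are merged into one maximal interval.
#'
#' @param g A valid `garg`.
#' @param samples Sample node ids; defaults to `g$samples`.
#' @param mode `"as-stored"` keeps every node on an inheritance path
#'   (including locally-unary nodes); `"coalescent-only"` bypasses nodes
#'   with a single child in each forest, the conventional tree depiction.
#' @return A `local_tree_seq`: genome length `L` and an ordered list of
#'   `local_forest` objects tiling `[0, L)`.
#' @examples
#' fx <- arg_fixtures()
#' lts <- trees(fx$fig1)
#' length(lts$forests)  # 3 trees: [0,2), [2,7), [7,10)
#' @export
trees <- function(g, samples = g$samples, mode = c("as-stored", "coalescent-only")) {
  mode <- match.arg(mode)
  viol <- validate_garg(g)
  if (length(viol) > 0) {
    stop("invalid gARG: ", paste(viol, collapse = "; "))
  }
  samples <- as.integer(samples)
  anc <- ancestry_tables(g, samples)

  # clip each edge row to the child's ancestral material
  ed <- g$edges
  cl_child <- integer(0); cl_parent <- integer(0)
  cl_left <- numeric(0); cl_right <- numeric(0)
  if (nrow(ed) > 0) {
    for (i in seq_len(nrow(ed))) {
      clip <- interval_intersect(interval_set(ed$left[i], ed$right[i]),
                                 anc[[as.character(ed$child[i])]]$path)
      if (nrow(clip) > 0) {
        cl_child <- c(cl_child, rep(ed$child[i], nrow(clip)))
        cl_parent <- c(cl_parent, rep(ed$parent[i], nrow(clip)))
        cl_left <- c(cl_left, clip[, 1L])
        cl_right <- c(cl_right, clip[, 2L])
      }
    }
  }

  pts <- sort(unique(c(0, g$L, cl_left, cl_right)))
  active <- rep(FALSE, length(cl_child))
  forests <- list()
  for (k in seq_len(length(pts) - 1L)) {
    pos <- pts[k]
    active[active & cl_right <= pos] <- FALSE   # removals first
    active[cl_left == pos] <- TRUE              # then insertions
    po <- integer(0)
    ch <- cl_child[active]
    pa <- cl_parent[active]
    if (anyDuplicated(ch)) {
      stop("overlapping parental inheritance during sweep at position ", pos)
    }
    present <- unique(c(ch, pa, samples))
    for (u in present) {
      m <- match(u, ch)
      po[[as.character(u)]] <- if (is.na(m)) NA_integer_ else as.integer(pa[m])
    }
    f <- new_local_forest(pos, pts[k + 1L], po, samples)
    if (mode == "coalescent-only") f <- reduce_forest(f)
    n <- length(forests)
    if (n > 0 && forest_equal(forests[[n]], f)) {
      forests[[n]]$right <- f$right
    } else {
      forests[[n + 1L]] <- f
    }
  }
  structure(list(L = g$L, forests = forests,
                 node_times = stats::setNames(g$nodes$time, g$nodes$id)),
            class = "local_tree_seq")
}

#' @export
print.local_tree_seq <- function(x, ...) {
  cat(sprintf("local tree sequence: %d forest(s) over [0, %s)\n",
              length(x$forests), format(x$L)))
  for (f in x$forests) {
    roots <- names(f$parent_of)[is.na(f$parent_of)]
    cat(sprintf("  [%s, %s): %d nodes, root(s) %s\n", format(f$left),
                format(f$right), length(f$parent_of),
                paste(roots, collapse = ", ")))
  }
  invisible(x)
}

#' Most recent common ancestor of a sample pair, per local tree
#'
#' For each forest of a local tree sequence, walks rootwards from both
#' samples and reports the first node the two paths share; `NA` where the
#' paths are disjoint (the pair has not coalesced in that region).
#'
#' @param lts A `local_tree_seq` from [trees()].
#' @param u,v Sample node ids.
#' @return A data frame with columns `left`, `right`, `mrca` (integer, `NA`
#'   for uncoalesced regions), one row per forest.
#' @export
pairwise_mrca <- function(lts, u, v) {
  u <- as.integer(u)
  v <- as.integer(v)
  rows <- lapply(lts$forests, function(f) {
    po <- f$parent_of
    if (!(as.character(u) %in% names(po)) || !(as.character(v) %in% names(po))) {
      stop("node ", if (!(as.character(u) %in% names(po))) u else v,
           " not present in forest [", f$left, ", ", f$right, ")")
    }
    upath <- u
    p <- u
    repeat {
      p <- po[[as.character(p)]]
      if (is.na(p)) break
      upath <- c(upath, p)
    }
    m <- NA_integer_
    p <- v
    repeat {
      if (p %in% upath) { m <- p; break }
      p <- po[[as.character(p)]]
      if (is.na(p)) break
    }
    data.frame(left = f$left, right = f$right, mrca = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

forest_children <- function(po) {
  ids <- names(po)
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (u in ids) {
    p <- po[[u]]
    if (!is.na(p)) kids[[as.character(p)]] <- c(kids[[as.character(p)]], u)
  }
  kids
}

forest_newick <- function(f, times = NULL) {
  po <- f$parent_of
  kids <- forest_children(po)
  with_lengths <- !is.null(times) && all(!is.na(times[names(po)]))
  emit <- function(u) {
    ks <- kids[[u]]
    lab <- u
    body <- if (length(ks) == 0) lab else {
      paste0("(", paste(vapply(ks, emit, character(1)), collapse = ","), ")", lab)
    }
    p <- po[[u]]
    if (with_lengths && !is.na(p)) {
      body <- paste0(body, ":", format_pos(times[[u]] - times[[as.character(p)]]))
    }
    body
  }
  roots <- names(po)[is.na(po)]
  paste0(vapply(roots, function(r) paste0(emit(r), ";"), character(1)),
         collapse = "")
}

#' Export a local tree sequence as Newick strings
#'
#' Writes one line per forest: `left<TAB>right<TAB>newick`. Node ids are the
#' Newick labels; branch lengths are parent-child time differences when all
#' node times are known, and omitted otherwise. Multi-root forests emit one
#' Newick string per root, semicolon-separated on the same line. Times are
#' measured pastwards, so branch lengths are child-time minus parent-time
#' negated, i.e. nonnegative for a valid graph.
#'
#' @param lts A `local_tree_seq`.
#' @param path File to write; `NULL` returns the lines without writing.
#' @return The lines, invisibly.
#' @export
export_newick <- function(lts, path = NULL) {
  times <- lts$node_times
  if (!is.null(times)) {
    # branch length = (parent time - child time): flip sign inside writer
    times <- -times
  }
  lines <- vapply(lts$forests, function(f) {
    paste(format_pos(f$left), format_pos(f$right),
          forest_newick(f, times), sep = "\t")
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
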