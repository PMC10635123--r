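#' Construct a genome ARG (gARG)
#'
#' A gARG is a directed acyclic graph whose nodes are haploid genomes and
#' whose edges record genetic inheritance between a child genome and a parent
#' genome, annotated with the set of disjoint half-open genomic intervals over
#' which the inheritance occurred. Edges are stored in tabular form, one row
#' per interval (`child`, `parent`, `left`, `right`), in the style of the
#' succinct tree sequence encoding; rows belonging to one (child, parent)
#' pair together form that edge's interval set and are canonicalized on
#' construction (sorted, abutting intervals merged).
#'
#' @param L Genome length; all intervals live on `[0, L)`.
#' @param nodes A data frame with columns `id` (unique integers), `is_sample`
#'   (logical), `time` (numeric, `NA` allowed, measured pastwards so parents
#'   are older than children) and optionally `metadata` (character labels).
#' @param edges A data frame with columns `child`, `parent`, `left`, `right`;
#'   one row per inherited interval. May be empty.
#' @param samples Integer vector of sampled node ids; defaults to the nodes
#'   flagged with `is_sample`.
#' @return An object of class `garg`.
#' @seealso [validate_garg()], [ancestral_material()], [trees()],
#'   [simplify_garg()]
#' @examples
#' g <- garg(
#'   L = 10,
#'   nodes = data.frame(id = 1:3, is_sample = c(TRUE, TRUE, FALSE),
#'                      time = c(0, 0, 1)),
#'   edges = data.frame(child = c(1, 2), parent = c(3, 3),
#'                      left = c(0, 0), right = c(10, 10))
#' )
#' validate_garg(g)
#' @export
garg <- function(L, nodes, edges = NULL, samples = NULL) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("L must be a single positive number")
  }
  nodes <- as.data.frame(nodes)
  if (!all(c("id", "is_sample") %in% names(nodes))) {
    stop("nodes must have columns id and is_sample")
  }
  if (is.null(nodes$time)) nodes$time <- NA_real_
  if (is.null(nodes$metadata)) nodes$metadata <- ""
  nodes$id <- as.integer(nodes$id)
  nodes$is_sample <- as.logical(nodes$is_sample)
  nodes$time <- as.numeric(nodes$time)
  nodes$metadata <- as.character(nodes$metadata)
  nodes <- nodes[order(nodes$id), c("id", "is_sample", "time", "metadata")]
  rownames(nodes) <- NULL

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(child = integer(0), parent = integer(0),
                        left = numeric(0), right = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("child", "parent", "left", "right") %in% names(edges))) {
      stop("edges must have columns child, parent, left, right")
    }
    edges <- edges[, c("child", "parent", "left", "right")]
    edges$child <- as.integer(edges$child)
    edges$parent <- as.integer(edges$parent)
    edges$left <- as.numeric(edges$left)
    edges$right <- as.numeric(edges$right)
    if (any(edges$left >= edges$right)) {
      stop("edge rows must satisfy left < right")
    }
    edges <- canonicalize_edges(edges)
  }

  if (is.null(samples)) {
    samples <- nodes$id[nodes$is_sample]
  }
  samples <- sort(unique(as.integer(samples)))

  structure(list(L = as.numeric(L), nodes = nodes, edges = edges,
                 samples = samples),
            class = "garg")
}

# Merge overlapping and abutting interval rows per (child, parent) pair and
# sort rows by (child, parent, left): a unique, byte-stable representation.
# Vectorized (no per-pair allocation) since the simulator funnels large raw
# recordings through here.
canonicalize_edges <- function(edges) {
  n <- nrow(edges)
  if (n == 0) return(edges)
  ord <- order(edges$child, edges$parent, edges$left, edges$right)
  child <- edges$child[ord]; parent <- edges$parent[ord]
  left <- edges$left[ord]; right <- edges$right[ord]
  same <- c(FALSE, child[-1L] == child[-n] & parent[-1L] == parent[-n])
  grp <- cumsum(!same)
  cm <- stats::ave(right, grp, FUN = cummax)
  prevcm <- c(-Inf, cm[-n])
  prevcm[!same] <- -Inf
  start_new <- left > prevcm  # strict gap: abutting/overlapping rows merge
  run <- cumsum(start_new)
  out <- data.frame(child = child[start_new], parent = parent[start_new],
                    left = left[start_new],
                    right = as.numeric(tapply(right, run, max)))
  rownames(out) <- NULL
  out
}

#' @export
print.garg <- function(x, ...) {
  cat(sprintf("gARG: %d nodes (%d samples), %d edge intervals, L = %s\n",
              nrow(x$nodes), length(x$samples), nrow(x$edges),
              format(x$L)))
  invisible(x)
}

#' @export
summary.garg <- function(object, ...) {
  pairs <- unique(object$edges[, c("child", "parent")])
  cat(sprintf("gARG over [0, %s)\n", format(object$L)))
  cat(sprintf("  nodes: %d (%d samples, %d dated)\n", nrow(object$nodes),
              length(object$samples), sum(!is.na(object$nodes$time))))
  cat(sprintf("  edges: %d (child, parent) pairs, %d interval rows\n",
              nrow(pairs), nrow(object$edges)))
  v <- validate_garg(object)
  if (length(v) == 0) {
    cat("  structurally valid\n")
  } else {
    cat("  violations:\n")
    for (msg in v) cat("   - ", msg, "\n", sep = "")
  }
  invisible(object)
}

#' Look up a node id by its metadata label
#'
#' Worked-example fixtures label nodes with letters in the `metadata` column;
#' this resolves a label to the integer node id.
#'
#' @param g A `garg` or `earg`.
#' @param label Character label(s) to look up.
#' @return Integer node id(s).
#' @export
node_id <- function(g, label) {
  tab <- if (inherits(g, "earg")) g$events else g$nodes
  idx <- match(label, tab$metadata)
  if (anyNA(idx)) {
    stop("no node with label: ", paste(label[is.na(idx)], collapse = ", "))
  }
  tab$id[idx]
}

#' Structural validation of a gARG
#'
#' Checks every invariant of the data model and returns the violations as
#' data rather than raising conditions: duplicate node ids, self edges,
#' references to unknown nodes, intervals outside `[0, L)`, overlapping
#' inheritance from distinct parents, cycles, sample-set membership, and
#' (when every node is dated) time ordering along edges.
#'
#' @param g A `garg`.
#' @return A character vector of violation messages; empty iff `g` is valid.
#' @export
validate_garg <- function(g) {
  v <- character(0)
  nd <- g$nodes
  ed <- g$edges

  dup <- nd$id[duplicated(nd$id)]
  if (length(dup) > 0) {
    v <- c(v, paste0("duplicate node ids: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(g$samples, nd$id)
  if (length(bad) > 0) {
    v <- c(v, paste0("sample ids not in node table: ", paste(bad, collapse = ", ")))
  }
  if (nrow(ed) > 0) {
    self <- ed$child == ed$parent
    for (i in which(self)) {
      v <- c(v, paste0("self edge at node ", ed$child[i]))
    }
    unk <- setdiff(unique(c(ed$child, ed$parent)), nd$id)
    if (length(unk) > 0) {
      v <- c(v, paste0("edge references unknown nodes: ", paste(unk, collapse = ", ")))
    }
    out_of_range <- ed$left < 0 | ed$right > g$L
    for (i in which(out_of_range)) {
      v <- c(v, sprintf("edge (%d, %d) interval [%s, %s) outside [0, %s)",
                        ed$child[i], ed$parent[i], format(ed$left[i]),
                        format(ed$right[i]), format(g$L)))
    }
    # per child, inheritance from distinct parents must be disjoint
    for (ch in unique(ed$child[!self])) {
      rows <- ed[ed$child == ch & ed$child != ed$parent, , drop = FALSE]
      per_parent <- lapply(split(seq_len(nrow(rows)), rows$parent), function(ix) {
        canonicalize_iset(cbind(rows$left[ix], rows$right[ix]))
      })
      if (length(per_parent) > 1) {
        ov <- iset_covered_at_least(per_parent, 2L)
        if (nrow(ov) > 0) {
          v <- c(v, sprintf("overlapping parental inheritance [%s, %s) for child %d",
                            format(ov[1L, 1L]), format(ov[1L, 2L]), ch))
        }
      }
    }
    if (length(unk) == 0 && length(dup) == 0) {
      if (is.null(topo_order(g))) {
        v <- c(v, "graph contains a cycle")
      }
    }
    if (all(!is.na(nd$time)) && nrow(ed) > 0) {
      tm <- stats::setNames(nd$time, nd$id)
      bad_t <- tm[as.character(ed$parent)] <= tm[as.character(ed$child)]
      for (i in which(bad_t & !self)) {
        v <- c(v, sprintf("edge (%d, %d) violates time ordering",
                          ed$child[i], ed$parent[i]))
      }
    }
  }
  unique(v)
}

# Topological order of node ids, children before parents.
# Returns NULL if the graph has a cycle. When all nodes are dated the
# order is by (time, id), which is also topological for a valid graph.
topo_order <- function(g) {
  nd <- g$nodes
  ed <- g$edges
  ids <- nd$id
  if (nrow(ed) == 0) return(ids)
  # Kahn's algorithm on child -> parent direction
  idx <- stats::setNames(seq_along(ids), ids)
  indeg <- integer(length(ids))  # number of unprocessed children feeding each node
  kids <- vector("list", length(ids))
  pairs <- unique(ed[, c("child", "parent")])
  for (i in seq_len(nrow(pairs))) {
    ci <- idx[[as.character(pairs$child[i])]]
    pi <- idx[[as.character(pairs$parent[i])]]
    indeg[pi] <- indeg[pi] + 1L
    kids[[ci]] <- c(kids[[ci]], pi)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    u <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, u)
    for (p in kids[[u]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids)) return(NULL)
  ids[out]
}

# Pastwards propagation of per-sample ancestry through the edges.
# Returns, for each node (as character id), a list with elements
#   path: interval set where the node lies on an inheritance path from
#         at least one sample,
#   all:  interval set where the node is an ancestor of *every* sample.
# Used by ancestral_material(), simplify and coalescence spans.
ancestry_tables <- function(g, samples) {
  samples <- as.integer(samples)
  if (length(samples) == 0) stop("sample set must be nonempty")
  unknown <- setdiff(samples, g$nodes$id)
  if (length(unknown) > 0) {
    stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  }
  ord <- topo_order(g)
  if (is.null(ord)) stop("gARG contains a cycle; cannot propagate ancestry")
  ids <- as.character(g$nodes$id)
  full <- interval_set(0, g$L)
  ed <- g$edges
  edges_by_child <- if (nrow(ed) > 0) split(seq_len(nrow(ed)), ed$child) else list()

  per_sample <- vector("list", length(samples))
  names(per_sample) <- as.character(samples)
  for (s in as.character(samples)) {
    anc <- stats::setNames(rep(list(empty_iset()), length(ids)), ids)
    anc[[s]] <- full
    for (u in as.character(ord)) {
      au <- anc[[u]]
      if (nrow(au) == 0) next
      for (i in edges_by_child[[u]]) {
        contrib <- interval_intersect(au, interval_set(ed$left[i], ed$right[i]))
        if (nrow(contrib) > 0) {
          p <- as.character(ed$parent[i])
          anc[[p]] <- interval_union(anc[[p]], contrib)
        }
      }
    }
    per_sample[[s]] <- anc
  }

  res <- stats::setNames(vector("list", length(ids)), ids)
  for (u in ids) {
    sets <- lapply(per_sample, `[[`, u)
    path <- iset_union_all(sets)
    all_anc <- sets[[1L]]
    if (length(sets) > 1) {
      for (k in 2:length(sets)) {
        if (nrow(all_anc) == 0) break
        all_anc <- interval_intersect(all_anc, sets[[k]])
      }
    }
    res[[u]] <- list(path = path, all = all_anc)
  }
  res
}

#' Ancestral material of a node
#'
#' The ancestral material of a node, with respect to a sample set, is the set
#' of genomic intervals at which the node lies on a path of genetic
#' inheritance from at least one sample. It is computed by propagating the
#' samples' full genomes pastwards through the graph, intersecting with each
#' edge's inheritance intervals.
#'
#' @param g A `garg`.
#' @param node A single node id.
#' @param samples Integer vector of sample ids; defaults to `g$samples`.
#' @return An `interval_set`.
#' @examples
#' fx <- arg_fixtures()
#' ancestral_material(fx$fig1, node_id(fx$fig1, "f"))  # [2, 10)
#' @export
ancestral_material <- function(g, node, samples = g$samples) {
  node <- as.integer(node)
  if (!(node %in% g$nodes$id)) stop("unknown node id: ", node)
  anc <- ancestry_tables(g, samples)
  anc[[as.character(node)]]$path
}
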