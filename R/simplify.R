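SIMPLIFY_LEVELS <- c("resolve-only", "prune-singly-connected",
                     "prune-unary-everywhere", "full")

normalize_level <- function(level) {
  aliases <- c("resolve" = "resolve-only",
               "prune-sc" = "prune-singly-connected",
               "prune-unary" = "prune-unary-everywhere")
  if (level %in% names(aliases)) level <- aliases[[level]]
  match.arg(level, SIMPLIFY_LEVELS)
}

# interval sets per (child, parent) pair, keyed "child|parent"
edge_pair_sets <- function(edges) {
  if (nrow(edges) == 0) return(list())
  key <- paste(edges$child, edges$parent, sep = "|")
  lapply(split(seq_len(nrow(edges)), key), function(ix) {
    canonicalize_iset(cbind(edges$left[ix], edges$right[ix]))
  })
}

pairs_to_edges <- function(sets) {
  if (length(sets) == 0) {
    return(data.frame(child = integer(0), parent = integer(0),
                      left = numeric(0), right = numeric(0)))
  }
  rows <- lapply(names(sets), function(k) {
    is <- sets[[k]]
    if (nrow(is) == 0) return(NULL)
    cp <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
    data.frame(child = cp[1L], parent = cp[2L], left = is[, 1L], right = is[, 2L])
  })
  ed <- do.call(rbind, rows)
  if (is.null(ed)) {
    return(data.frame(child = integer(0), parent = integer(0),
                      left = numeric(0), right = numeric(0)))
  }
  canonicalize_edges(ed)
}

#' Coalescence spans of every node
#'
#' For each node, with respect to a sample set: its *ancestral* interval set
#' (loci where it lies on an inheritance path from at least one sample), the
#' *coalescent* subset (loci where at least two child-edge lineages carrying
#' ancestral material meet in the node), and the fraction of the ancestral
#' span that is coalescent. Nodes with a fraction strictly between 0 and 1
#' are "locally unary": they are pass-through in some local trees but mark a
#' coalescence elsewhere along the genome.
#'
#' @param g A `garg`.
#' @param samples Sample node ids; defaults to `g$samples`.
#' @return A named list (by node id), each element a list with
#'   `coalescent`, `ancestral` (interval sets) and `fraction` in `[0, 1]`.
#'   Printable summary via [as.data.frame()] on the `"coalescence_spans"`
#'   class.
#' @examples
#' fx <- arg_fixtures()
#' sp <- coalescence_spans(fx$fig1)
#' sp[[as.character(node_id(fx$fig1, "f"))]]$fraction  # 5/8
#' @export
coalescence_spans <- function(g, samples = g$samples) {
  anc <- ancestry_tables(g, samples)
  sets <- edge_pair_sets(g$edges)
  child_of_pair <- lapply(strsplit(names(sets), "|", fixed = TRUE), as.integer)
  out <- stats::setNames(vector("list", nrow(g$nodes)), g$nodes$id)
  for (i in seq_len(nrow(g$nodes))) {
    u <- g$nodes$id[i]
    ancestral <- anc[[as.character(u)]]$path
    kid_sets <- list()
    for (k in seq_along(sets)) {
      if (child_of_pair[[k]][2L] == u) {
        c_id <- child_of_pair[[k]][1L]
        clip <- interval_intersect(sets[[k]], anc[[as.character(c_id)]]$path)
        if (nrow(clip) > 0) kid_sets[[length(kid_sets) + 1L]] <- clip
      }
    }
    coalescent <- if (length(kid_sets) >= 2) {
      iset_covered_at_least(kid_sets, 2L)
    } else {
      empty_iset()
    }
    a_span <- interval_span(ancestral)
    frac <- if (a_span > 0) interval_span(coalescent) / a_span else 0
    out[[as.character(u)]] <- list(coalescent = coalescent,
                                   ancestral = ancestral, fraction = frac)
  }
  class(out) <- "coalescence_spans"
  out
}

#' @export
as.data.frame.coalescence_spans <- function(x, ...) {
  data.frame(
    id = as.integer(names(x)),
    ancestral_span = vapply(x, function(e) interval_span(e$ancestral), numeric(1)),
    coalescent_span = vapply(x, function(e) interval_span(e$coalescent), numeric(1)),
    fraction = vapply(x, function(e) e$fraction, numeric(1)),
    row.names = NULL
  )
}

#' @export
print.coalescence_spans <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

# Hudson-style resolution: each edge's intervals are intersected with the
# child's ancestral material, truncated where the whole sample set has
# already coalesced in the child or one of its descendants (material above
# a locus MRCA carries no further information about the sample's ancestry).
resolve_edges <- function(g, samples, anc = ancestry_tables(g, samples)) {
  sets <- edge_pair_sets(g$edges)
  out <- sets
  for (k in names(sets)) {
    cp <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
    a <- anc[[as.character(cp[1L])]]
    pending <- interval_subtract(a$path, a$all)
    out[[k]] <- interval_intersect(sets[[k]], pending)
  }
  out
}

collapse_diamonds <- function(nodes, sets, samples, retain) {
  protected <- union(samples, retain)
  repeat {
    pair_cp <- lapply(strsplit(names(sets), "|", fixed = TRUE), as.integer)
    nonempty <- vapply(sets, function(s) nrow(s) > 0, logical(1))
    ch <- vapply(pair_cp, `[`, integer(1), 1L)[nonempty]
    pa <- vapply(pair_cp, `[`, integer(1), 2L)[nonempty]
    n_child_pairs <- table(factor(pa, levels = nodes$id))
    n_parent_pairs <- table(factor(ch, levels = nodes$id))
    pure <- stats::setNames(
      as.integer(n_child_pairs) == 1L & as.integer(n_parent_pairs) == 1L &
        !(nodes$id %in% protected),
      nodes$id
    )
    changed <- FALSE
    for (v in unique(ch[duplicated(ch)])) {
      parents <- pa[ch == v]
      chains <- lapply(parents, function(p) {
        interior <- integer(0)
        iv <- sets[[paste(v, p, sep = "|")]]
        cur <- p
        while (isTRUE(pure[[as.character(cur)]])) {
          nxt <- pa[ch == cur]
          if (length(nxt) != 1L) break
          iv <- interval_intersect(iv, sets[[paste(cur, nxt, sep = "|")]])
          interior <- c(interior, cur)
          cur <- nxt
        }
        list(terminal = cur, interior = interior, interval = iv)
      })
      terminals <- vapply(chains, `[[`, integer(1), "terminal")
      for (w in unique(terminals[duplicated(terminals)])) {
        grp <- chains[terminals == w]
        if (length(grp) < 2L) next
        merged <- iset_union_all(lapply(grp, `[[`, "interval"))
        drop_nodes <- unlist(lapply(grp, `[[`, "interior"))
        # remove the chain edges (v -> p and every interior hop)
        for (chain in grp) {
          hops <- c(v, chain$interior, chain$terminal)
          for (j in seq_len(length(hops) - 1L)) {
            sets[[paste(hops[j], hops[j + 1L], sep = "|")]] <- NULL
          }
        }
        key <- paste(v, w, sep = "|")
        sets[[key]] <- if (is.null(sets[[key]])) merged else {
          interval_union(sets[[key]], merged)
        }
        if (length(drop_nodes) > 0) {
          nodes <- nodes[!(nodes$id %in% drop_nodes), , drop = FALSE]
        }
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (!changed) break
  }
  list(nodes = nodes, sets = sets)
}

#' Simplify a gARG with respect to a sample set
#'
#' Propagates and resolves ancestral material for the samples, producing a
#' sample-resolved gARG at one of four precision levels, ordered by
#' strictness:
#'
#' * `"resolve-only"`: edge intervals are intersected with the child's
#'   ancestral material (truncated where the full sample set has already
#'   coalesced); empty edges are dropped, and non-sample nodes left with no
#'   edges are removed. Topology is otherwise preserved.
#' * `"prune-singly-connected"`: additionally collapses reconvergent
#'   pass-through ("diamond") structures: groups of two or more parallel
#'   unary chains from one child that rejoin at a single ancestor without
#'   carrying any coalescence are replaced by a direct edge.
#' * `"prune-unary-everywhere"`: additionally removes nodes whose coalescent
#'   span is empty, reconnecting their children to the next surviving
#'   ancestor locus by locus.
#' * `"full"`: bypasses every locally-unary node per locus, so that every
#'   surviving node-interval pair has at least two children in its local
#'   tree (the conventional "fully simplified" form).
#'
#' The restricted local trees over the samples are preserved exactly at
#' every level.
#'
#' @param g A valid `garg`.
#' @param samples Nonempty vector of sample node ids; defaults to `g$samples`.
#' @param level Simplification level (aliases `"resolve"`, `"prune-sc"`,
#'   `"prune-unary"` are accepted).
#' @param retain_nodes Node ids forced to survive (e.g. nodes marking
#'   recombination events), exempt from pruning at every level.
#' @param densify_ids If `TRUE`, surviving nodes are renumbered `0..n-1` in
#'   time order (topological order with samples first when times are
#'   missing).
#' @return A list with elements `garg` (the simplified graph) and `report`,
#'   a `simplify_report` carrying `node_map` (old id to new id, `NA` when
#'   removed), `removed_edges` (a data frame of dropped (child, parent)
#'   pairs, in input ids) and `spans`, the [coalescence_spans()] of the
#'   input.
#' @examples
#' fx <- arg_fixtures()
#' res <- simplify_garg(fx$fig5, level = "full")
#' res$garg
#' @export
simplify_garg <- function(g, samples = g$samples, level = "resolve-only",
                          retain_nodes = integer(0), densify_ids = FALSE) {
  level <- normalize_level(level)
  if (length(samples) == 0) stop("sample set must be nonempty")
  samples <- sort(unique(as.integer(samples)))
  unknown <- setdiff(samples, g$nodes$id)
  if (length(unknown) > 0) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  retain_nodes <- intersect(as.integer(retain_nodes), g$nodes$id)

  anc <- ancestry_tables(g, samples)
  spans <- coalescence_spans(g, samples)
  input_pairs <- unique(g$edges[, c("child", "parent")])

  sets <- resolve_edges(g, samples, anc)
  nodes <- g$nodes

  if (level %in% c("prune-singly-connected", "prune-unary-everywhere", "full")) {
    res <- collapse_diamonds(nodes, sets, samples, retain_nodes)
    nodes <- res$nodes
    sets <- res$sets
  }

  if (level %in% c("prune-unary-everywhere", "full")) {
    # coalescence spans on the current (resolved, possibly collapsed) graph
    cur <- garg(g$L, nodes, pairs_to_edges(sets), samples = samples)
    cur_spans <- coalescence_spans(cur, samples)
    removable <- nodes$id[
      !(nodes$id %in% samples) & !(nodes$id %in% retain_nodes) &
        vapply(as.character(nodes$id),
               function(u) nrow(cur_spans[[u]]$coalescent) == 0, logical(1))
    ]
    # reconnect through removed nodes, youngest first, so chains compose
    ordv <- topo_order(cur)
    for (u in intersect(ordv, removable)) {
      keys <- names(sets)
      cps <- strsplit(keys, "|", fixed = TRUE)
      child_keys <- keys[vapply(cps, function(x) x[2L] == u, logical(1))]
      parent_keys <- keys[vapply(cps, function(x) x[1L] == u, logical(1))]
      for (ck in child_keys) {
        c_id <- strsplit(ck, "|", fixed = TRUE)[[1L]][1L]
        for (pk in parent_keys) {
          p_id <- strsplit(pk, "|", fixed = TRUE)[[1L]][2L]
          piece <- interval_intersect(sets[[ck]], sets[[pk]])
          if (nrow(piece) > 0) {
            key <- paste(c_id, p_id, sep = "|")
            sets[[key]] <- if (is.null(sets[[key]])) piece else {
              interval_union(sets[[key]], piece)
            }
          }
        }
      }
      for (k in c(child_keys, parent_keys)) sets[[k]] <- NULL
      nodes <- nodes[nodes$id != as.integer(u), , drop = FALSE]
    }
  }

  g_out <- garg(g$L, nodes, pairs_to_edges(sets), samples = samples)

  if (level == "full") {
    lts <- trees(g_out, samples, mode = "as-stored")
    acc <- list()
    for (f in lts$forests) {
      rf <- reduce_forest(f, keep_extra = retain_nodes)
      po <- rf$parent_of
      for (u in names(po)) {
        p <- po[[u]]
        if (is.na(p)) next
        key <- paste(u, p, sep = "|")
        piece <- interval_set(f$left, f$right)
        acc[[key]] <- if (is.null(acc[[key]])) piece else {
          interval_union(acc[[key]], piece)
        }
      }
    }
    used <- unique(unlist(lapply(names(acc), function(k) {
      as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
    })))
    keep_ids <- sort(unique(c(used, samples, retain_nodes)))
    nodes_out <- g_out$nodes[g_out$nodes$id %in% keep_ids, , drop = FALSE]
    g_out <- garg(g$L, nodes_out, pairs_to_edges(acc), samples = samples)
  }

  # drop non-sample, non-retained nodes with no incident edges
  incident <- unique(c(g_out$edges$child, g_out$edges$parent))
  keep <- g_out$nodes$id %in% c(incident, samples, retain_nodes)
  g_out <- garg(g$L, g_out$nodes[keep, , drop = FALSE], g_out$edges,
                samples = samples)

  node_map <- stats::setNames(rep(NA_integer_, nrow(g$nodes)), g$nodes$id)
  node_map[as.character(g_out$nodes$id)] <- g_out$nodes$id

  if (densify_ids) {
    nd <- g_out$nodes
    if (all(!is.na(nd$time))) {
      ord <- order(nd$time, nd$id)
    } else {
      topo <- topo_order(g_out)
      ord <- order(!(nd$id %in% samples), match(nd$id, topo))
    }
    new_ids <- stats::setNames(seq_along(ord) - 1L, nd$id[ord])
    ed <- g_out$edges
    ed$child <- new_ids[as.character(ed$child)]
    ed$parent <- new_ids[as.character(ed$parent)]
    nd$id <- new_ids[as.character(nd$id)]
    g_out <- garg(g$L, nd, ed, samples = unname(new_ids[as.character(samples)]))
    node_map[!is.na(node_map)] <-
      unname(new_ids[as.character(node_map[!is.na(node_map)])])
  }

  out_pairs <- unique(g_out$edges[, c("child", "parent")])
  if (densify_ids) {
    # report removed edges in input ids
    old_of_new <- stats::setNames(as.integer(names(node_map[!is.na(node_map)])),
                                  node_map[!is.na(node_map)])
    out_pairs$child <- old_of_new[as.character(out_pairs$child)]
    out_pairs$parent <- old_of_new[as.character(out_pairs$parent)]
  }
  removed <- input_pairs[
    !(paste(input_pairs$child, input_pairs$parent) %in%
        paste(out_pairs$child, out_pairs$parent)), , drop = FALSE]
  rownames(removed) <- NULL

  report <- structure(list(node_map = node_map, removed_edges = removed,
                           spans = spans, level = level),
                      class = "simplify_report")
  list(garg = g_out, report = report)
}

#' @export
print.simplify_report <- function(x, ...) {
  cat(sprintf("simplify report (level %s): %d of %d nodes removed, %d edges removed\n",
              x$level, sum(is.na(x$node_map)), length(x$node_map),
              nrow(x$removed_edges)))
  invisible(x)
}
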