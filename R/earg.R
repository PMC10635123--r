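#' Construct an event ARG (eARG)
#'
#' The classical ARG encoding: internal nodes are *events* rather than
#' genomes. Common-ancestor events merge two lineages into one parent
#' lineage; recombination events split one lineage in two and carry a
#' crossover breakpoint, with the two parent edges explicitly designated
#' `left` and `right` (material left of the breakpoint follows the left
#' parent). Local trees are recovered by tracing pastwards from the samples
#' and routing through recombination nodes by breakpoint position.
#'
#' @param L Genome length.
#' @param events Data frame with columns `id`, `kind` (one of `"sample"`,
#'   `"common-ancestor"`, `"recombination"`), `breakpoint` (`NA` except for
#'   recombination events), `time` (optional, `NA` allowed) and optionally
#'   `metadata`.
#' @param edges Data frame with columns `child`, `parent`, `side` (one of
#'   `"left"`, `"right"`, `"only"`): the parent edges of each event.
#' @return An object of class `earg`.
#' @seealso [earg_tree_at()], [earg_to_garg()], [convert_and_resolve()]
#' @export
earg <- function(L, events, edges) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("L must be a single positive number")
  }
  events <- as.data.frame(events)
  if (!all(c("id", "kind") %in% names(events))) {
    stop("events must have columns id and kind")
  }
  if (is.null(events$breakpoint)) events$breakpoint <- NA_real_
  if (is.null(events$time)) events$time <- NA_real_
  if (is.null(events$metadata)) events$metadata <- ""
  events$id <- as.integer(events$id)
  events$kind <- as.character(events$kind)
  events$breakpoint <- as.numeric(events$breakpoint)
  events$time <- as.numeric(events$time)
  events$metadata <- as.character(events$metadata)
  events <- events[order(events$id),
                   c("id", "kind", "breakpoint", "time", "metadata")]
  rownames(events) <- NULL

  edges <- as.data.frame(edges)
  if (!all(c("child", "parent", "side") %in% names(edges))) {
    stop("edges must have columns child, parent, side")
  }
  edges <- edges[, c("child", "parent", "side")]
  edges$child <- as.integer(edges$child)
  edges$parent <- as.integer(edges$parent)
  edges$side <- as.character(edges$side)
  edges <- edges[order(edges$child, edges$side), ]
  rownames(edges) <- NULL

  structure(list(L = as.numeric(L), events = events, edges = edges),
            class = "earg")
}

#' @export
print.earg <- function(x, ...) {
  kinds <- table(x$events$kind)
  cat(sprintf("eARG: %d events (%s), %d parent edges, L = %s\n",
              nrow(x$events),
              paste(names(kinds), as.integer(kinds), sep = ": ", collapse = ", "),
              nrow(x$edges), format(x$L)))
  invisible(x)
}

#' Structural validation of an eARG
#'
#' @param e An `earg`.
#' @return Character vector of violations; empty iff valid.
#' @export
validate_earg <- function(e) {
  v <- character(0)
  ev <- e$events
  ed <- e$edges
  ok_kinds <- c("sample", "common-ancestor", "recombination")
  bad <- unique(ev$kind[!(ev$kind %in% ok_kinds)])
  if (length(bad) > 0) v <- c(v, paste0("unknown event kinds: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(ev$id)) v <- c(v, "duplicate event ids")
  unk <- setdiff(unique(c(ed$child, ed$parent)), ev$id)
  if (length(unk) > 0) v <- c(v, paste0("edge references unknown events: ", paste(unk, collapse = ", ")))
  bad_side <- unique(ed$side[!(ed$side %in% c("left", "right", "only"))])
  if (length(bad_side) > 0) v <- c(v, paste0("unknown edge sides: ", paste(bad_side, collapse = ", ")))

  for (i in seq_len(nrow(ev))) {
    u <- ev$id[i]
    out <- ed[ed$child == u, , drop = FALSE]
    if (ev$kind[i] == "recombination") {
      if (is.na(ev$breakpoint[i]) || ev$breakpoint[i] < 0 || ev$breakpoint[i] > e$L) {
        v <- c(v, paste0("recombination event ", u, " lacks a breakpoint in [0, L]"))
      }
      if (nrow(out) != 2L || !setequal(out$side, c("left", "right"))) {
        v <- c(v, paste0("recombination event ", u,
                         " must have exactly one left and one right parent edge"))
      }
    } else {
      if (!is.na(ev$breakpoint[i])) {
        v <- c(v, paste0("non-recombination event ", u, " carries a breakpoint"))
      }
      if (nrow(out) > 1L || any(out$side != "only")) {
        v <- c(v, paste0("event ", u, " must have at most one parent edge, side 'only'"))
      }
    }
  }
  # acyclicity via the corresponding topology
  ids <- ev$id
  idx <- stats::setNames(seq_along(ids), ids)
  if (length(unk) == 0 && nrow(ed) > 0) {
    g <- garg(e$L,
              data.frame(id = ids, is_sample = ev$kind == "sample", time = ev$time),
              data.frame(child = ed$child, parent = ed$parent,
                         left = 0, right = e$L))
    if (is.null(topo_order(g))) v <- c(v, "graph contains a cycle")
  }
  unique(v)
}

earg_samples <- function(e) e$events$id[e$events$kind == "sample"]

#' Local tree of an eARG at one position
#'
#' Traces pastwards from each sample, routing through each recombination
#' node by its breakpoint: material at position `x` follows the left parent
#' iff `x` is strictly left of the breakpoint (a position exactly at the
#' breakpoint routes rightwards, matching the half-open `[0, b)` / `[b, L)`
#' convention). Paths merge at common-ancestor nodes.
#'
#' @param e An `earg`.
#' @param x Genome position, `0 <= x < L`.
#' @param samples Sample event ids; defaults to all sample events.
#' @return A `local_forest`.
#' @export
earg_tree_at <- function(e, x, samples = earg_samples(e)) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x >= e$L) {
    stop("position x must satisfy 0 <= x < L")
  }
  v <- validate_earg(e)
  if (length(v) > 0) stop("malformed eARG: ", paste(v, collapse = "; "))
  ev <- e$events
  ed <- e$edges
  parent_at <- function(u) {
    out <- ed[ed$child == u, , drop = FALSE]
    if (nrow(out) == 0) return(NA_integer_)
    kind <- ev$kind[ev$id == u]
    if (kind == "recombination") {
      b <- ev$breakpoint[ev$id == u]
      side <- if (x < b) "left" else "right"
      as.integer(out$parent[out$side == side])
    } else {
      as.integer(out$parent[1L])
    }
  }
  parent_of <- integer(0)
  queue <- as.integer(samples)
  seen <- integer(0)
  while (length(queue) > 0) {
    u <- queue[1L]
    queue <- queue[-1L]
    if (u %in% seen) next
    seen <- c(seen, u)
    p <- parent_at(u)
    parent_of[[as.character(u)]] <- p
    if (!is.na(p) && !(p %in% seen)) queue <- c(queue, p)
  }
  new_local_forest(x, x, parent_of, as.integer(samples))
}

#' Convert an eARG to a gARG
#'
#' Node-for-node copy of the topology, with inheritance annotations derived
#' from the event types: the single outbound edge of a common-ancestor (or
#' sample) event is annotated `[0, L)`; the two outbound edges of a
#' recombination event with breakpoint `b` are annotated `[0, b)` (left) and
#' `[b, L)` (right). The conversion is information-preserving: annotations
#' are in one-to-one correspondence with the event structure.
#'
#' @param e A valid `earg`.
#' @return A `garg` with the same node ids, times and metadata; sample
#'   events become sample nodes.
#' @export
earg_to_garg <- function(e) {
  v <- validate_earg(e)
  if (length(v) > 0) stop("malformed eARG: ", paste(v, collapse = "; "))
  ev <- e$events
  ed <- e$edges
  child <- integer(0); parent <- integer(0); left <- numeric(0); right <- numeric(0)
  for (i in seq_len(nrow(ed))) {
    u <- ed$child[i]
    kind <- ev$kind[ev$id == u]
    if (kind == "recombination") {
      b <- ev$breakpoint[ev$id == u]
      if (ed$side[i] == "left") {
        if (b > 0) {
          child <- c(child, u); parent <- c(parent, ed$parent[i])
          left <- c(left, 0); right <- c(right, b)
        }
      } else {
        if (b < e$L) {
          child <- c(child, u); parent <- c(parent, ed$parent[i])
          left <- c(left, b); right <- c(right, e$L)
        }
      }
    } else {
      child <- c(child, u); parent <- c(parent, ed$parent[i])
      left <- c(left, 0); right <- c(right, e$L)
    }
  }
  garg(e$L,
       data.frame(id = ev$id, is_sample = ev$kind == "sample",
                  time = ev$time, metadata = ev$metadata),
       data.frame(child = child, parent = parent, left = left, right = right))
}

#' Convert an eARG to a sample-resolved gARG
#'
#' The two-step conversion: annotate the event topology with inheritance
#' intervals ([earg_to_garg()]), then resolve the ancestral material of the
#' samples ([simplify_garg()] at level `"resolve-only"`). Nodes marking
#' recombination events are retained even where resolution leaves them
#' without ancestral material; pass `retain_recombinations = FALSE` to let
#' them be dropped like any other node.
#'
#' @param e A valid `earg`.
#' @param samples Sample ids; defaults to the eARG's sample events.
#' @param retain_recombinations Keep recombination-event nodes (default
#'   `TRUE`).
#' @return A list with `garg` (the sample-resolved gARG) and `report` (a
#'   `simplify_report`).
#' @examples
#' fx <- arg_fixtures()
#' res <- convert_and_resolve(fx$fig3)
#' # the grand MRCA is gone:
#' node_id(fx$fig3, "q") %in% res$garg$nodes$id
#' @export
convert_and_resolve <- function(e, samples = earg_samples(e),
                                retain_recombinations = TRUE) {
  g <- earg_to_garg(e)
  retain <- if (retain_recombinations) {
    e$events$id[e$events$kind == "recombination"]
  } else {
    integer(0)
  }
  simplify_garg(g, samples = samples, level = "resolve-only",
                retain_nodes = retain)
}
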