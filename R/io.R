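# Serialize a position/time with full round-trip precision, integer-valued
# doubles without a decimal point (byte-stable output).
format_pos <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (v == floor(v) && abs(v) < 2^53) sprintf("%.0f", v) else sprintf("%.17g", v)
  }, character(1))
}

io_error <- function(path, line, reason) {
  stop(sprintf("%s: line %d: %s", path, line, reason), call. = FALSE)
}

#' Read and write gARG node/edge tables
#'
#' Plain TSV serialization of a gARG: `#`-prefixed header lines carry the
#' format version and genome length, followed by a `#NODES` section
#' (`id`, `is_sample`, `time`, `metadata`; a blank time field means
#' "unknown") and an `#EDGES` section (`child`, `parent`, `left`, `right`;
#' one row per interval, sorted by child, parent, left). Positions are
#' written with full round-trip precision, so writing the same canonical
#' gARG twice yields byte-identical files and `read_garg(write_garg(g))`
#' restores `g` exactly.
#'
#' @param g A `garg`.
#' @param path File path.
#' @param validate Validate the graph after reading (default `TRUE`); a
#'   structurally invalid file raises an error listing the violations.
#' @return `read_garg` returns a `garg`; `write_garg` returns `path`
#'   invisibly.
#' @export
write_garg <- function(g, path) {
  nd <- g$nodes
  ed <- g$edges
  lines <- c(
    "#garg\t1",
    paste0("#L\t", format_pos(g$L)),
    "#NODES",
    "#id\tis_sample\ttime\tmetadata",
    sprintf("%d\t%d\t%s\t%s", nd$id, as.integer(nd$id %in% g$samples),
            format_pos(nd$time), nd$metadata),
    "#EDGES",
    "#child\tparent\tleft\tright"
  )
  if (nrow(ed) > 0) {
    lines <- c(lines, sprintf("%d\t%d\t%s\t%s", ed$child, ed$parent,
                              format_pos(ed$left), format_pos(ed$right)))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_num <- function(s, path, line, what, allow_blank = FALSE) {
  if (allow_blank && (is.na(s) || s == "")) return(NA_real_)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) io_error(path, line, paste0("cannot parse ", what, ": '", s, "'"))
  v
}

#' @rdname write_garg
#' @export
read_garg <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1L], "#garg")) {
    io_error(path, 1L, "not a gARG file (missing '#garg' header)")
  }
  L <- NA_real_
  section <- ""
  nd <- list(); edl <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (startsWith(ln, "#")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (f[1L] == "#L") L <- parse_num(f[2L], path, i, "genome length")
      if (f[1L] == "#NODES") section <- "nodes"
      if (f[1L] == "#EDGES") section <- "edges"
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (section == "nodes") {
      if (length(f) < 3L) io_error(path, i, "node row needs id, is_sample, time[, metadata]")
      nd[[length(nd) + 1L]] <- data.frame(
        id = as.integer(parse_num(f[1L], path, i, "node id")),
        is_sample = parse_num(f[2L], path, i, "is_sample flag") != 0,
        time = parse_num(f[3L], path, i, "time", allow_blank = TRUE),
        metadata = if (length(f) >= 4L) f[4L] else ""
      )
    } else if (section == "edges") {
      if (length(f) != 4L) io_error(path, i, "edge row needs child, parent, left, right")
      left <- parse_num(f[3L], path, i, "left")
      right <- parse_num(f[4L], path, i, "right")
      if (left >= right) io_error(path, i, sprintf("left >= right (%s >= %s)", f[3L], f[4L]))
      edl[[length(edl) + 1L]] <- data.frame(
        child = as.integer(parse_num(f[1L], path, i, "child")),
        parent = as.integer(parse_num(f[2L], path, i, "parent")),
        left = left, right = right
      )
    } else {
      io_error(path, i, "data row outside #NODES/#EDGES section")
    }
  }
  if (is.na(L)) io_error(path, 1L, "missing '#L' header")
  if (length(nd) == 0) io_error(path, 1L, "no node rows")
  g <- garg(L, do.call(rbind, nd),
            if (length(edl) > 0) do.call(rbind, edl) else NULL)
  if (validate) {
    v <- validate_garg(g)
    if (length(v) > 0) {
      stop(sprintf("%s: invalid gARG:\n%s", path,
                   paste0("  - ", v, collapse = "\n")), call. = FALSE)
    }
  }
  g
}

#' Read and write eARG event/edge tables
#'
#' TSV serialization of an event ARG, analogous to [write_garg()]:
#' an `#EVENTS` section (`id`, `kind`, `breakpoint`, `time`, `metadata`;
#' blank breakpoint/time mean absent) and an `#EDGES` section (`child`,
#' `parent`, `side`).
#'
#' @param e An `earg`.
#' @param path File path.
#' @param validate Validate after reading (default `TRUE`).
#' @return `read_earg` returns an `earg`; `write_earg` returns `path`
#'   invisibly.
#' @export
write_earg <- function(e, path) {
  ev <- e$events
  ed <- e$edges
  lines <- c(
    "#earg\t1",
    paste0("#L\t", format_pos(e$L)),
    "#EVENTS",
    "#id\tkind\tbreakpoint\ttime\tmetadata",
    sprintf("%d\t%s\t%s\t%s\t%s", ev$id, ev$kind, format_pos(ev$breakpoint),
            format_pos(ev$time), ev$metadata),
    "#EDGES",
    "#child\tparent\tside"
  )
  if (nrow(ed) > 0) {
    lines <- c(lines, sprintf("%d\t%d\t%s", ed$child, ed$parent, ed$side))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_earg
#' @export
read_earg <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1L], "#earg")) {
    io_error(path, 1L, "not an eARG file (missing '#earg' header)")
  }
  L <- NA_real_
  section <- ""
  evl <- list(); edl <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (startsWith(ln, "#")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (f[1L] == "#L") L <- parse_num(f[2L], path, i, "genome length")
      if (f[1L] == "#EVENTS") section <- "events"
      if (f[1L] == "#EDGES") section <- "edges"
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (section == "events") {
      if (length(f) < 4L) io_error(path, i, "event row needs id, kind, breakpoint, time[, metadata]")
      evl[[length(evl) + 1L]] <- data.frame(
        id = as.integer(parse_num(f[1L], path, i, "event id")),
        kind = f[2L],
        breakpoint = parse_num(f[3L], path, i, "breakpoint", allow_blank = TRUE),
        time = parse_num(f[4L], path, i, "time", allow_blank = TRUE),
        metadata = if (length(f) >= 5L) f[5L] else ""
      )
    } else if (section == "edges") {
      if (length(f) != 3L) io_error(path, i, "edge row needs child, parent, side")
      edl[[length(edl) + 1L]] <- data.frame(
        child = as.integer(parse_num(f[1L], path, i, "child")),
        parent = as.integer(parse_num(f[2L], path, i, "parent")),
        side = f[3L]
      )
    } else {
      io_error(path, i, "data row outside #EVENTS/#EDGES section")
    }
  }
  if (is.na(L)) io_error(path, 1L, "missing '#L' header")
  if (length(evl) == 0) io_error(path, 1L, "no event rows")
  e <- earg(L, do.call(rbind, evl),
            if (length(edl) > 0) do.call(rbind, edl) else {
              data.frame(child = integer(0), parent = integer(0),
                         side = character(0))
            })
  if (validate) {
    v <- validate_earg(e)
    if (length(v) > 0) {
      stop(sprintf("%s: invalid eARG:\n%s", path,
                   paste0("  - ", v, collapse = "\n")), call. = FALSE)
    }
  }
  e
}
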