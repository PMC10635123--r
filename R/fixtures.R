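#' Worked-example fixtures
#'
#' In-memory transcriptions of four small worked examples used throughout
#' the documentation and tests. Node letters are stored in the `metadata`
#' column and can be resolved with [node_id()].
#'
#' * `fig1`: a gARG of 16 genomes (a-p) embedded in a pedigree of eight
#'   diploid individuals over four generations, genome length 10. Samples
#'   a-d; genome a inherits `[0,2)` from e and `[2,10)` from f, genome c is
#'   the complementary recombinant (`[0,7)` from f, `[7,10)` from e), b and
#'   d are non-recombinant copies of g and h. Samples a and c coalesce in f
#'   over `[2,7)`, where exactly three parental-generation genomes (f, g,
#'   h) carry ancestral material, and all samples reach their MRCA in n.
#'   Two recombination breakpoints (2 and 7) delineate three local trees.
#' * `fig2`: the classical three-sample eARG: samples a, b, c, one
#'   recombination event d (breakpoint `fig2_breakpoint`) and three
#'   common-ancestor events e, f, g; d inherits left of the breakpoint
#'   from e and right of it from f.
#' * `fig3`: a 17-event eARG (a-q) in the style of classical
#'   coalescent-with-recombination realizations: samples a, b, c, six
#'   recombination events (breakpoints 2, 3, 5, 6, 7, 8) and eight
#'   common-ancestor events, with a "grand MRCA" q. The genome fully
#'   coalesces in k (over `[0,3)`) and p (over `[3,10)`), so resolution
#'   against the samples removes q; the recombination at position 5 (node
#'   g) falls in non-ancestral material, so g's right-hand edge to j is
#'   dropped. This fixture is a reconstruction of the classical example:
#'   the event table satisfies all of those documented properties and every
#'   edge is listed explicitly below.
#' * `fig5`: a gARG of 18 genomes (a-r) in the shape produced by a diploid
#'   Wright-Fisher simulation, containing a reconvergent "diamond"
#'   j-l/m-n (genome j recombines at position 5 and both lineages rejoin
#'   in n without coalescing) and nodes that are unary everywhere (n, r),
#'   for exercising the simplification levels.
#'
#' @param fig2_breakpoint Breakpoint position of the recombination event in
#'   the `fig2` eARG (default 5).
#' @param L Genome length for `fig2` (default 10; `fig1`, `fig3` and `fig5`
#'   are fixed at 10).
#' @return A list with elements `fig1` (`garg`), `fig2` (`earg`), `fig3`
#'   (`earg`) and `fig5` (`garg`), all structurally valid.
#' @examples
#' fx <- arg_fixtures()
#' validate_garg(fx$fig1)
#' @export
arg_fixtures <- function(fig2_breakpoint = 5, L = 10) {
  list(fig1 = fixture_fig1(), fig2 = fixture_fig2(fig2_breakpoint, L),
       fig3 = fixture_fig3(), fig5 = fixture_fig5())
}

lab_ids <- function(labels) stats::setNames(seq_along(labels), labels)

fixture_fig1 <- function() {
  labs <- letters[1:16]
  id <- lab_ids(labs)
  times <- rep(0:3, each = 4)  # a-d samples, e-h, i-l, m-p
  e <- function(child, parent, left, right) {
    data.frame(child = id[[child]], parent = id[[parent]],
               left = left, right = right)
  }
  edges <- rbind(
    e("a", "e", 0, 2), e("a", "f", 2, 10),   # a: recombinant of e and f at 2
    e("b", "g", 0, 10),                      # b: direct copy of g
    e("c", "f", 0, 7), e("c", "e", 7, 10),   # c: complementary recombinant at 7
    e("d", "h", 0, 10),
    e("e", "i", 0, 10), e("f", "k", 0, 10),
    e("g", "i", 0, 10), e("h", "k", 0, 10),
    e("i", "n", 0, 10), e("k", "n", 0, 10),
    e("j", "o", 0, 10), e("l", "p", 0, 10)   # j, l: non-ancestral relatives
  )
  garg(10,
       data.frame(id = unname(id), is_sample = times == 0, time = times,
                  metadata = labs),
       edges)
}

fixture_fig2 <- function(breakpoint = 5, L = 10) {
  labs <- letters[1:7]
  id <- lab_ids(labs)
  ev <- data.frame(
    id = unname(id),
    kind = c("sample", "sample", "sample", "recombination",
             rep("common-ancestor", 3)),
    breakpoint = c(NA, NA, NA, breakpoint, NA, NA, NA),
    time = c(0, 0, 0, 1, 2, 3, 4),
    metadata = labs
  )
  ed <- function(child, parent, side) {
    data.frame(child = id[[child]], parent = id[[parent]], side = side)
  }
  earg(L, ev, rbind(
    ed("a", "d", "only"),
    ed("d", "e", "left"), ed("d", "f", "right"),
    ed("b", "e", "only"), ed("c", "f", "only"),
    ed("e", "g", "only"), ed("f", "g", "only")
  ))
}

fixture_fig3 <- function() {
  labs <- letters[1:17]  # a..q
  id <- lab_ids(labs)
  kind <- c(a = "sample", b = "sample", c = "sample",
            d = "recombination", e = "recombination", f = "common-ancestor",
            g = "recombination", h = "common-ancestor", i = "common-ancestor",
            j = "common-ancestor", k = "common-ancestor", l = "recombination",
            m = "common-ancestor", n = "recombination", o = "recombination",
            p = "common-ancestor", q = "common-ancestor")
  bp <- c(d = 2, e = 7, g = 5, l = 3, n = 8, o = 6)
  tm <- c(a = 0, b = 0, c = 0, d = 1, e = 1, l = 1, f = 2, g = 2.5, h = 3,
          n = 3.5, m = 4, i = 4.5, k = 5, p = 6, o = 7, j = 8, q = 9)
  ev <- data.frame(
    id = unname(id), kind = unname(kind[labs]),
    breakpoint = unname(bp[labs]),
    time = unname(tm[labs]), metadata = labs
  )
  ed <- function(child, parent, side) {
    data.frame(child = id[[child]], parent = id[[parent]], side = side)
  }
  earg(10, ev, rbind(
    ed("a", "d", "only"), ed("b", "l", "only"), ed("c", "e", "only"),
    ed("d", "g", "left"), ed("d", "f", "right"),
    ed("e", "f", "left"), ed("e", "h", "right"),
    ed("l", "m", "left"), ed("l", "i", "right"),
    ed("g", "h", "left"), ed("g", "j", "right"),
    ed("f", "n", "only"),
    ed("n", "k", "left"), ed("n", "i", "right"),
    ed("h", "m", "only"), ed("m", "k", "only"),
    ed("i", "p", "only"), ed("k", "p", "only"),
    ed("p", "o", "only"),
    ed("o", "q", "left"), ed("o", "j", "right"),
    ed("j", "q", "only")
  ))
}

fixture_fig5 <- function() {
  labs <- letters[1:18]  # a..r
  id <- lab_ids(labs)
  tm <- c(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0,
          g = 1, h = 1, i = 1, j = 1, l = 2, m = 2, r = 2,
          k = 3, n = 3, o = 4, p = 5, q = 6)
  e <- function(child, parent, left, right) {
    data.frame(child = id[[child]], parent = id[[parent]],
               left = left, right = right)
  }
  edges <- rbind(
    e("a", "g", 0, 10), e("b", "g", 0, 10),
    e("c", "h", 0, 10),
    e("d", "h", 0, 6), e("d", "i", 6, 10),   # d recombines at 6
    e("e", "i", 0, 10),
    e("f", "j", 0, 10),
    e("j", "l", 0, 5), e("j", "m", 5, 10),   # diamond: j splits at 5 ...
    e("l", "n", 0, 5), e("m", "n", 5, 10),   # ... and rejoins in n
    e("g", "r", 0, 10), e("r", "k", 0, 10),  # r: unary everywhere
    e("h", "k", 0, 10),
    e("k", "o", 0, 10), e("i", "o", 0, 10),
    e("o", "p", 0, 10), e("n", "p", 0, 10),
    e("p", "q", 0, 10)                       # q: above the MRCA p
  )
  garg(10,
       data.frame(id = unname(id), is_sample = unname(tm[labs]) == 0,
                  time = unname(tm[labs]), metadata = labs),
       edges)
}
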