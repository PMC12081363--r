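#' Edge degree
#'
#' The degree of an edge `uv` is `d(u) + d(v) - 2`: the number of edges
#' adjacent to it.  An edge joining two degree-1 vertices (an isolated
#' bond) has edge degree 0; this is admitted everywhere downstream.
#'
#' @param a,b endpoint degrees (positive integers, vectorized).
#' @return `a + b - 2`.
#' @examples
#' edge_degree(1, 3)  # 2
#' edge_degree(3, 3)  # 4
#' @export
edge_degree <- function(a, b) {
  if (any(a < 1) || any(b < 1)) stop("endpoint degrees must be >= 1")
  a + b - 2
}

#' Edge partition of a molecular graph
#'
#' Groups the edges by the unordered pair of endpoint degrees `(a, b)`
#' with `a <= b` and counts each class.  The partition is the sufficient
#' statistic for every K-Banhatti descriptor: endpoint degrees are kept
#' separately (rather than only the derived edge degree `a + b - 2`)
#' because the product-form descriptors need them.
#'
#' @param g a `molecular_graph`.
#' @return an `edge_partition`: a data frame with columns `a`, `b`
#'   (canonical `a <= b`), `edge_degree` and `count`, sorted by `(a, b)`.
#'   Class counts always sum to the number of edges of `g`.
#' @examples
#' p3 <- molecular_graph(rbind(c(1, 2), c(2, 3)))
#' edge_partition(p3)  # single class (1,2) with count 2
#' @export
edge_partition <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- degrees(g)
  du <- d[g$edges[, 1L]]
  dv <- d[g$edges[, 2L]]
  as_edge_partition(data.frame(a = pmin(du, dv), b = pmax(du, dv),
                               count = 1L))
}

#' Coerce degree-pair classes to an edge partition
#'
#' Accepts a data frame (or matrix) with columns `a`, `b` and `count`;
#' keys are canonicalized to `a <= b` and repeated classes are
#' aggregated, so `(3, 1)` and `(1, 3)` denote the same class.  This is
#' the entry point for partitions transcribed from published tables.
#'
#' @param x a data frame or matrix with columns `a`, `b`, `count`.
#' @return an `edge_partition` (see [edge_partition()]).
#' @examples
#' as_edge_partition(data.frame(a = c(1, 2), b = c(3, 2), count = c(4, 6)))
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  x <- as.data.frame(x)
  if (!all(c("a", "b", "count") %in% names(x))) {
    stop("'x' needs columns 'a', 'b' and 'count'")
  }
  a <- as.integer(x$a); b <- as.integer(x$b); m <- as.integer(x$count)
  if (any(a < 1) || any(b < 1)) stop("endpoint degrees must be >= 1")
  if (any(m < 0)) stop("class counts must be non-negative")
  keep <- m > 0L
  a <- a[keep]; b <- b[keep]; m <- m[keep]
  if (length(a) == 0L) stop("empty edge partition")
  lo <- pmin(a, b); hi <- pmax(a, b)
  agg <- stats::aggregate(list(count = m), list(a = lo, b = hi), sum)
  agg <- agg[order(agg$a, agg$b), , drop = FALSE]
  rownames(agg) <- NULL
  p <- data.frame(a = agg$a, b = agg$b,
                  edge_degree = edge_degree(agg$a, agg$b),
                  count = agg$count)
  class(p) <- c("edge_partition", "data.frame")
  p
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("<edge_partition> %d classes, %d edges\n",
              nrow(x), sum(x$count)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Multiplicity of a degree-pair class
#'
#' @param p an `edge_partition`.
#' @param a,b endpoint degrees; `(a, b)` and `(b, a)` are equivalent.
#' @return the class count, 0 if the class is absent.
#' @export
partition_multiplicity <- function(p, a, b) {
  stopifnot(inherits(p, "edge_partition"))
  lo <- min(a, b); hi <- max(a, b)
  hit <- p$a == lo & p$b == hi
  if (any(hit)) p$count[hit] else 0L
}

#' Vertex-edge incidences of a molecular graph
#'
#' Every edge `uv` contributes two incidences: `(d(u), d(uv))` and
#' `(d(v), d(uv))` where `d(uv) = d(u) + d(v) - 2`.  Descriptor sums over
#' this list need no partition step, which makes it the independent
#' oracle path used to cross-check the partition-based computation.
#'
#' @param g a `molecular_graph`.
#' @return a data frame with columns `vertex_degree` and `edge_degree`
#'   and exactly `2 * n_edges(g)` rows.
#' @export
incidences <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- degrees(g)
  du <- unname(d[g$edges[, 1L]])
  dv <- unname(d[g$edges[, 2L]])
  e <- edge_degree(du, dv)
  data.frame(vertex_degree = c(rbind(du, dv)),
             edge_degree = c(rbind(e, e)))
}

#' Read / write an edge partition as CSV
#'
#' The CSV has columns `a`, `b`, `edge_degree`, `count` -- one row per
#' degree-pair class, mirroring the row layout of published partition
#' tables.
#'
#' @param p an `edge_partition`.
#' @param path file path.
#' @return `write_partition_csv()`: `path` invisibly;
#'   `read_partition_csv()`: an `edge_partition`.
#' @export
write_partition_csv <- function(p, path) {
  stopifnot(inherits(p, "edge_partition"))
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  as_edge_partition(utils::read.csv(path))
}
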