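#' K-Banhatti descriptors of an edge partition
#'
#' The five K-Banhatti descriptors sum a function of the vertex degree
#' `d(v)` and edge degree `d(e) = d(u) + d(v) - 2` over all vertex-edge
#' incidences of the graph:
#'
#' * `B1  = sum (d(v) + d(e))` -- first K-Banhatti index,
#' * `B2  = sum  d(v) * d(e)`  -- second K-Banhatti index,
#' * `HB1 = sum (d(v) + d(e))^2` -- first hyper K-Banhatti index,
#' * `HB2 = sum (d(v) * d(e))^2` -- second hyper K-Banhatti index,
#' * `Hb  = sum 2 / (d(v) + d(e))` -- harmonic K-Banhatti index.
#'
#' On an edge partition the sums collapse to class-wise closed forms:
#' a class `(a, b)` with multiplicity `m` and `e = a + b - 2`
#' contributes, e.g., `m * ((a + e) + (b + e))` to `B1`.  The first four
#' descriptors are non-negative integers for integer degrees; `Hb` is a
#' positive rational, computed at full floating precision (any 4-decimal
#' presentation is a formatting concern only).
#'
#' @param p an `edge_partition`, or a `molecular_graph` (partitioned
#'   first).
#' @return a single numeric value.
#' @examples
#' p3 <- molecular_graph(rbind(c(1, 2), c(2, 3)))
#' banhatti_b1(p3)  # 10
#' @seealso [descriptors_from_graph()] for all five at once,
#'   [oracle_descriptors()] for the incidence-sum cross-check.
#' @export
banhatti_b1 <- function(p) {
  p <- .as_partition(p)
  e <- p$edge_degree
  sum(p$count * ((p$a + e) + (p$b + e)))
}

#' @rdname banhatti_b1
#' @export
banhatti_b2 <- function(p) {
  p <- .as_partition(p)
  e <- p$edge_degree
  sum(p$count * (p$a * e + p$b * e))
}

#' @rdname banhatti_b1
#' @export
banhatti_hb1 <- function(p) {
  p <- .as_partition(p)
  e <- p$edge_degree
  sum(p$count * ((p$a + e)^2 + (p$b + e)^2))
}

#' @rdname banhatti_b1
#' @export
banhatti_hb2 <- function(p) {
  p <- .as_partition(p)
  e <- p$edge_degree
  sum(p$count * ((p$a * e)^2 + (p$b * e)^2))
}

#' @rdname banhatti_b1
#' @export
banhatti_hb <- function(p) {
  p <- .as_partition(p)
  e <- p$edge_degree
  sum(p$count * (2 / (p$a + e) + 2 / (p$b + e)))
}

.as_partition <- function(p) {
  if (inherits(p, "molecular_graph")) return(edge_partition(p))
  if (!inherits(p, "edge_partition")) {
    stop("expected an 'edge_partition' or 'molecular_graph'")
  }
  p
}

#' All five K-Banhatti descriptors of a graph or partition
#'
#' @param g a `molecular_graph` or `edge_partition`.
#' @return a named numeric vector `c(B1, B2, HB1, HB2, Hb)`.
#' @examples
#' descriptors_from_graph(molecular_graph(rbind(c(1, 2))))
#' # B1 = 2, B2 = 0, HB1 = 2, HB2 = 0, Hb = 4
#' @export
descriptors_from_graph <- function(g) {
  p <- .as_partition(g)
  c(B1 = banhatti_b1(p), B2 = banhatti_b2(p),
    HB1 = banhatti_hb1(p), HB2 = banhatti_hb2(p),
    Hb = banhatti_hb(p))
}

#' Incidence-sum oracle for the K-Banhatti descriptors
#'
#' Computes each descriptor by direct summation over the vertex-edge
#' incidence list, with no partition step.  This path is deliberately
#' independent of [edge_partition()] so the two can cross-check each
#' other: they must agree exactly on the integer descriptors and to
#' floating-point accuracy on `Hb` for every graph.
#'
#' @param g a `molecular_graph`.
#' @return a named numeric vector `c(B1, B2, HB1, HB2, Hb)`.
#' @export
oracle_descriptors <- function(g) {
  inc <- incidences(g)
  d <- inc$vertex_degree
  e <- inc$edge_degree
  c(B1 = sum(d + e), B2 = sum(d * e),
    HB1 = sum((d + e)^2), HB2 = sum((d * e)^2),
    Hb = sum(2 / (d + e)))
}

#' Descriptor table for a batch of molecules
#'
#' @param graphs a list of `molecular_graph` objects (e.g.
#'   [drug_graphs()]), or a single graph.
#' @return a tibble with columns `drug`, `B1`, `B2`, `HB1`, `HB2`, `Hb`,
#'   one row per molecule.
#' @examples
#' descriptor_table(drug_graphs("Linezolid"))
#' @export
descriptor_table <- function(graphs) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  if (length(graphs) == 0L) {
    return(tibble::tibble(drug = character(), B1 = numeric(),
                          B2 = numeric(), HB1 = numeric(),
                          HB2 = numeric(), Hb = numeric()))
  }
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    dv <- descriptors_from_graph(g)
    nm <- if (!is.null(g$name)) g$name else names(graphs)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- sprintf("molecule_%d", i)
    tibble::tibble(drug = nm, B1 = dv[["B1"]], B2 = dv[["B2"]],
                   HB1 = dv[["HB1"]], HB2 = dv[["HB2"]], Hb = dv[["Hb"]])
  })
  do.call(rbind, rows)
}
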