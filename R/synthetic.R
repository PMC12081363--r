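#' Molecule-like random graph
#'
#' Generates a connected simple graph with all degrees in
#' `[1, max_degree]`, shaped like a drug skeleton: a random spanning
#' tree grown under the degree cap, then ring-closing edges added
#' between non-adjacent vertices with residual degree.  Ring closures
#' are capped at `floor(n/4)` so the cyclomatic number stays
#' molecule-like (drug skeletons carry a handful of rings, not dense
#' cores).
#'
#' All randomness is governed by the single `seed` argument; the global
#' random state is left untouched and identical inputs give identical
#' graphs.
#'
#' @param n_vertices number of vertices, at least 2.
#' @param max_degree degree cap; 4 matches carbon-skeleton valence.
#' @param ring_bias probability of accepting each candidate ring
#'   closure.
#' @param seed integer seed.
#' @param name optional name for the generated graph.
#' @return a `molecular_graph`.
#' @examples
#' g <- random_molecular_graph(20, seed = 1)
#' max(degrees(g)) <= 4
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4,
                                   ring_bias = 0.15, seed = 1,
                                   name = NULL) {
  if (n_vertices < 2) stop("'n_vertices' must be at least 2")
  if (max_degree < 1) stop("'max_degree' must be positive")
  if (max_degree == 1 && n_vertices > 2) {
    stop("infeasible: a connected graph on > 2 vertices needs max_degree >= 2")
  }
  withr::with_seed(as.integer(seed), {
    n <- as.integer(n_vertices)
    deg <- integer(n)
    edges <- matrix(integer(), ncol = 2)
    order <- sample.int(n)
    # spanning tree: attach each new vertex to a random open earlier one
    for (i in 2:n) {
      open <- order[seq_len(i - 1)]
      open <- open[deg[open] < max_degree]
      if (length(open) == 0L) {
        stop("infeasible spec: degree cap too tight for a spanning tree")
      }
      anchor <- if (length(open) == 1L) open else sample(open, 1L)
      v <- order[i]
      edges <- rbind(edges, c(min(anchor, v), max(anchor, v)))
      deg[anchor] <- deg[anchor] + 1L
      deg[v] <- deg[v] + 1L
    }
    # ring closures, capped to keep the cyclomatic number molecule-like
    max_rings <- floor(n / 4)
    if (max_rings > 0 && ring_bias > 0) {
      adj <- paste(edges[, 1], edges[, 2])
      cand <- which(deg < max_degree)
      if (length(cand) >= 2L) {
        pairs <- utils::combn(cand, 2L)
        pairs <- pairs[, sample.int(ncol(pairs)), drop = FALSE]
        added <- 0L
        for (j in seq_len(ncol(pairs))) {
          if (added >= max_rings) break
          u <- pairs[1, j]; v <- pairs[2, j]
          if (deg[u] >= max_degree || deg[v] >= max_degree) next
          key <- paste(min(u, v), max(u, v))
          if (key %in% adj) next
          if (stats::runif(1) <= ring_bias) {
            edges <- rbind(edges, c(min(u, v), max(u, v)))
            adj <- c(adj, key)
            deg[u] <- deg[u] + 1L
            deg[v] <- deg[v] + 1L
            added <- added + 1L
          }
        }
      }
    }
    molecular_graph(edges, name = name)
  })
}

#' Synthetic descriptor-property table with a planted model
#'
#' Emulates the statistical shape of the drug panel: descriptors are
#' computed from random molecule-like graphs, and the response is a
#' planted polynomial in one chosen descriptor plus Gaussian noise.
#' Optionally a stated fraction of response cells is masked missing, as
#' in real property tables.  With `noise_sd = 0` a polynomial refit of
#' the same degree recovers the planted coefficients exactly (up to
#' floating-point error), which anchors the parameter-recovery tests.
#'
#' @param n_drugs number of synthetic molecules.
#' @param planted_degree degree of the planted polynomial, 1 to 4.
#' @param coefficients planted coefficients, highest power first,
#'   length `planted_degree`.
#' @param intercept planted intercept.
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   response.
#' @param descriptor which descriptor drives the response.
#' @param missing_rate fraction of response cells masked missing.
#' @param n_vertices_range inclusive range of graph sizes to draw from.
#' @param max_degree,ring_bias passed to [random_molecular_graph()].
#' @param seed integer seed governing all randomness.
#' @return a tibble with columns `drug`, `B1..Hb` and `property`;
#'   attribute `planted` records the generating model.
#' @export
synthetic_qspr_table <- function(n_drugs, planted_degree = 1,
                                 coefficients = 1, intercept = 0,
                                 noise_sd = 0, descriptor = "B1",
                                 missing_rate = 0,
                                 n_vertices_range = c(10, 60),
                                 max_degree = 4, ring_bias = 0.15,
                                 seed = 1) {
  if (!planted_degree %in% 1:4) stop("'planted_degree' must be 1..4")
  if (length(coefficients) != planted_degree) {
    stop("need exactly 'planted_degree' coefficients (highest power first)")
  }
  withr::with_seed(as.integer(seed), {
    sizes <- sample(seq(n_vertices_range[1], n_vertices_range[2]),
                    n_drugs, replace = TRUE)
    graph_seeds <- sample.int(.Machine$integer.max - 1L, n_drugs)
    noise <- stats::rnorm(n_drugs, sd = noise_sd)
    mask <- stats::runif(n_drugs) < missing_rate
  })
  graphs <- lapply(seq_len(n_drugs), function(i) {
    random_molecular_graph(sizes[i], max_degree = max_degree,
                           ring_bias = ring_bias, seed = graph_seeds[i],
                           name = sprintf("synthetic_%03d", i))
  })
  tab <- descriptor_table(graphs)
  x <- tab[[descriptor]]
  co <- c(coefficients, intercept)
  y <- vapply(x, function(xi) sum(co * xi^(planted_degree:0)), numeric(1))
  y <- y + noise
  y[mask] <- NA_real_
  tab$property <- y
  attr(tab, "planted") <- list(degree = planted_degree,
                               coefficients = coefficients,
                               intercept = intercept,
                               descriptor = descriptor,
                               noise_sd = noise_sd,
                               missing_rate = missing_rate)
  tab
}
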