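# small graphs used across tests
path_graph <- function(n) {
  molecular_graph(cbind(seq_len(n - 1), 2:n))
}

cycle_graph <- function(n) {
  molecular_graph(rbind(cbind(seq_len(n - 1), 2:n), c(n, 1)))
}

# disjoint union with relabelled vertices; disconnected by construction
disjoint_union <- function(g1, g2) {
  e1 <- cbind(paste0("a", g1$edges[, 1]), paste0("a", g1$edges[, 2]))
  e2 <- cbind(paste0("b", g2$edges[, 1]), paste0("b", g2$edges[, 2]))
  suppressWarnings(molecular_graph(rbind(e1, e2)))
}

# reconstruct partition class counts from the incidence list: the
# partner degree of an incidence (d, e) is e + 2 - d
partition_from_incidences <- function(g) {
  inc <- incidences(g)
  partner <- inc$edge_degree + 2L - inc$vertex_degree
  lo <- pmin(inc$vertex_degree, partner)
  hi <- pmax(inc$vertex_degree, partner)
  agg <- stats::aggregate(list(n = rep(1L, length(lo))),
                          list(a = lo, b = hi), sum)
  agg$count <- agg$n / 2L
  agg[order(agg$a, agg$b), c("a", "b", "count")]
}
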