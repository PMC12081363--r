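#' Construct a hydrogen-suppressed molecular graph
#'
#' A molecular graph is the simple undirected skeleton of a molecule:
#' vertices are heavy atoms, edges are bonds.  Hydrogens are never
#' vertices and bond order is ignored (a double or aromatic bond
#' contributes one edge), so every degree-based descriptor depends only
#' on the heavy-atom connectivity.
#'
#' Vertex identifiers are opaque labels; no element typing is stored.
#' The constructor rejects self-loops, duplicate edges, edges whose
#' endpoints are not declared vertices and isolated vertices (an atom
#' with no bond cannot occur in a connected skeleton).  Disconnected
#' graphs are admitted with a warning, so that salts or counter-ions do
#' not hard-fail, but all packaged drug fixtures are connected.
#'
#' @param edges a two-column matrix or data frame of edge endpoints, or a
#'   list of length-2 vectors.
#' @param vertices optional vector of vertex labels; inferred from the
#'   edges when omitted.  Declaring a vertex that appears in no edge is
#'   an error.
#' @param name optional molecule name.
#' @param formula optional molecular-formula string (metadata only).
#' @return an object of class `molecular_graph` with elements `name`,
#'   `formula`, `vertices` (character) and `edges` (two-column character
#'   matrix, one row per edge).
#' @examples
#' g <- molecular_graph(rbind(c(1, 2), c(2, 3)))
#' degrees(g)
#' @export
molecular_graph <- function(edges, vertices = NULL, name = NULL,
                            formula = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2L) stop("each edge must have exactly two endpoints")
      as.character(e)
    }))
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  mode(edges) <- "character"
  if (anyNA(edges)) stop("edge endpoints must not be missing")

  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- which(edges[, 1L] == edges[, 2L])[1L]
    stop(sprintf("self-loop at vertex '%s' (edge %d)", edges[bad, 1L], bad))
  }
  # canonical within-edge order so duplicates are order-insensitive
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    bad <- edges[which(duplicated(key))[1L], ]
    stop(sprintf("duplicate edge (%s, %s)", bad[1L], bad[2L]))
  }

  seen <- unique(as.vector(edges))
  if (is.null(vertices)) {
    vertices <- sort(seen)
  } else {
    vertices <- as.character(vertices)
    if (anyDuplicated(vertices)) stop("duplicate vertex labels")
    missing_v <- setdiff(seen, vertices)
    if (length(missing_v) > 0L) {
      stop(sprintf("edge endpoint '%s' is not a declared vertex",
                   missing_v[1L]))
    }
    isolated <- setdiff(vertices, seen)
    if (length(isolated) > 0L) {
      stop(sprintf("vertex '%s' has degree 0 (isolated atom)", isolated[1L]))
    }
  }
  if (length(vertices) < 2L || nrow(edges) < 1L) {
    stop("a molecular graph needs at least two vertices joined by an edge")
  }

  g <- structure(
    list(name = name, formula = formula, vertices = vertices, edges = edges),
    class = "molecular_graph"
  )
  if (!is_connected(g)) {
    warning(sprintf("graph%s is not connected",
                    if (is.null(name)) "" else paste0(" '", name, "'")))
  }
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph%s> %d vertices, %d edges, degrees %d..%d\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              n_vertices(x), n_edges(x),
              min(degrees(x)), max(degrees(x))))
  invisible(x)
}

#' Number of vertices / edges of a molecular graph
#' @param g a `molecular_graph`.
#' @return an integer count.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' Vertex degrees
#'
#' The degree of a vertex is the number of edges incident to it, i.e.
#' the number of neighbouring heavy atoms.
#'
#' @param g a `molecular_graph`.
#' @param v a single vertex label.
#' @return `vertex_degree()`: the degree of `v`; `degrees()`: a named
#'   integer vector over all vertices of `g`.
#' @examples
#' p3 <- molecular_graph(rbind(c(1, 2), c(2, 3)))
#' vertex_degree(p3, "2")
#' @export
vertex_degree <- function(g, v) {
  v <- as.character(v)
  if (length(v) != 1L) stop("'v' must be a single vertex label")
  if (!v %in% g$vertices) stop(sprintf("unknown vertex '%s'", v))
  sum(g$edges == v)
}

#' @rdname vertex_degree
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- integer(n_vertices(g))
  names(d) <- g$vertices
  tab <- table(factor(as.vector(g$edges), levels = g$vertices))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Is the graph connected?
#' @param g a `molecular_graph`.
#' @return `TRUE` if every vertex is reachable from every other.
#' @export
is_connected <- function(g) {
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  igraph::is_connected(ig)
}

#' Read a molecular graph from a JSON fixture
#'
#' The fixture format is one JSON document per molecule with fields
#' `name`, `formula`, `vertices` (list of labels) and `edges` (list of
#' two-element lists).  Files written by [write_graph_json()] load back
#' to the same vertex and edge sets.
#'
#' @param path path to a JSON fixture file.
#' @return a validated `molecular_graph`.
#' @seealso [read_edgelist()] for the plain two-column format,
#'   [drug_graphs()] for the packaged fixtures.
#' @export
read_graph_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such fixture file: '%s'", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("malformed JSON in '%s': %s",
                                 path, conditionMessage(e)))
                  })
  for (field in c("vertices", "edges")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("fixture '%s' lacks required field '%s'", path, field))
    }
  }
  edges <- doc$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  molecular_graph(edges, vertices = doc$vertices,
                  name = doc$name, formula = doc$formula)
}

#' Write a molecular graph to a JSON fixture
#' @param g a `molecular_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "molecular_graph"))
  doc <- list(name = g$name, formula = g$formula,
              vertices = g$vertices,
              edges = unname(split(g$edges, row(g$edges))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a molecular graph from a plain edge list
#'
#' Each non-blank, non-comment line holds two whitespace-separated
#' vertex labels; vertices are inferred from the edges.
#'
#' @param path path to the edge-list file.
#' @param name optional molecule name.
#' @return a validated `molecular_graph`.
#' @export
read_edgelist <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such edge-list file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge record at line %d of '%s': '%s'",
                 keep[bad[1L]], path, lines[keep[bad[1L]]]))
  }
  molecular_graph(do.call(rbind, parts), name = name)
}

#' Packaged drug graph fixtures
#'
#' Loads the hydrogen-suppressed skeletons of the 20 anti-pneumonia
#' drugs shipped with the package.  Eighteen are encoded from standard
#' published structures.  The Unasyn and Avibactam fixtures are instead
#' synthetic realizations of the published edge partitions (which differ
#' from the real skeletons by one edge each) so that partition-level
#' reference values are reproduced exactly; their files are suffixed
#' `_synthetic` and carry a `synthetic` flag.
#'
#' @param names optional character vector of drug names (case
#'   insensitive); defaults to all fixtures.
#' @return a named list of `molecular_graph` objects.
#' @examples
#' g <- drug_graphs("Linezolid")[[1]]
#' n_edges(g)
#' @export
drug_graphs <- function(names = NULL) {
  dir <- system.file("extdata", "graphs", package = "kbanhatti")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  graphs <- lapply(files, read_graph_json)
  names(graphs) <- vapply(graphs, function(g) g$name, character(1))
  if (!is.null(names)) {
    idx <- match(tolower(names), tolower(names(graphs)))
    if (anyNA(idx)) {
      stop(sprintf("no packaged fixture for drug '%s'",
                   names[which(is.na(idx))[1L]]))
    }
    graphs <- graphs[idx]
  }
  graphs
}

#' Build a molecular graph from a SMILES string
#'
#' Optional adapter around the ChemmineR/OpenBabel toolchain: the SMILES
#' is parsed and its heavy-atom skeleton (hydrogens suppressed, bond
#' order dropped) is returned.  The core package has no chemistry-toolkit
#' dependency; this helper is only available when ChemmineR is installed.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @return a `molecular_graph`.
#' @export
graph_from_smiles <- function(smiles, name = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("graph_from_smiles() needs the ChemmineR package")
  }
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  bonds <- ChemmineR::bondblock(sdf)
  molecular_graph(cbind(bonds[, 1L], bonds[, 2L]), name = name)
}
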