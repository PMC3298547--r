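#' Construct a directed network
#'
#' The basic container used throughout the package: a set of vertex
#' identifiers plus a set of labelled directed edges. Edge labels carry
#' interaction semantics (e.g. activation/inhibition) as metadata only; all
#' topological computations are label-blind and count parallel edges with
#' different labels once. Self-loops are rejected: the pair-connectivity
#' semantics used downstream range over ordered pairs of distinct vertices,
#' for which a self-loop is inert.
#'
#' @param vertices character vector of vertex identifiers.
#' @param edges data frame with columns `from`, `to` and optionally `label`;
#'   may be `NULL` or empty for an edgeless network.
#' @param name free-text network name.
#' @return an object of class `pkn_network` with elements `vertices`
#'   (sorted character vector), `edges` (data frame `from`, `to`, `label`)
#'   and `name`.
#' @export
pkn_network <- function(vertices = character(), edges = NULL, name = "") {
  vertices <- sort(unique(as.character(vertices)))
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges must have columns 'from' and 'to'")
    if (is.null(edges$label)) edges$label <- ""
    edges <- edges[, c("from", "to", "label")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$label <- as.character(edges$label)
    loops <- edges$from == edges$to
    if (any(loops)) edges <- edges[!loops, , drop = FALSE]
    edges <- unique(edges)
    missing <- setdiff(c(edges$from, edges$to), vertices)
    if (length(missing))
      stop("edge endpoint(s) not in vertex set: ",
           paste(utils::head(missing, 5), collapse = ", "))
    edges <- edges[order(edges$from, edges$to, edges$label), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(vertices = vertices, edges = edges, name = name),
            class = "pkn_network")
}

#' @exportS3Method base::print
print.pkn_network <- function(x, ...) {
  cat(sprintf("<pkn_network%s> %d vertices, %d edges (%d distinct pairs)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$vertices), nrow(x$edges), n_edges(x)))
  invisible(x)
}

#' Number of distinct directed vertex pairs joined by an edge
#'
#' Parallel edges that differ only in label count once.
#' @param net a `pkn_network`.
#' @return integer edge count as used by all topological analyses.
#' @export
n_edges <- function(net) {
  nrow(unique(net$edges[, c("from", "to")]))
}

#' Convert to an igraph object (label-blind)
#'
#' @param net a `pkn_network`.
#' @return a directed `igraph` graph with one edge per distinct ordered pair
#'   and vertices in sorted order (so downstream outputs are deterministic).
#' @export
as_igraph <- function(net) {
  ed <- unique(net$edges[, c("from", "to")])
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = net$vertices))
}

#' Read a directed network from SIF or edge-list format
#'
#' SIF lines are `source<TAB>label<TAB>target[<TAB>target2 ...]`; edge-list
#' lines are `source<TAB>target`. Fields may be separated by any whitespace.
#' Lines starting with `#` are comments. A line with a single token declares
#' an isolated (orphan) vertex in either format, which keeps the
#' write/read round trip exact for networks with orphans. Duplicate edges are
#' collapsed and self-loops dropped with a message.
#'
#' @param path input file path.
#' @param format `"sif"` or `"edgelist"`.
#' @return a `pkn_network`.
#' @export
read_network <- function(path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  verts <- character()
  from <- to <- lab <- character()
  n_loops <- 0L
  for (i in idx) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) == 1L) { verts <- c(verts, f); next }
    if (format == "sif") {
      if (length(f) < 3L)
        stop(sprintf("malformed SIF line %d: expected >= 3 fields", i))
      src <- f[1]; l <- f[2]; tgt <- f[-(1:2)]
    } else {
      if (length(f) < 2L)
        stop(sprintf("malformed edge-list line %d: expected >= 2 fields", i))
      src <- f[1]; l <- ""; tgt <- f[2]
    }
    for (tg in tgt) {
      verts <- c(verts, src, tg)
      if (src == tg) { n_loops <- n_loops + 1L; next }
      from <- c(from, src); to <- c(to, tg); lab <- c(lab, l)
    }
  }
  if (n_loops > 0L)
    message(sprintf("read_network: dropped %d self-loop line(s)", n_loops))
  pkn_network(verts,
              data.frame(from = from, to = to, label = lab,
                         stringsAsFactors = FALSE),
              name = basename(path))
}

#' Write a directed network to SIF or edge-list format
#'
#' Edges are emitted in lexicographic (from, to, label) order and orphan
#' vertices as trailing single-token lines, so output is byte-reproducible
#' and `read_network()` round-trips exactly.
#'
#' @param net a `pkn_network`.
#' @param path output file path.
#' @param format `"sif"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  ed <- net$edges
  lines <- if (nrow(ed) == 0L) character() else if (format == "sif") {
    lb <- ifelse(nzchar(ed$label), ed$label, "edge")
    paste(ed$from, lb, ed$to, sep = "\t")
  } else {
    paste(unique(ed[, c("from", "to")])$from,
          unique(ed[, c("from", "to")])$to, sep = "\t")
  }
  orphans <- setdiff(net$vertices, c(ed$from, ed$to))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(lines, sort(orphans)), con)
  invisible(path)
}

#' Weakly connected components
#'
#' Components of the underlying undirected graph; orphan vertices each form
#' a singleton component.
#'
#' @param net a `pkn_network`.
#' @return list with `membership` (named integer vector; components numbered
#'   by their lexicographically smallest member), `sizes` and `n`.
#' @export
weak_components <- function(net) {
  if (length(net$vertices) == 0L)
    return(list(membership = stats::setNames(integer(), character()),
                sizes = integer(), n = 0L))
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "weak")
  mem <- comp$membership
  # renumber components deterministically by smallest member name
  first <- tapply(names(mem), mem, min)
  newid <- stats::setNames(rank(first, ties.method = "first"), names(first))
  mem2 <- stats::setNames(as.integer(newid[as.character(mem)]), names(mem))
  mem2 <- mem2[net$vertices]
  list(membership = mem2,
       sizes = as.integer(table(mem2)),
       n = as.integer(comp$no))
}

#' Remove orphan (edgeless) vertices
#'
#' Removing a vertex without incident edges cannot change connectivity, so
#' topological analyses operate on the pruned network; enrichment universes
#' keep the orphans.
#'
#' @param net a `pkn_network`.
#' @return a `pkn_network` containing exactly the vertices with degree >= 1.
#' @export
remove_orphans <- function(net) {
  keep <- intersect(net$vertices, c(net$edges$from, net$edges$to))
  pkn_network(keep, net$edges, name = net$name)
}

#' Induced subnetwork on a vertex subset
#'
#' @param net a `pkn_network`.
#' @param vertices character vector, must be a subset of `net$vertices`.
#' @return the induced `pkn_network`: the given vertices plus every edge of
#'   `net` with both endpoints in the set.
#' @export
induced_subnetwork <- function(net, vertices) {
  vertices <- unique(as.character(vertices))
  bad <- setdiff(vertices, net$vertices)
  if (length(bad))
    stop("vertex not in network: ", paste(utils::head(bad, 5), collapse = ", "))
  ed <- net$edges[net$edges$from %in% vertices & net$edges$to %in% vertices, ,
                  drop = FALSE]
  pkn_network(vertices, ed, name = net$name)
}

# sorted adjacency lists used by the extension and sampling code
adjacency_lists <- function(net, mode = c("all", "out", "in")) {
  mode <- match.arg(mode)
  ed <- unique(net$edges[, c("from", "to")])
  res <- stats::setNames(vector("list", length(net$vertices)), net$vertices)
  add <- function(res, key, val) {
    s <- split(val, key)
    res[names(s)] <- Map(c, res[names(s)], s)
    res
  }
  if (mode %in% c("out", "all")) res <- add(res, ed$from, ed$to)
  if (mode %in% c("in", "all")) res <- add(res, ed$to, ed$from)
  lapply(res, function(x) sort(unique(x)))
}
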