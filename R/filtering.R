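#' Read a tag-count expression table
#'
#' One condition per file: a tab-separated table with columns `source_id`
#' (expression-platform identifier, e.g. a SAGE tag) and `count`.
#'
#' @param path input TSV path.
#' @param condition condition name; defaults to the file name.
#' @return a `pkn_expression` object: list with `condition` and `counts`
#'   (named numeric vector, one entry per source id).
#' @export
read_expression <- function(path, condition = basename(path)) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("source_id", "count") %in% names(d)))
    stop("expression table needs columns 'source_id' and 'count'")
  pkn_expression(stats::setNames(as.numeric(d$count), d$source_id), condition)
}

#' Construct an expression set from a named count vector
#' @param counts named numeric vector of tag counts.
#' @param condition condition name.
#' @return a `pkn_expression` object.
#' @export
pkn_expression <- function(counts, condition = "") {
  stopifnot(!is.null(names(counts)))
  structure(list(condition = condition, counts = counts),
            class = "pkn_expression")
}

#' Read an identifier mapping table
#'
#' Many-to-many map from expression-platform identifiers to reference-network
#' vertex identifiers; 2-column TSV (`source_id`, `vertex_id`).
#'
#' @param path input TSV path.
#' @return data frame of class `pkn_idmap` with columns `source_id`,
#'   `vertex_id`.
#' @export
read_idmap <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("source_id", "vertex_id") %in% names(d)))
    stop("identifier map needs columns 'source_id' and 'vertex_id'")
  pkn_idmap(d$source_id, d$vertex_id)
}

#' @rdname read_idmap
#' @param source_id,vertex_id parallel character vectors of mapping pairs.
#' @export
pkn_idmap <- function(source_id, vertex_id) {
  d <- unique(data.frame(source_id = as.character(source_id),
                         vertex_id = as.character(vertex_id),
                         stringsAsFactors = FALSE))
  class(d) <- c("pkn_idmap", "data.frame")
  d
}

#' Map detected genes onto the reference network
#'
#' A source id is "detected" when its tag count reaches `threshold`
#' (presence/absence semantics; the default calls a gene present with a
#' single tag). A reference vertex is detected iff at least one of its
#' source ids is detected. Unmapped source ids and ids mapping only outside
#' the reference are tallied, never errors.
#'
#' @param expr a `pkn_expression`.
#' @param idmap a `pkn_idmap`.
#' @param ref the reference `pkn_network`.
#' @param threshold minimum tag count for detection (default 1).
#' @return a `pkn_detection`: list with `condition`, `detected` (sorted
#'   vertex ids, subset of `ref$vertices`), `n_unmapped`, `n_outside`.
#' @export
map_detection <- function(expr, idmap, ref, threshold = 1) {
  det_src <- names(expr$counts)[expr$counts >= threshold]
  hit <- idmap[idmap$source_id %in% det_src, , drop = FALSE]
  n_unmapped <- sum(!det_src %in% idmap$source_id)
  mapped <- unique(hit$vertex_id)
  inside <- intersect(mapped, ref$vertices)
  # source ids all of whose targets fall outside the reference
  out_src <- setdiff(unique(hit$source_id[!hit$vertex_id %in% ref$vertices]),
                     unique(hit$source_id[hit$vertex_id %in% ref$vertices]))
  pkn_detection(inside, expr$condition,
                n_unmapped = n_unmapped, n_outside = length(out_src))
}

#' @rdname map_detection
#' @param detected character vector of detected vertex ids.
#' @param condition condition name.
#' @param n_unmapped,n_outside bookkeeping counts.
#' @export
pkn_detection <- function(detected, condition = "",
                          n_unmapped = 0L, n_outside = 0L) {
  structure(list(condition = condition,
                 detected = sort(unique(as.character(detected))),
                 n_unmapped = as.integer(n_unmapped),
                 n_outside = as.integer(n_outside)),
            class = "pkn_detection")
}

#' Set algebra on two condition detection sets
#'
#' The analysis network defaults to the union of the normal and disease
#' detection sets (keeping silenced and induced genes alike and minimising
#' fragmentation); intersection and symmetric difference support
#' condition-contrast runs.
#'
#' @param normal,disease `pkn_detection` objects over the same reference.
#' @return list of `pkn_detection`s: `union`, `intersection`,
#'   `symmetric_difference`.
#' @export
combine_conditions <- function(normal, disease) {
  u <- union(normal$detected, disease$detected)
  i <- intersect(normal$detected, disease$detected)
  s <- setdiff(u, i)
  list(union = pkn_detection(u, "union"),
       intersection = pkn_detection(i, "intersection"),
       symmetric_difference = pkn_detection(s, "symmetric_difference"))
}

#' Strictly filter the reference network onto a detection set
#'
#' The strictly filtered network is the induced subgraph of the reference on
#' the detected vertices: only vertices mapped to detectable genes are kept,
#' together with every reference edge between them.
#'
#' @param ref the reference `pkn_network`.
#' @param det a `pkn_detection` or character vector of vertex ids
#'   (must be a subset of `ref$vertices`).
#' @return the strict `pkn_network`.
#' @export
strict_filter <- function(ref, det) {
  v <- if (inherits(det, "pkn_detection")) det$detected else as.character(det)
  net <- induced_subnetwork(ref, v)
  net$name <- paste0(ref$name, " [strict]")
  net
}

#' k-fold neighborhood extension of a vertex set
#'
#' One extension step adds every in- and out-neighbor of the current set;
#' applying it once to the strict vertex set gives the 1-extended network's
#' vertices, twice gives the 2-neighborhood. `k = 0` returns the seed. The
#' k-extended network itself is `induced_subnetwork(ref, extend(...))`, which
#' draws all reference edges between the chosen vertices.
#'
#' @param ref the reference `pkn_network`.
#' @param seed character vector of seed vertices (or `pkn_detection`).
#' @param k number of extension steps (non-negative integer).
#' @return sorted character vector of vertices.
#' @export
extend <- function(ref, seed, k = 1) {
  if (inherits(seed, "pkn_detection")) seed <- seed$detected
  seed <- unique(as.character(seed))
  bad <- setdiff(seed, ref$vertices)
  if (length(bad))
    stop("seed vertex not in reference: ",
         paste(utils::head(bad, 5), collapse = ", "))
  stopifnot(k >= 0)
  if (k == 0 || length(seed) == 0L) return(sort(seed))
  ed <- unique(ref$edges[, c("from", "to")])
  cur <- seed
  for (step in seq_len(k)) {
    nb <- c(ed$to[ed$from %in% cur], ed$from[ed$to %in% cur])
    nxt <- union(cur, nb)
    if (length(nxt) == length(cur)) break
    cur <- nxt
  }
  sort(cur)
}

#' Extended filtering of the reference network
#'
#' Convenience wrapper: induced subgraph on `extend(ref, seed, k)`.
#'
#' @inheritParams extend
#' @return the k-extended `pkn_network`.
#' @export
extended_filter <- function(ref, seed, k = 1) {
  net <- induced_subnetwork(ref, extend(ref, seed, k))
  net$name <- paste0(ref$name, sprintf(" [%d-extended]", k))
  net
}

#' Write a detection report
#'
#' @param det a `pkn_detection`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(det, path) {
  d <- data.frame(vertex = det$detected, status = "detected",
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
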