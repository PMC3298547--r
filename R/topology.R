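#' Pairwise disconnectivity index
#'
#' Scores every vertex by the fraction of initially connected ordered vertex
#' pairs that become disconnected when the vertex is removed — a non-local
#' bottleneck measure. For vertex `v`, with `C` the set of ordered pairs
#' `(s, t)`, `s != t`, connected by a directed path: `N0(v)` counts the
#' pairs of `C` not involving `v` (mediator convention, the default),
#' `N_minus(v)` the connected ordered pairs after deleting `v`, and
#' `Dis(v) = (N0(v) - N_minus(v)) / N0(v)` (0 when `N0(v) = 0`). The
#' all-pairs variant (`pairs = "all"`) keeps pairs involving `v` in the
#' denominator, in which case `N0(v) = |C|` and pairs through `v` count as
#' destroyed. Orphan vertices should be removed beforehand
#' ([remove_orphans()]): their score is identically zero.
#'
#' Reachability is recomputed from scratch for each removal (BFS from every
#' vertex), `O(V (V + E))` per removal, which is practical up to a few
#' thousand vertices. Vertices with zero in- or out-degree cannot mediate a
#' path and are short-circuited.
#'
#' @param net a `pkn_network` with at least 2 vertices.
#' @param pairs `"mediator"` (exclude pairs involving `v` from `N0`) or
#'   `"all"`.
#' @return data frame of class `pkn_dis` with columns `vertex`, `N0`,
#'   `N_minus`, `dis`, `dis_norm` (dis divided by the maximum, or all zero
#'   when the maximum is 0).
#' @export
dis_index <- function(net, pairs = c("mediator", "all")) {
  pairs <- match.arg(pairs)
  verts <- net$vertices
  nv <- length(verts)
  if (nv < 2L) stop("dis_index needs at least 2 vertices")
  g <- as_igraph(net)
  D <- igraph::distances(g, mode = "out")
  conn <- is.finite(D) & D > 0            # ordered connected pairs
  total <- sum(conn)
  out_cnt <- rowSums(conn)                # pairs (v, .)
  in_cnt <- colSums(conn)                 # pairs (., v)
  N0 <- if (pairs == "mediator") total - out_cnt - in_cnt else
    rep(total, nv)
  N_minus <- numeric(nv)
  for (i in seq_len(nv)) {
    if (in_cnt[i] == 0 || out_cnt[i] == 0) {
      # cannot mediate: pairs among the others are unchanged
      N_minus[i] <- total - out_cnt[i] - in_cnt[i]
      next
    }
    sub <- igraph::delete_vertices(g, i)
    Ds <- igraph::distances(sub, mode = "out")
    N_minus[i] <- sum(is.finite(Ds) & Ds > 0)
  }
  dis <- ifelse(N0 > 0, (N0 - N_minus) / N0, 0)
  mx <- max(dis)
  res <- data.frame(vertex = verts, N0 = as.numeric(N0),
                    N_minus = as.numeric(N_minus), dis = dis,
                    dis_norm = if (mx > 0) dis / mx else rep(0, nv),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("pkn_dis", "data.frame")
  res
}

#' Dis-increase between a filtered network and its reference
#'
#' For each vertex of the filtered network, the difference of max-normalised
#' Dis values, `Dis_f(v)/max_w Dis_f(w) - Dis_r(v)/max_w Dis_r(w)`,
#' measuring the increase (or decrease) of the vertex' topological influence
#' caused by filtering. Bounded in \[-1, 1\].
#'
#' @param filtered `pkn_dis` scores of the filtered network.
#' @param reference `pkn_dis` scores of the reference network; must contain
#'   every filtered vertex.
#' @return data frame with columns `vertex`, `dis_norm_filtered`,
#'   `dis_norm_reference`, `delta_dis`.
#' @export
dis_increase <- function(filtered, reference) {
  missing <- setdiff(filtered$vertex, reference$vertex)
  if (length(missing))
    stop("filtered vertex absent from reference scores: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (max(filtered$dis) <= 0 || max(reference$dis) <= 0)
    stop("max Dis is 0; normalisation undefined")
  ref_norm <- stats::setNames(reference$dis_norm, reference$vertex)
  res <- data.frame(vertex = filtered$vertex,
                    dis_norm_filtered = filtered$dis_norm,
                    dis_norm_reference = as.numeric(ref_norm[filtered$vertex]),
                    stringsAsFactors = FALSE)
  res$delta_dis <- res$dis_norm_filtered - res$dis_norm_reference
  rownames(res) <- NULL
  res
}

#' Bow-tie decomposition of a directed network
#'
#' Partitions the vertices into the largest strongly connected component
#' (LSCC; ties broken towards the component containing the lexicographically
#' smallest vertex), IN (vertices outside the LSCC that reach it), OUT
#' (vertices outside the LSCC reachable from it) and OTHER (the remainder,
#' including tendrils and disconnected parts). When every strong component
#' is a singleton the decomposition is degenerate: all vertices are labelled
#' OTHER and the result flagged.
#'
#' @param net a `pkn_network`.
#' @return list of class `pkn_bowtie`: `compartment` (named character
#'   vector, values in LSCC/IN/OUT/OTHER), `sizes`, `degenerate` flag.
#' @export
bowtie_decompose <- function(net) {
  verts <- net$vertices
  comp <- stats::setNames(rep("OTHER", length(verts)), verts)
  g <- as_igraph(net)
  sc <- igraph::components(g, mode = "strong")
  if (length(verts) == 0L || max(sc$csize) < 2L) {
    sizes <- c(LSCC = 0L, IN = 0L, OUT = 0L, OTHER = length(verts))
    return(structure(list(compartment = comp, sizes = sizes,
                          degenerate = TRUE), class = "pkn_bowtie"))
  }
  big <- which(sc$csize == max(sc$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(b)
      min(names(sc$membership)[sc$membership == b]), "")
    big <- big[order(firsts)[1]]
  }
  lscc <- names(sc$membership)[sc$membership == big]
  rep_v <- lscc[1]
  reach_in <- names(igraph::subcomponent(g, rep_v, mode = "in"))
  reach_out <- names(igraph::subcomponent(g, rep_v, mode = "out"))
  comp[lscc] <- "LSCC"
  comp[setdiff(reach_in, lscc)] <- "IN"
  comp[setdiff(reach_out, lscc)] <- "OUT"
  sizes <- vapply(c("LSCC", "IN", "OUT", "OTHER"),
                  function(x) sum(comp == x), 0L)
  structure(list(compartment = comp, sizes = sizes, degenerate = FALSE),
            class = "pkn_bowtie")
}

#' Per-vertex log fold-change of tag abundance
#'
#' Tag counts are aggregated per vertex via the identifier map, converted to
#' counts per million within each condition's library, and compared as
#' `log2((disease_cpm + c) / (normal_cpm + c))` with pseudocount `c` so the
#' value is finite even for condition-specific vertices. Library-size
#' normalisation makes the value invariant under sequencing depth.
#'
#' @param normal,disease `pkn_expression` objects.
#' @param idmap a `pkn_idmap` from tag ids to vertex ids.
#' @param c pseudocount (> 0, default 0.5, on the cpm scale).
#' @param direction `"disease_vs_normal"` (default) or `"normal_vs_disease"`.
#' @return data frame with columns `vertex`, `normal_cpm`, `disease_cpm`,
#'   `lfc`.
#' @export
log_fold_change <- function(normal, disease, idmap, c = 0.5,
                            direction = c("disease_vs_normal",
                                          "normal_vs_disease")) {
  direction <- match.arg(direction)
  stopifnot(c > 0)
  agg <- function(expr) {
    m <- idmap[idmap$source_id %in% names(expr$counts), , drop = FALSE]
    v <- tapply(expr$counts[m$source_id], m$vertex_id, sum)
    tot <- sum(expr$counts)
    if (tot <= 0) tot <- 1
    v * 1e6 / tot
  }
  ncpm <- agg(normal)
  dcpm <- agg(disease)
  verts <- sort(union(names(ncpm), names(dcpm)))
  nv <- ifelse(verts %in% names(ncpm), ncpm[verts], 0)
  dv <- ifelse(verts %in% names(dcpm), dcpm[verts], 0)
  lfc <- log2((dv + c) / (nv + c))
  if (direction == "normal_vs_disease") lfc <- -lfc
  data.frame(vertex = verts, normal_cpm = as.numeric(nv),
             disease_cpm = as.numeric(dv), lfc = as.numeric(lfc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classical (mean-centered) Levene test for equal variances
#'
#' Absolute deviations from the group means are compared by a one-way
#' ANOVA-type statistic: with `Z_ij = |Y_ij - mean(Y_i)|`,
#' `W = ((N - g)/(g - 1)) * sum n_i (Zbar_i - Zbar)^2 / sum (Z_ij - Zbar_i)^2`
#' referred to `F(g - 1, N - g)`. The mean-centered form suits symmetric,
#' moderate-tailed distributions such as log fold-changes.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `W`, `df1`, `df2`, `p`, `degenerate` (TRUE when the
#'   within-group deviations are constant and the statistic undefined, in
#'   which case `W` and `p` are `NA`).
#' @export
levene_test <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  g <- length(groups)
  Z <- lapply(groups, function(y) abs(y - mean(y)))
  n_i <- lengths(Z)
  N <- sum(n_i)
  zbar_i <- vapply(Z, mean, 0)
  zbar <- sum(unlist(Z)) / N
  num <- sum(n_i * (zbar_i - zbar)^2)
  den <- sum(vapply(seq_len(g), function(i) sum((Z[[i]] - zbar_i[i])^2), 0))
  if (den <= 0) {
    if (num <= 0)
      return(list(W = NA_real_, df1 = g - 1L, df2 = N - g, p = NA_real_,
                  degenerate = TRUE))
    return(list(W = Inf, df1 = g - 1L, df2 = N - g, p = 0,
                degenerate = TRUE))
  }
  W <- ((N - g) / (g - 1)) * num / den
  list(W = W, df1 = g - 1L, df2 = N - g,
       p = stats::pf(W, g - 1, N - g, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Differential-expression variance by bow-tie compartment
#'
#' Groups per-vertex log fold-changes by bow-tie compartment and tests the
#' compartments for equal variances with the mean-centered Levene test;
#' unequal variances indicate a correspondence between topological position
#' (e.g. LSCC membership) and expression stability.
#'
#' @param bt a `pkn_bowtie`.
#' @param de data frame from [log_fold_change()] (columns `vertex`, `lfc`);
#'   vertices absent from the decomposition are ignored.
#' @return list with `table` (per-compartment n, mean, variance) and
#'   `levene` (result of [levene_test()] across the eligible compartments).
#' @export
compartment_variance_report <- function(bt, de) {
  de <- de[de$vertex %in% names(bt$compartment), , drop = FALSE]
  grp <- split(de$lfc, bt$compartment[de$vertex])
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) < 2L)
    stop("need >= 2 compartments with >= 2 members each")
  tab <- data.frame(compartment = names(grp), n = lengths(grp),
                    mean_lfc = vapply(grp, mean, 0),
                    var_lfc = vapply(grp, stats::var, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, levene = levene_test(grp))
}
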