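#' Read a GMT pathway collection
#'
#' Standard gene-set format: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path input GMT path.
#' @return named list of character vectors of member ids, with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: expected >= 3 fields", bad[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[`, "", 2L), names(sets))
  sets
}

#' Write a GMT pathway collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description))
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tissue expression matrix
#'
#' TSV with first column `spot_id` and one column of non-negative
#' normalised intensities per tissue (emulating a GCRMA-normalised
#' multi-tissue panel).
#'
#' @param path input TSV path.
#' @return numeric matrix, rownames = spot ids.
#' @export
read_tissue_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("tissue intensities must be non-negative")
  m
}

#' Expression drawing weights over the reference universe
#'
#' The overall expression value of a vertex is the sum of its mapped spots'
#' intensities over all tissues; the drawing probability is that value
#' normalised over the mappable universe. Universe vertices without any
#' mapped spot are excluded (and reported via the `excluded` attribute);
#' vertices whose mapped rows are all zero receive the smallest positive
#' overall expression, since a vertex known to exist cannot have drawing
#' probability zero.
#'
#' @param tm tissue matrix (rows = spots) as from [read_tissue_matrix()].
#' @param spot_map a `pkn_idmap` from spot/tag ids to vertex ids.
#' @param universe character vector of reference vertex ids (including
#'   orphans: enrichment keeps them).
#' @return a `pkn_weights` data frame with columns `vertex`, `E`, `p`
#'   (p sums to 1); attributes `excluded` (universe vertices without spots)
#'   and `zero_imputed` (count).
#' @export
compute_weights <- function(tm, spot_map, universe) {
  stopifnot(length(universe) > 0L)
  universe <- sort(unique(as.character(universe)))
  rs <- rowSums(tm)
  map <- spot_map[spot_map$source_id %in% rownames(tm) &
                    spot_map$vertex_id %in% universe, , drop = FALSE]
  E <- tapply(rs[map$source_id], map$vertex_id, sum)
  excluded <- setdiff(universe, names(E))
  E <- E[sort(names(E))]
  if (length(E) == 0L || all(E <= 0))
    stop("no positive expression weight in the universe")
  n_zero <- sum(E <= 0)
  if (n_zero > 0L) E[E <= 0] <- min(E[E > 0])
  w <- data.frame(vertex = names(E), E = as.numeric(E),
                  p = as.numeric(E) / sum(E), stringsAsFactors = FALSE)
  rownames(w) <- NULL
  class(w) <- c("pkn_weights", "data.frame")
  attr(w, "excluded") <- excluded
  attr(w, "zero_imputed") <- n_zero
  w
}

#' Group odds ratio for a pathway
#'
#' Single odds parameter of the noncentral test: ratio of the average
#' overall expression inside the pathway (within the universe) to the
#' average outside. Scale-invariant in the weights.
#'
#' @param w a `pkn_weights`.
#' @param pathway character vector of vertex ids.
#' @return positive scalar odds `omega`.
#' @export
group_odds <- function(w, pathway) {
  inside <- w$vertex %in% pathway
  if (!any(inside) || all(inside))
    stop("pathway group and its complement must both be non-empty")
  mean(w$E[inside]) / mean(w$E[!inside])
}

#' Overlap table for an enrichment test
#'
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n filtered-set size within the universe.
#' @param k overlap size.
#' @param omega positive odds parameter.
#' @return validated list of class `pkn_overlap`.
#' @export
overlap_table <- function(N, K, n, k, omega = 1) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, omega > 0)
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  if (k < lo || k > hi)
    stop(sprintf("overlap k=%d outside support [%d, %d]", k, lo, hi))
  structure(list(N = N, K = K, n = n, k = k, omega = omega,
                 support = lo:hi), class = "pkn_overlap")
}

# log-space pmf of the univariate noncentral (Fisher) hypergeometric
# distribution on its support, normalised
noncentral_log_pmf <- function(N, K, n, omega) {
  x <- max(0L, n - (N - K)):min(n, K)
  lw <- lchoose(K, x) + lchoose(N - K, n - x) + x * log(omega)
  lw <- lw - max(lw)
  list(x = x, logp = lw - log(sum(exp(lw))))
}

#' One-tailed noncentral Fisher exact test for over-representation
#'
#' Null model: the filtered vertex set is drawn from the reference universe
#' biased by expression, so that the overlap count follows the univariate
#' noncentral (Fisher) hypergeometric distribution with odds `omega`. The
#' p-value is the probability of an overlap at least as large as observed —
#' the sum over all tables with the observed margins and outcome at least as
#' extreme. `omega = 1` recovers the central one-sided Fisher test.
#' Computation is in log space and normalised over the support.
#'
#' @param t a `pkn_overlap` from [overlap_table()], or `N` may be given with
#'   the remaining counts as separate arguments.
#' @param K,n,k,omega see [overlap_table()]; used when `t` is numeric.
#' @return p-value in (0, 1].
#' @export
noncentral_fisher_test <- function(t, K = NULL, n = NULL, k = NULL,
                                   omega = 1) {
  if (!inherits(t, "pkn_overlap")) t <- overlap_table(t, K, n, k, omega)
  d <- noncentral_log_pmf(t$N, t$K, t$n, t$omega)
  tail <- d$logp[d$x >= t$k]
  m <- max(tail)
  min(1, exp(m) * sum(exp(tail - m)))
}

#' Central one-sided Fisher exact test
#'
#' The classical test against the reference network as background set:
#' identical to [noncentral_fisher_test()] with the odds forced to 1.
#'
#' @inheritParams noncentral_fisher_test
#' @return p-value in (0, 1].
#' @export
central_fisher_test <- function(t, K = NULL, n = NULL, k = NULL) {
  if (!inherits(t, "pkn_overlap")) t <- overlap_table(t, K, n, k, 1)
  t$omega <- 1
  noncentral_fisher_test(t)
}

#' Weighted sampling without replacement
#'
#' Sequential urn draw with probability proportional to weight among the
#' remaining items, implemented by the exponential-key method (draw
#' `rexp(1)/w_i` per item, keep the `size` smallest keys), which yields the
#' same distribution and vectorises.
#'
#' @param x items to draw from.
#' @param size sample size.
#' @param w positive weights, same length as `x`.
#' @return vector of `size` sampled items.
#' @export
weighted_sample <- function(x, size, w) {
  stopifnot(length(w) == length(x), all(w > 0), size <= length(x))
  keys <- stats::rexp(length(x)) / w
  x[order(keys)[seq_len(size)]]
}

# membership matrix (vertices x T) of T weighted samples of given size,
# followed by one extension step; returns logical matrices
mc_extended_samples <- function(ref, w, n_strict, T) {
  verts <- ref$vertices
  nv <- length(verts)
  wv <- stats::setNames(rep(0, nv), verts)
  wv[w$vertex] <- w$E
  universe_idx <- which(wv > 0)
  stopifnot(n_strict <= length(universe_idx))
  keys <- matrix(stats::rexp(length(universe_idx) * T), ncol = T) /
    wv[universe_idx]
  sel <- matrix(FALSE, nv, T, dimnames = list(verts, NULL))
  for (t in seq_len(T)) {
    pick <- universe_idx[order(keys[, t])[seq_len(n_strict)]]
    sel[pick, t] <- TRUE
  }
  ed <- unique(ref$edges[, c("from", "to")])
  if (nrow(ed) > 0L) {
    i <- match(c(ed$from, ed$to), verts)
    j <- match(c(ed$to, ed$from), verts)
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
    ext <- sel | (as.matrix(A %*% sel) > 0)
  } else ext <- sel
  list(strict = sel, extended = ext)
}

#' Monte-Carlo empirical p-value for the 1-extended network
#'
#' The extended network's vertices are a deterministic function of the
#' strict set, so the null distribution of the extended overlap is obtained
#' by sampling strict-sized vertex sets from the expression-weighted urn,
#' applying the strict-to-1-extended mapping to each sample, and recording
#' the overlap with the pathway. The empirical p-value uses the add-one form
#' `(1 + #{o_t >= o_obs}) / (1 + T)` so it is never zero and remains a valid
#' FDR input; the plain `r/T` form is available via `add_one = FALSE`.
#'
#' @param ref reference `pkn_network`.
#' @param w a `pkn_weights` over the universe.
#' @param n_strict size of the strict (seed) sets to draw.
#' @param pathway character vector of pathway vertex ids.
#' @param o_obs observed overlap of the pathway with the 1-extended set.
#' @param T number of Monte-Carlo samples (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @param add_one use the add-one empirical p-value form (default TRUE).
#' @return list with `p` and `overlaps` (length-`T` sampled null overlaps).
#' @export
monte_carlo_extended_test <- function(ref, w, n_strict, pathway, o_obs,
                                      T = 10000, seed = NULL,
                                      add_one = TRUE) {
  stopifnot(T >= 1)
  if (!is.null(seed)) set.seed(seed)
  sm <- mc_extended_samples(ref, w, n_strict, T)
  pw <- ref$vertices %in% pathway
  overlaps <- as.integer(crossprod(sm$extended, pw))
  r <- sum(overlaps >= o_obs)
  p <- if (add_one) (1 + r) / (1 + T) else r / T
  list(p = p, overlaps = overlaps)
}

#' Pathway over-representation across a collection
#'
#' Tests every pathway whose overlap with the filtered vertex set reaches
#' `min_overlap` (default 2; singleton overlaps are reported as untested and
#' excluded from the FDR family). All counts are taken within the mappable
#' universe defined by the weight vector. Modes:
#' \describe{
#'   \item{`strict_exact`}{noncentral Fisher test with per-pathway group
#'     odds — the strict-network test.}
#'   \item{`extended_mc`}{Monte-Carlo empirical p-values for the 1-extended
#'     network; `filtered` must then be the *strict* detection set, from
#'     which the observed extension and the null samples are derived. One
#'     shared set of `T` samples serves all pathways.}
#'   \item{`central`}{classical one-sided Fisher test (odds 1) against the
#'     reference universe — the comparison baseline.}
#' }
#' q-values are computed over the tested family only and rows sorted by
#' (q, p).
#'
#' @param ref reference `pkn_network`.
#' @param filtered a `pkn_detection` or vertex character vector (strict set).
#' @param pathways named list of pathway member vectors (reference ids).
#' @param w a `pkn_weights`.
#' @param mode one of `"strict_exact"`, `"extended_mc"`, `"central"`.
#' @param min_overlap minimum overlap for testing (default 2).
#' @param T Monte-Carlo sample count for `extended_mc`.
#' @param seed RNG seed for `extended_mc`.
#' @param lambda tuning parameter of the q-value pi0 estimate.
#' @return data frame with columns `pathway`, `N`, `K`, `n`, `k`, `omega`,
#'   `p`, `q`, `method`, `T`.
#' @export
enrich_all <- function(ref, filtered, pathways, w,
                       mode = c("strict_exact", "extended_mc", "central"),
                       min_overlap = 2, T = 10000, seed = NULL,
                       lambda = 0.5) {
  mode <- match.arg(mode)
  if (inherits(filtered, "pkn_detection")) filtered <- filtered$detected
  universe <- w$vertex
  N <- length(universe)
  strict_u <- intersect(filtered, universe)
  eval_set <- if (mode == "extended_mc")
    intersect(extend(ref, filtered, 1), universe) else strict_u
  n_eval <- length(eval_set)
  K <- vapply(pathways, function(pw) length(intersect(pw, universe)), 0L)
  k <- vapply(pathways, function(pw) length(intersect(pw, eval_set)), 0L)
  keep <- k >= min_overlap & K >= 1L
  res <- data.frame(pathway = names(pathways), N = N, K = K,
                    n = n_eval, k = k, omega = NA_real_,
                    p = NA_real_, q = NA_real_, method = mode,
                    T = if (mode == "extended_mc") T else NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L) return(res)
  if (mode == "extended_mc") {
    if (!is.null(seed)) set.seed(seed)
    sm <- mc_extended_samples(ref, w, length(strict_u), T)
    P <- vapply(res$pathway,
                function(nm) ref$vertices %in% intersect(pathways[[nm]],
                                                         universe),
                logical(length(ref$vertices)))
    null_ov <- crossprod(sm$extended, P)  # T x pathways
    res$p <- vapply(seq_len(nrow(res)), function(i)
      (1 + sum(null_ov[, i] >= res$k[i])) / (1 + T), 0)
    res$omega <- vapply(res$pathway,
                        function(nm) group_odds(w, pathways[[nm]]), 0)
  } else {
    res$omega <- if (mode == "central") 1 else
      vapply(res$pathway, function(nm) group_odds(w, pathways[[nm]]), 0)
    res$p <- vapply(seq_len(nrow(res)), function(i)
      noncentral_fisher_test(overlap_table(res$N[i], res$K[i], res$n[i],
                                           res$k[i], res$omega[i])), 0)
  }
  res$q <- storey_qvalues(res$p, lambda = lambda)
  res <- res[order(res$q, res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}
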