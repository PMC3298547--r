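# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals: reachability
# is computed by boolean matrix closure, components by union-find, and the
# noncentral test by direct enumeration in plain arithmetic.

random_net <- function(n, m, labels = c("act", "inh")) {
  verts <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = verts, to = verts, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- min(m, nrow(pairs))
  pick <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  pick$label <- if (is.null(labels)) rep("", m) else
    sample(labels, m, replace = TRUE)
  pkn_network(verts, pick)
}

# n x n logical matrix: [s, t] TRUE iff s reaches t by a nonempty path
reach_oracle <- function(net) {
  verts <- net$vertices
  n <- length(verts)
  A <- matrix(FALSE, n, n, dimnames = list(verts, verts))
  ed <- unique(net$edges[, c("from", "to")])
  A[cbind(ed$from, ed$to)] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

conn_pairs_oracle <- function(net) {
  R <- reach_oracle(net)
  diag(R) <- FALSE
  R
}

dis_oracle <- function(net, pairs = "mediator") {
  verts <- net$vertices
  C <- conn_pairs_oracle(net)
  total <- sum(C)
  res <- data.frame(vertex = verts, N0 = NA_real_, N_minus = NA_real_)
  for (i in seq_along(verts)) {
    v <- verts[i]
    res$N0[i] <- if (pairs == "mediator")
      total - sum(C[v, ]) - sum(C[, v]) else total
    sub <- induced_subnetwork(net, setdiff(verts, v))
    res$N_minus[i] <- sum(conn_pairs_oracle(sub))
  }
  res$dis <- ifelse(res$N0 > 0, (res$N0 - res$N_minus) / res$N0, 0)
  res
}

wcc_count_oracle <- function(net) {
  verts <- net$vertices
  if (length(verts) == 0L) return(0L)
  parent <- stats::setNames(verts, verts)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(net$edges))) {
    a <- find(net$edges$from[i]); b <- find(net$edges$to[i])
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(verts, find, "")))
}

bowtie_oracle_check <- function(net, bt) {
  R <- reach_oracle(net)
  comp <- bt$compartment
  lscc <- names(comp)[comp == "LSCC"]
  ok <- TRUE
  # LSCC mutually reachable
  for (v in lscc) for (w in lscc)
    if (v != w && (!R[v, w] || !R[w, v])) ok <- FALSE
  for (v in names(comp)) {
    reaches <- any(R[v, lscc])
    reached <- any(R[lscc, v])
    expected <- if (v %in% lscc) "LSCC"
      else if (reaches && !reached) "IN"
      else if (reached && !reaches) "OUT"
      else "OTHER"
    if (comp[[v]] != expected) ok <- FALSE
  }
  ok
}

# direct-arithmetic noncentral hypergeometric upper tail
ncfisher_oracle <- function(N, K, n, k, omega) {
  x <- max(0, n - (N - K)):min(n, K)
  w <- choose(K, x) * choose(N - K, n - x) * omega^x
  sum(w[x >= k]) / sum(w)
}

random_overlap_table <- function(Nmax = 60) {
  N <- sample(2:Nmax, 1)
  K <- sample(1:(N - 1), 1)
  n <- sample(1:N, 1)
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  k <- if (lo == hi) lo else sample(lo:hi, 1)
  list(N = N, K = K, n = n, k = k)
}
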