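# well-separated per-generator seed streams from one user seed
seed_stream <- function(seed, k) (as.integer(seed) %% 214748364L) * 10L + k

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-input generator. Defaults emulate the
#' scale of a curated signaling reference network and of SAGE-style
#' tag-count expression data: a sparse directed graph of 1800 vertices and
#' 3900 edges with a planted strongly connected core (so the bow-tie
#' decomposition is non-degenerate), 137 pathways of mean size 48, an
#' 84-tissue intensity panel, and presence/absence gene detection at a base
#' rate of 0.33 per condition (yielding strict networks of roughly 600
#' vertices from an 1800-vertex reference). Enrichment is planted in the
#' detection probability — matching the pipeline's presence semantics — by
#' multiplying the base rate by `enrichment_factor` for members of
#' `planted_pathway`. Tag counts are negative binomial (SAGE libraries are
#' over-dispersed); differential expression is log-normal around zero with
#' the noise variance inflated by `variance_inflation` for vertices of the
#' reference network's IN compartment, tying topology to expression
#' variability.
#'
#' @param seed integer RNG seed recorded with every output.
#' @param n_vertices,n_edges reference network scale.
#' @param core_size size of the planted strongly connected core.
#' @param n_pathways,mean_pathway_size pathway collection scale.
#' @param pathway_locality fraction of each pathway grown as a connected
#'   neighborhood ball; the rest is sampled network-wide.
#' @param n_tissues number of tissue columns in the intensity panel.
#' @param detection_base_rate probability that a background gene is
#'   detectable in the tissue at all; both conditions then observe the
#'   detectable set up to a small independent dropout, so the two
#'   conditions' detection sets overlap heavily (their symmetric difference
#'   is small) as in real paired tissue libraries.
#' @param condition_dropout per-condition probability that a detectable
#'   gene is missed.
#' @param planted_pathway id of the pathway receiving the detection boost.
#' @param enrichment_factor multiplier (>= 1) on the detection rate of
#'   planted-pathway members; 1 means no planted signal.
#' @param library_size named vector, total tag counts per condition.
#' @param nb_dispersion negative-binomial dispersion (1/size); tag sampling
#'   within one library is close to Poisson, so the default adds only mild
#'   extra-Poisson noise.
#' @param lfc_sd standard deviation of the true log2 fold-change noise.
#' @param variance_inflation factor multiplying the log fold-change noise
#'   *variance* for IN-compartment vertices.
#' @param tissue_sdlog log-sd of the log-normal tissue intensities.
#' @param breast_upweight intensity multiplier of the designated
#'   breast-like tissue column for a random 20% vertex subset.
#' @param n_enzymes,n_substrates,n_currency,currency_reactions reaction
#'   table scale; each currency substrate is planted into
#'   `currency_reactions` (> 100) distinct reactions.
#' @return validated list of class `pkn_simconfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_vertices = 1800L, n_edges = 3900L,
                       core_size = 300L,
                       n_pathways = 137L, mean_pathway_size = 48,
                       pathway_locality = 0.5,
                       n_tissues = 84L,
                       detection_base_rate = 0.33,
                       condition_dropout = 0.05,
                       planted_pathway = "PW001",
                       enrichment_factor = 1,
                       library_size = c(normal = 50000, disease = 50000),
                       nb_dispersion = 0.1,
                       lfc_sd = 0.5,
                       variance_inflation = 4,
                       tissue_sdlog = 1,
                       breast_upweight = 3,
                       n_enzymes = 120L, n_substrates = 400L,
                       n_currency = 3L, currency_reactions = 150L) {
  cfg <- list(seed = as.integer(seed), n_vertices = as.integer(n_vertices),
              n_edges = as.integer(n_edges), core_size = as.integer(core_size),
              n_pathways = as.integer(n_pathways),
              mean_pathway_size = mean_pathway_size,
              pathway_locality = pathway_locality,
              n_tissues = as.integer(n_tissues),
              detection_base_rate = detection_base_rate,
              condition_dropout = condition_dropout,
              planted_pathway = planted_pathway,
              enrichment_factor = enrichment_factor,
              library_size = library_size,
              nb_dispersion = nb_dispersion, lfc_sd = lfc_sd,
              variance_inflation = variance_inflation,
              tissue_sdlog = tissue_sdlog,
              breast_upweight = breast_upweight,
              n_enzymes = as.integer(n_enzymes),
              n_substrates = as.integer(n_substrates),
              n_currency = as.integer(n_currency),
              currency_reactions = as.integer(currency_reactions))
  stopifnot(cfg$n_vertices >= 2,
            cfg$n_edges <= cfg$n_vertices * (cfg$n_vertices - 1),
            cfg$core_size >= 0, cfg$core_size <= cfg$n_vertices,
            cfg$n_edges >= cfg$core_size,
            cfg$detection_base_rate > 0, cfg$detection_base_rate <= 1,
            cfg$condition_dropout >= 0, cfg$condition_dropout < 1,
            cfg$enrichment_factor >= 1,
            cfg$mean_pathway_size >= 1, cfg$n_tissues >= 1,
            cfg$pathway_locality >= 0, cfg$pathway_locality <= 1,
            all(cfg$library_size > 0), cfg$lfc_sd > 0,
            cfg$variance_inflation >= 1)
  class(cfg) <- "pkn_simconfig"
  cfg
}

#' Simulate the directed reference network
#'
#' Heavy-tailed out- and in-degrees (preferential-attachment-style vertex
#' weights) plus a planted strongly connected core of `core_size` vertices
#' (a random cycle through them), yielding non-degenerate bow-tie structure.
#' Edges between two non-core vertices are oriented along a fixed random
#' vertex order, so directed cycles must pass through the core and the
#' largest strongly connected component stays a moderate fraction of the
#' network (as in curated signaling networks) instead of engulfing it.
#' Exactly `n_edges` distinct edges; fully reproducible per seed.
#'
#' @param cfg a `pkn_simconfig`.
#' @return a `pkn_network`.
#' @export
simulate_reference <- function(cfg) {
  set.seed(seed_stream(cfg$seed, 0L))
  nv <- cfg$n_vertices
  verts <- sprintf("V%04d", seq_len(nv))
  # zipf-like attachment weights on a shuffled order
  wt <- (sample(nv))^(-0.75)
  from <- to <- character(0)
  core <- verts[seq_len(cfg$core_size)]
  if (cfg$core_size >= 2) {
    cyc <- sample(core)
    from <- cyc
    to <- c(cyc[-1], cyc[1])
  }
  need <- cfg$n_edges
  seen <- paste(from, to)
  # orientation order; the whole core shares one (median) rank so a
  # non-core vertex lies strictly before or after it and no directed cycle
  # can leave the core
  rank_v <- stats::setNames(sample(nv) + 0.0, verts)
  is_core <- stats::setNames(verts %in% core, verts)
  rank_v[core] <- nv / 2 + 0.25   # non-integer: never ties a vertex rank
  while (length(from) < need) {
    b <- 2L * (need - length(from)) + 16L
    s <- sample(verts, b, replace = TRUE, prob = wt)
    t <- sample(verts, b, replace = TRUE, prob = wt)
    # orient pairs with a non-core endpoint low-to-high so directed cycles
    # are confined to the planted core
    flip <- !(is_core[s] & is_core[t]) & rank_v[s] > rank_v[t]
    tmp <- s[flip]; s[flip] <- t[flip]; t[flip] <- tmp
    ok <- s != t
    key <- paste(s, t)
    ok <- ok & !duplicated(key) & !(key %in% seen)
    s <- s[ok]; t <- t[ok]
    room <- need - length(from)
    if (length(s) > room) { s <- s[seq_len(room)]; t <- t[seq_len(room)] }
    from <- c(from, s); to <- c(to, t)
    seen <- c(seen, paste(s, t))
  }
  lab <- sample(c("act", "inh"), need, replace = TRUE, prob = c(0.8, 0.2))
  pkn_network(verts, data.frame(from = from, to = to, label = lab,
                                stringsAsFactors = FALSE),
              name = "synthetic reference")
}

#' Simulate a pathway collection on a network
#'
#' Pathway sizes follow a shifted Poisson around the configured mean. A
#' fraction `pathway_locality` of each pathway's members is grown as an
#' undirected ball from a random seed vertex — mild topological clustering
#' mimicking the cascade core of a curated pathway — while the remainder is
#' drawn uniformly from the network, like the scattered regulators and
#' targets a curated map also contains. Overlaps between pathways are
#' allowed.
#'
#' @param net the reference `pkn_network`.
#' @param cfg a `pkn_simconfig`.
#' @return named list of member vectors (a GMT-ready collection).
#' @export
simulate_pathways <- function(net, cfg) {
  set.seed(seed_stream(cfg$seed, 1L))
  adj <- adjacency_lists(net, mode = "all")
  verts <- net$vertices
  sets <- vector("list", cfg$n_pathways)
  sizes <- 1L + stats::rpois(cfg$n_pathways,
                             max(0, cfg$mean_pathway_size - 1))
  sizes <- pmax(2L, pmin(sizes, length(verts)))
  for (i in seq_len(cfg$n_pathways)) {
    n_local <- max(1L, round(cfg$pathway_locality * sizes[i]))
    seed_v <- sample(verts, 1L)
    members <- seed_v
    frontier <- seed_v
    while (length(members) < n_local && length(frontier) > 0L) {
      nb <- setdiff(sample(unique(unlist(adj[frontier]))), members)
      take <- utils::head(nb, n_local - length(members))
      members <- c(members, take)
      frontier <- take
    }
    if (length(members) < sizes[i])
      members <- c(members,
                   sample(setdiff(verts, members),
                          sizes[i] - length(members)))
    sets[[i]] <- sort(members)
  }
  names(sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  attr(sets, "description") <- stats::setNames(
    rep("synthetic pathway", cfg$n_pathways), names(sets))
  sets
}

#' Simulate expression inputs for both conditions
#'
#' Every vertex receives 1–3 tag identifiers. Detection is presence-based:
#' a vertex is *detectable* with probability
#' `min(1, detection_base_rate * enrichment_factor^(member of planted
#' pathway))`, and each condition observes a detectable vertex unless an
#' independent dropout (probability `condition_dropout`) misses it — so the
#' union detection rate is close to the detectable rate and the conditions'
#' symmetric difference is small. Detected vertices receive
#' negative-binomial tag counts scaled to the configured library size (with
#' at least one tag present), undetected vertices all-zero counts. True
#' log2 fold-changes are normal with sd `lfc_sd`, inflated by
#' `sqrt(variance_inflation)` for vertices in the reference network's IN
#' compartment. The tissue matrix has log-normal intensities per tag with a
#' designated breast-like column upweighted for a random 20% vertex subset.
#'
#' @param net the reference `pkn_network`.
#' @param pathways pathway collection from [simulate_pathways()].
#' @param cfg a `pkn_simconfig`.
#' @return list with `normal`, `disease` (`pkn_expression`), `idmap`
#'   (`pkn_idmap`), `tissue` (matrix), and `truth` (per-vertex detection
#'   flags, true fold-changes, compartments, planted members).
#' @export
simulate_expression <- function(net, pathways, cfg) {
  set.seed(seed_stream(cfg$seed, 2L))
  verts <- net$vertices
  nv <- length(verts)
  planted <- if (cfg$enrichment_factor > 1) {
    if (!cfg$planted_pathway %in% names(pathways))
      stop("planted pathway not in collection: ", cfg$planted_pathway)
    pathways[[cfg$planted_pathway]]
  } else character(0)
  n_tags <- sample(1:3, nv, replace = TRUE)
  tags <- sprintf("TAG%05d", seq_len(sum(n_tags)))
  tag_vertex <- rep(verts, n_tags)
  idmap <- pkn_idmap(tags, tag_vertex)
  p_det <- pmin(1, cfg$detection_base_rate *
                  ifelse(verts %in% planted, cfg$enrichment_factor, 1))
  detectable <- stats::runif(nv) < p_det
  det_n <- detectable & stats::runif(nv) >= cfg$condition_dropout
  det_d <- detectable & stats::runif(nv) >= cfg$condition_dropout
  comp <- bowtie_decompose(net)$compartment[verts]
  sd_v <- cfg$lfc_sd * ifelse(comp == "IN",
                              sqrt(cfg$variance_inflation), 1)
  delta <- stats::rnorm(nv, 0, sd_v)        # true log2 fold-change
  base_mu <- stats::rlnorm(nv, meanlog = 2, sdlog = 1)
  draw_counts <- function(detected, mu_v, lib) {
    mu_tag <- rep(mu_v / n_tags, n_tags) * rep(detected, n_tags)
    tot <- sum(mu_tag)
    if (tot > 0) mu_tag <- mu_tag * lib / tot
    cnt <- stats::rnbinom(length(mu_tag), mu = mu_tag,
                          size = 1 / cfg$nb_dispersion)
    cnt[mu_tag == 0] <- 0L
    # presence guarantee: a detected vertex shows at least one tag
    first_tag <- cumsum(c(1L, n_tags[-nv]))
    zero_det <- detected & tapply(cnt, tag_vertex, sum)[verts] == 0
    cnt[first_tag[zero_det]] <- 1L
    stats::setNames(cnt, tags)
  }
  normal <- pkn_expression(draw_counts(det_n, base_mu,
                                       cfg$library_size[["normal"]]),
                           "normal")
  disease <- pkn_expression(draw_counts(det_d, base_mu * 2^delta,
                                        cfg$library_size[["disease"]]),
                            "disease")
  tissue <- matrix(stats::rlnorm(length(tags) * cfg$n_tissues,
                                 meanlog = 4, sdlog = cfg$tissue_sdlog),
                   nrow = length(tags),
                   dimnames = list(tags,
                                   c("breast",
                                     sprintf("tissue%02d",
                                             seq_len(cfg$n_tissues - 1L)))))
  up <- verts %in% sample(verts, round(0.2 * nv))
  tissue[rep(up, n_tags), "breast"] <-
    tissue[rep(up, n_tags), "breast"] * cfg$breast_upweight
  list(normal = normal, disease = disease, idmap = idmap, tissue = tissue,
       truth = list(detected_normal = stats::setNames(det_n, verts),
                    detected_disease = stats::setNames(det_d, verts),
                    delta = stats::setNames(delta, verts),
                    compartment = comp, planted = planted))
}

#' Simulate a reaction table
#'
#' Enzymes catalyse 1–5 reactions each over a substrate pool in which every
#' non-currency substrate occurs in at most 10 reactions, while each of the
#' planted currency substrates is inserted into more than 100 distinct
#' reactions; reversibility is Bernoulli(0.5).
#'
#' @param cfg a `pkn_simconfig`.
#' @return a `pkn_reactions`.
#' @export
simulate_reactions <- function(cfg) {
  set.seed(seed_stream(cfg$seed, 3L))
  enzymes <- sprintf("ENZ%03d", seq_len(cfg$n_enzymes))
  pool <- sprintf("SUB%04d", seq_len(cfg$n_substrates))
  usage <- stats::setNames(integer(cfg$n_substrates), pool)
  rxn_enz <- rep(enzymes, sample(1:5, cfg$n_enzymes, replace = TRUE))
  n_rxn <- length(rxn_enz)
  if (n_rxn <= cfg$currency_reactions)
    stop("too few reactions to plant currency substrates")
  educts <- products <- vector("list", n_rxn)
  pick <- function(k, exclude = character(0)) {
    avail <- setdiff(names(usage)[usage < 10L], exclude)
    s <- sample(avail, min(k, length(avail)))
    usage[s] <<- usage[s] + 1L
    s
  }
  for (i in seq_len(n_rxn)) {
    educts[[i]] <- pick(sample(1:3, 1))
    products[[i]] <- pick(sample(1:3, 1), exclude = educts[[i]])
  }
  currency <- sprintf("CUR%02d", seq_len(cfg$n_currency))
  for (cu in currency) {
    hit <- sample(n_rxn, cfg$currency_reactions)
    side <- stats::runif(length(hit)) < 0.5
    for (j in seq_along(hit)) {
      i <- hit[j]
      if (side[j]) educts[[i]] <- c(educts[[i]], cu)
      else products[[i]] <- c(products[[i]], cu)
    }
  }
  pkn_reactions(sprintf("RXN%04d", seq_len(n_rxn)), rxn_enz,
                educts, products,
                stats::runif(n_rxn) < 0.5)
}
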