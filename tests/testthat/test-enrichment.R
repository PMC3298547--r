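test_that("weights sum mapped spot rows and normalise over the universe", {
  tm <- matrix(c(1, 2, 0.5, 0.5), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("t1", "t2")))
  w <- compute_weights(tm, pkn_idmap(c("s1", "s2"), c("vA", "vB")),
                       c("vA", "vB"))
  expect_equal(w$p, c(0.75, 0.25))

  # two spots of one vertex add up
  tm2 <- matrix(2, 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  w2 <- compute_weights(tm2, pkn_idmap(c("s1", "s2"), c("vA", "vA")), "vA")
  expect_equal(w2$E, 4)

  # identical rows give the uniform distribution
  tm3 <- matrix(1, 3, 4, dimnames = list(paste0("s", 1:3), NULL))
  w3 <- compute_weights(tm3, pkn_idmap(paste0("s", 1:3), c("a", "b", "c")),
                        c("a", "b", "c"))
  expect_equal(w3$p, rep(1 / 3, 3))

  # universe vertex without a spot is excluded and reported
  w4 <- compute_weights(tm, pkn_idmap(c("s1", "s2"), c("vA", "vB")),
                        c("vA", "vB", "vC"))
  expect_equal(attr(w4, "excluded"), "vC")

  # all-zero rows get the smallest positive weight; all-zero matrix errors
  tm5 <- matrix(c(3, 0), 2, 1, dimnames = list(c("s1", "s2"), NULL))
  w5 <- compute_weights(tm5, pkn_idmap(c("s1", "s2"), c("vA", "vB")),
                        c("vA", "vB"))
  expect_equal(w5$E, c(3, 3))
  expect_equal(attr(w5, "zero_imputed"), 1L)
  tm6 <- matrix(0, 2, 2, dimnames = list(c("s1", "s2"), NULL))
  expect_error(compute_weights(tm6, pkn_idmap(c("s1", "s2"), c("vA", "vB")),
                               c("vA", "vB")), "positive")
})

test_that("group odds is the pathway/background mean ratio, scale invariant", {
  w <- structure(data.frame(vertex = letters[1:4], E = c(2, 2, 1, 1),
                            p = c(2, 2, 1, 1) / 6),
                 class = c("pkn_weights", "data.frame"))
  expect_equal(group_odds(w, c("a", "b")), 2)
  w$E <- c(1, 1, 1, 1)
  expect_equal(group_odds(w, c("a", "b")), 1)
  w$E <- c(2, 2, 1, 1) * 37
  expect_equal(group_odds(w, c("a", "b")), 2)
  expect_error(group_odds(w, letters[1:4]), "non-empty")
  expect_error(group_odds(w, "zz"), "non-empty")
})

test_that("noncentral test reproduces enumerated tail probabilities", {
  expect_equal(noncentral_fisher_test(overlap_table(10, 5, 4, 4, 1)),
               5 / 210, tolerance = 1e-12)
  # N=4, K=2, n=2: support weights (1, 4w, w^2)
  expect_equal(noncentral_fisher_test(overlap_table(4, 2, 2, 2, 1)),
               1 / 6, tolerance = 1e-12)
  expect_equal(noncentral_fisher_test(overlap_table(4, 2, 2, 2, 2)),
               4 / 13, tolerance = 1e-12)
  # at the support minimum the whole distribution is "at least as extreme"
  expect_equal(noncentral_fisher_test(overlap_table(10, 8, 7, 5, 3.3)), 1)
  expect_error(overlap_table(10, 5, 4, 5), "support")
})

test_that("noncentral tail is monotone and matches the oracle on random tables", {
  set.seed(401)
  for (i in 1:150) {
    tb <- random_overlap_table(60)
    for (omega in c(0.1, 0.5, 1, 2, 10)) {
      p <- noncentral_fisher_test(overlap_table(tb$N, tb$K, tb$n, tb$k,
                                                omega))
      expect_equal(p, ncfisher_oracle(tb$N, tb$K, tb$n, tb$k, omega),
                   tolerance = 1e-12)
      expect_gt(p, 0); expect_lte(p, 1)
    }
    # tail nonincreasing in k
    lo <- max(0, tb$n - (tb$N - tb$K)); hi <- min(tb$n, tb$K)
    ps <- vapply(lo:hi, function(k)
      noncentral_fisher_test(overlap_table(tb$N, tb$K, tb$n, k, 2)), 0)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("central test equals the classical one-sided Fisher test", {
  set.seed(402)
  for (i in 1:200) {
    tb <- random_overlap_table(150)
    p <- central_fisher_test(overlap_table(tb$N, tb$K, tb$n, tb$k))
    expect_equal(p, stats::phyper(tb$k - 1, tb$K, tb$N - tb$K, tb$n,
                                  lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(p, noncentral_fisher_test(overlap_table(tb$N, tb$K, tb$n,
                                                         tb$k, 1)),
                 tolerance = 1e-14)
  }
  expect_equal(central_fisher_test(overlap_table(10, 5, 4, 0)), 1)
})

test_that("weighted sampling without replacement follows the urn probabilities", {
  set.seed(403)
  # size-1 draws recover the weight distribution
  draws <- replicate(6000, weighted_sample(c("a", "b"), 1, c(2, 1)))
  expect_equal(mean(draws == "a"), 2 / 3, tolerance = 0.03)
  # full-size draw returns everything
  expect_setequal(weighted_sample(letters[1:5], 5, 1:5), letters[1:5])
  expect_error(weighted_sample(letters[1:3], 4, 1:3))
})

test_that("Monte-Carlo extended test: determinism, p=1 floor, edgeless consistency", {
  set.seed(404)
  ref <- random_net(12, 20)
  w <- structure(data.frame(vertex = ref$vertices, E = runif(12, 0.5, 2),
                            p = NA), class = c("pkn_weights", "data.frame"))
  w$p <- w$E / sum(w$E)
  pw <- sample(ref$vertices, 4)
  r1 <- monte_carlo_extended_test(ref, w, 5, pw, o_obs = 2, T = 500,
                                  seed = 99)
  r2 <- monte_carlo_extended_test(ref, w, 5, pw, o_obs = 2, T = 500,
                                  seed = 99)
  expect_identical(r1, r2)
  expect_equal(monte_carlo_extended_test(ref, w, 5, pw, o_obs = 0, T = 200,
                                         seed = 1)$p, 1)
  expect_true(r1$p >= 1 / 501 && r1$p <= 1)

  # edgeless reference: extension is the identity, uniform weights make the
  # null exactly central hypergeometric
  edgeless <- pkn_network(sprintf("u%02d", 1:20))
  wu <- structure(data.frame(vertex = edgeless$vertices, E = 1, p = 1 / 20),
                  class = c("pkn_weights", "data.frame"))
  pw2 <- edgeless$vertices[1:5]
  for (k in c(2, 3)) {
    res <- monte_carlo_extended_test(edgeless, wu, 5, pw2, o_obs = k,
                                     T = 10000, seed = 7)
    exact <- stats::phyper(k - 1, 5, 15, 5, lower.tail = FALSE)
    se <- sqrt(exact * (1 - exact) / 10000)
    expect_lt(abs(res$p - exact), 3 * se + 2 / 10001)
  }
})

test_that("q-values: worked examples, BH reduction, monotonicity, bounds", {
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03), lambda = 0),
               c(0.03, 0.03, 0.03))
  expect_equal(storey_qvalues(rep(1, 5), lambda = 0.5), rep(1, 5))
  p1 <- 0.2
  expect_equal(storey_qvalues(p1, lambda = 0.5), min(1, 1 * p1))
  set.seed(405)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- storey_qvalues(p, lambda = 0)
    # pi0 = 1 recovers Benjamini-Hochberg
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    q5 <- storey_qvalues(p, lambda = 0.5)
    m <- length(p)
    pi0 <- min(1, max(1 / m, sum(p > 0.5) / (m * 0.5)))
    expect_true(all(q5 <= 1))
    expect_true(all(q5 >= pi0 * p - 1e-12))
    # monotone in p, permutation invariant
    o <- order(p)
    expect_true(all(diff(q5[o]) >= -1e-12))
    perm <- sample(m)
    expect_equal(storey_qvalues(p[perm], 0.5), q5[perm])
  }
  expect_equal(storey_qvalues(numeric()), numeric())
})

test_that("enrich_all applies the overlap threshold, modes and FDR family", {
  set.seed(406)
  ref <- random_net(30, 60)
  tm <- matrix(rlnorm(30 * 4), 30, 4,
               dimnames = list(paste0("s", 1:30), NULL))
  idmap <- pkn_idmap(paste0("s", 1:30), ref$vertices)
  w <- compute_weights(tm, idmap, ref$vertices)
  pws <- list(PW1 = ref$vertices[1:8], PW2 = ref$vertices[9:12],
              PW3 = ref$vertices[c(1, 20)])
  filtered <- ref$vertices[c(1:6, 20)]
  res <- enrich_all(ref, filtered, pws, w, mode = "strict_exact")
  # PW2 overlaps in 0 vertices -> excluded from table and FDR family
  expect_false("PW2" %in% res$pathway)
  expect_equal(res$q, storey_qvalues(res$p))
  expect_true(all(diff(res$q) >= -1e-12))  # sorted by q
  cen <- enrich_all(ref, filtered, pws, w, mode = "central")
  expect_true(all(cen$omega == 1))
  mc <- enrich_all(ref, filtered, pws, w, mode = "extended_mc", T = 300,
                   seed = 5)
  expect_true(all(mc$p >= 1 / 301 & mc$p <= 1))
  mc2 <- enrich_all(ref, filtered, pws, w, mode = "extended_mc", T = 300,
                    seed = 5)
  expect_identical(mc, mc2)
  # single tested pathway: q = clamp(pi0 * p)
  res1 <- enrich_all(ref, filtered, pws["PW1"], w, mode = "strict_exact")
  expect_equal(res1$q, min(1, res1$p * 1))
})

test_that("planted enrichment is recovered at small scale", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = 700 + s, n_vertices = 300, n_edges = 650,
                      core_size = 50, n_pathways = 25,
                      mean_pathway_size = 20, detection_base_rate = 0.3,
                      enrichment_factor = 3)
    ref <- simulate_reference(cfg)
    pws <- simulate_pathways(ref, cfg)
    ex <- simulate_expression(ref, pws, cfg)
    u <- combine_conditions(map_detection(ex$normal, ex$idmap, ref),
                            map_detection(ex$disease, ex$idmap, ref))$union
    w <- compute_weights(ex$tissue, ex$idmap, ref$vertices)
    res <- enrich_all(ref, u, pws, w, mode = "strict_exact")
    if (res$pathway[1] == cfg$planted_pathway) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("GMT files round-trip", {
  sets <- list(A = c("x", "y"), B = c("y", "z", "w"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back[["A"]], sets$A)
  expect_equal(back[["B"]], sets$B)
  writeLines("name_only\tdesc", f)
  expect_error(read_gmt(f), "GMT")
})
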