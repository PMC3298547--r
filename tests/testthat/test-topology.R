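path3 <- pkn_network(c("a", "b", "c"),
                     data.frame(from = c("a", "b"), to = c("b", "c")))

test_that("Dis scores match hand-derived cases", {
  d <- dis_index(path3)
  expect_equal(d$dis[d$vertex == "b"], 1)   # pair (a,c) destroyed
  expect_equal(d$dis[d$vertex != "b"], c(0, 0))
  expect_equal(d$dis_norm[d$vertex == "b"], 1)

  # complete digraph: any remaining pair stays directly connected
  full3 <- pkn_network(c("a", "b", "c"),
                       expand.grid(from = c("a", "b", "c"),
                                   to = c("a", "b", "c"),
                                   stringsAsFactors = FALSE))
  expect_equal(dis_index(full3)$dis, rep(0, 3))

  # leaf without throughput scores zero
  star <- pkn_network(c("h", "l1", "l2"),
                      data.frame(from = "h", to = c("l1", "l2")))
  ds <- dis_index(star)
  expect_equal(ds$dis[ds$vertex %in% c("l1", "l2")], c(0, 0))
  expect_error(dis_index(pkn_network("a")), "at least 2")
})

test_that("Dis equals the exhaustive remove-and-recount oracle", {
  set.seed(501)
  for (i in 1:30) {
    net <- remove_orphans(random_net(sample(4:40, 1), sample(5:70, 1)))
    if (length(net$vertices) < 2) next
    d <- dis_index(net)
    o <- dis_oracle(net)
    expect_identical(d$N0, o$N0)
    expect_identical(d$N_minus, o$N_minus)
    expect_equal(d$dis, o$dis)
    # removal never creates connected pairs among the others
    expect_true(all(d$N_minus <= d$N0))
    expect_true(all(d$dis >= 0 & d$dis <= 1))
    if (max(d$dis) > 0) expect_equal(max(d$dis_norm), 1)
  }
})

test_that("the all-pairs Dis variant counts pairs through the vertex", {
  d <- dis_index(path3, pairs = "all")
  # removing b destroys (a,b),(b,c),(a,c) out of 3 connected pairs;
  # removing a destroys (a,b),(a,c)
  expect_equal(d$N0, rep(3, 3))
  expect_equal(d$dis[d$vertex == "b"], 1)
  expect_equal(d$dis[d$vertex == "a"], 2 / 3)
})

test_that("Dis-increase: identity, antisymmetry, bounds, hand example", {
  d <- dis_index(path3)
  inc <- dis_increase(d, d)
  expect_equal(inc$delta_dis, rep(0, 3))

  # path a->b->c->d versus the same with shortcut a->c
  p4 <- pkn_network(letters[1:4],
                    data.frame(from = letters[1:3], to = letters[2:4]))
  p4s <- pkn_network(letters[1:4],
                     data.frame(from = c(letters[1:3], "a"),
                                to = c(letters[2:4], "c")))
  d1 <- dis_index(p4); d2 <- dis_index(p4s)
  inc12 <- dis_increase(d1, d2)
  # hand computation: in p4, Dis(b)=Dis(c)=1 (norm 1,1); with the shortcut
  # removing b only loses pairs involving b: Dis(b)=0, Dis(c)=1 (norm 0,1)
  expect_equal(inc12$delta_dis[inc12$vertex == "b"], 1)
  expect_equal(inc12$delta_dis[inc12$vertex == "c"], 0)
  expect_true(all(inc12$delta_dis >= -1 & inc12$delta_dis <= 1))
  inc21 <- dis_increase(d2, d1)
  expect_equal(inc12$delta_dis, -inc21$delta_dis)

  set.seed(502)
  for (i in 1:10) {
    a <- remove_orphans(random_net(8, 14)); b <- remove_orphans(random_net(8, 14))
    shared <- intersect(a$vertices, b$vertices)
    da <- tryCatch(dis_index(a), error = function(e) NULL)
    db <- tryCatch(dis_index(b), error = function(e) NULL)
    if (is.null(da) || is.null(db)) next
    sa <- da[da$vertex %in% shared, ]; sb <- db[db$vertex %in% shared, ]
    if (nrow(sa) == 0 || max(sa$dis) == 0 || max(sb$dis) == 0) next
    iab <- dis_increase(sa, sb)
    iba <- dis_increase(sb, sa)
    expect_equal(iab$delta_dis, -iba$delta_dis)
    expect_true(all(abs(iab$delta_dis) <= 1 + 1e-12))
  }
  dz <- d; dz$dis <- dz$dis * 0; dz$dis_norm <- dz$dis
  expect_error(dis_increase(dz, d), "max Dis")
})

test_that("bow-tie decomposition labels compartments by reachability", {
  net <- pkn_network(c("a", "b", "c", "d"),
                     data.frame(from = c("a", "b", "d", "b"),
                                to = c("b", "a", "a", "c")))
  bt <- bowtie_decompose(net)
  expect_equal(sort(names(bt$compartment)[bt$compartment == "LSCC"]),
               c("a", "b"))
  expect_equal(names(bt$compartment)[bt$compartment == "IN"], "d")
  expect_equal(names(bt$compartment)[bt$compartment == "OUT"], "c")
  expect_false(bt$degenerate)

  cyc <- pkn_network(c("x", "y", "z"),
                     data.frame(from = c("x", "y", "z"),
                                to = c("y", "z", "x")))
  expect_equal(unname(bowtie_decompose(cyc)$sizes["LSCC"]), 3L)

  # equal-size SCC tie broken toward the lexicographically smallest member
  two <- pkn_network(c("a", "b", "m", "n"),
                     data.frame(from = c("a", "b", "m", "n"),
                                to = c("b", "a", "n", "m")))
  bt2 <- bowtie_decompose(two)
  expect_setequal(names(bt2$compartment)[bt2$compartment == "LSCC"],
                  c("a", "b"))

  dag <- pkn_network(c("a", "b"), data.frame(from = "a", to = "b"))
  btd <- bowtie_decompose(dag)
  expect_true(btd$degenerate)
  expect_true(all(btd$compartment == "OTHER"))
})

test_that("bow-tie labels agree with the reachability oracle on random digraphs", {
  set.seed(503)
  for (i in 1:30) {
    net <- random_net(sample(4:30, 1), sample(5:60, 1))
    bt <- bowtie_decompose(net)
    if (bt$degenerate) next
    expect_true(bowtie_oracle_check(net, bt))
    expect_equal(sum(bt$sizes), length(net$vertices))
  }
})

test_that("log fold-change respects normalization and pseudocounts", {
  idmap <- pkn_idmap(c("t1", "t2"), c("vA", "vB"))
  n <- pkn_expression(c(t1 = 10, t2 = 10), "normal")
  d <- pkn_expression(c(t1 = 10, t2 = 10), "disease")
  de <- log_fold_change(n, d, idmap)
  expect_equal(de$lfc, c(0, 0))

  # absent in normal, present in disease: finite positive
  d2 <- pkn_expression(c(t1 = 20, t2 = 0), "disease")
  n2 <- pkn_expression(c(t1 = 0, t2 = 20), "normal")
  de2 <- log_fold_change(n2, d2, idmap)
  expect_true(is.finite(de2$lfc[de2$vertex == "vA"]))
  expect_gt(de2$lfc[de2$vertex == "vA"], 0)

  # doubling the disease library with identical composition changes nothing
  d3 <- pkn_expression(c(t1 = 20, t2 = 20), "disease")
  de3 <- log_fold_change(n, d3, idmap)
  expect_equal(de3$lfc, de$lfc)

  # sign convention flips
  de4 <- log_fold_change(n2, d2, idmap, direction = "normal_vs_disease")
  expect_equal(de4$lfc, -de2$lfc)
})

test_that("Levene statistic matches the worked example and car's oracle", {
  res <- levene_test(list(c(0, 1, 2), c(0, 2, 4)))
  expect_equal(res$W, 0.8)
  expect_equal(res$p, stats::pf(0.8, 1, 4, lower.tail = FALSE))

  same <- levene_test(list(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)

  deg <- levene_test(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)

  skip_if_not_installed("car")
  set.seed(504)
  for (i in 1:10) {
    y <- c(rnorm(8), rnorm(12, sd = 2))
    g <- factor(rep(1:2, c(8, 12)))
    ours <- levene_test(split(y, g))
    ref <- car::leveneTest(y, g, center = mean)
    expect_equal(ours$W, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Levene test holds its size under equal variances", {
  set.seed(505)
  rej <- mean(replicate(800, {
    levene_test(list(rnorm(50), rnorm(50)))$p < 0.05
  }))
  expect_gte(rej, 0.025)
  expect_lte(rej, 0.075)
})

test_that("compartment variance report groups eligible compartments", {
  bt <- structure(list(compartment = c(a = "LSCC", b = "LSCC", f = "LSCC",
                                       c = "IN", d = "IN", g = "IN",
                                       e = "OUT"),
                       sizes = c(LSCC = 3L, IN = 3L, OUT = 1L, OTHER = 0L),
                       degenerate = FALSE), class = "pkn_bowtie")
  de <- data.frame(vertex = c("a", "b", "f", "c", "d", "g", "e"),
                   lfc = c(0.1, -0.1, 0.4, 2, -2, 0.5, 5))
  rep_ <- compartment_variance_report(bt, de)
  expect_equal(nrow(rep_$table), 2L)  # OUT has a single member
  expect_false(rep_$levene$degenerate)

  de0 <- data.frame(vertex = c("a", "b", "f", "c", "d", "g", "e"),
                    lfc = rep(1, 7))
  expect_true(compartment_variance_report(bt, de0)$levene$degenerate)

  bt1 <- structure(list(compartment = c(a = "LSCC", b = "LSCC"),
                        sizes = c(LSCC = 2L, IN = 0L, OUT = 0L, OTHER = 0L),
                        degenerate = FALSE), class = "pkn_bowtie")
  expect_error(compartment_variance_report(bt1, de), ">= 2 compartments")
})
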