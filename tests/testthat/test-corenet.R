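test_that("edges follow the strict |r| >= threshold contract", {
  # identical profiles: r = 1
  base <- c(1, 3, 2, 5, 4, 6)
  vals <- rbind(g1 = base, g2 = base, g3 = rev(base) + rnorm(6, sd = 3))
  net <- build_network(make_expr(vals, condition = rep(c("A", "B"), 3)),
                       c("g1", "g2", "g3"), r_threshold = 0.8)
  e12 <- net$edges[net$edges$gene_a == "g1" & net$edges$gene_b == "g2", ]
  expect_equal(e12$r, 1)
  # a pair at r = 0.79 is excluded at threshold 0.8, kept at 0.79
  pair <- correlated_pair(0.79)
  rownames(pair) <- c("a", "b")
  expr <- make_expr(pair, condition = rep(c("A", "B"), 10))
  expect_equal(nrow(build_network(expr, c("a", "b"), 0.8)$edges), 0L)
  net79 <- build_network(expr, c("a", "b"), 0.79)
  expect_equal(nrow(net79$edges), 1L)
  expect_equal(net79$edges$r, 0.79, tolerance = 1e-12)
  # isolated nodes stay in the node set at degree 0 with NA APCC
  expect_identical(unname(net79$degree), c(1L, 1L))
  iso <- build_network(expr, c("a", "b"), 0.999)
  expect_identical(unname(iso$degree), c(0L, 0L))
  expect_true(all(is.na(iso$apcc)))
})

test_that("edge set equals the brute-force all-pairs oracle", {
  set.seed(8)
  vals <- matrix(rnorm(6 * 12), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:12)))
  vals[2, ] <- vals[1, ] + rnorm(12, sd = 0.2)
  vals[4, ] <- -vals[3, ] + rnorm(12, sd = 0.2)
  expr <- make_expr(vals, condition = rep(c("A", "B"), each = 6))
  for (thr in c(0.3, 0.6, 0.9)) {
    got <- build_network(expr, rownames(vals), thr)$edges
    want <- oracle_edges(vals, thr)
    key <- function(e) paste(e$gene_a, e$gene_b)
    expect_setequal(key(got), key(want))
    expect_equal(got$r[order(key(got))], want$r[order(key(want))],
                 tolerance = 1e-12)
  }
})

test_that("zero-variance genes are excluded with a warning", {
  vals <- rbind(ok1 = rnorm(8), ok2 = rnorm(8), flat = rep(1, 8))
  expect_warning(
    net <- build_network(make_expr(vals, condition = rep(c("A", "B"), each = 4)),
                         rownames(vals), 0.5),
    "zero-variance.*flat")
  expect_identical(net$nodes, c("ok1", "ok2"))
})

test_that("hub classification follows degree and APCC boundaries", {
  # star node with 5 neighbours all r = -0.9: APCC = -0.9, fight-club
  e <- edge_df(rep("hub", 5), sprintf("x%d", 1:5), rep(-0.9, 5))
  net <- classify_hubs(make_net(e))
  expect_equal(unname(net$apcc["hub"]), -0.9)
  expect_identical(unname(net$hub_class["hub"]), "fight_club")
  # degree 4 is non_hub no matter how negative the APCC
  e4 <- edge_df(rep("hub", 4), sprintf("x%d", 1:4), rep(-0.9, 4))
  net4 <- classify_hubs(make_net(e4))
  expect_identical(unname(net4$hub_class["hub"]), "non_hub")
  # APCC exactly at party_cut is party; just below is date
  ep <- edge_df(rep("p", 5), sprintf("y%d", 1:5), rep(0.8, 5))
  expect_identical(unname(classify_hubs(make_net(ep))$hub_class["p"]), "party")
  ed <- edge_df(rep("p", 5), sprintf("y%d", 1:5), rep(0.79, 5))
  expect_identical(unname(classify_hubs(make_net(ed))$hub_class["p"]), "date")
})

test_that("classification matches a per-node oracle on random networks", {
  for (s in 1:10) {
    net <- classify_hubs(random_net(n = 20L, p_edge = 0.4, seed = s),
                         hub_degree = 5L, party_cut = 0.8)
    expect_identical(unname(net$hub_class),
                     unname(oracle_hub_class(net, 5L, 0.8)))
    # accounting: hub classes partition the nodes with degree >= 5
    s5 <- summary(net)
    expect_equal(s5$n_party + s5$n_date + s5$n_fight_club,
                 sum(net$degree >= 5L))
    expect_true(all(net$apcc >= -1 & net$apcc <= 1, na.rm = TRUE))
  }
})

test_that("raising the threshold never adds edges", {
  d <- synthetic_design(n_genes = 60L, module_sizes = c(15L, 15L),
                        n_switch = 5L, seed = 3L)
  expr <- generate_expression(d)
  thr <- c(0.5, 0.7, 0.9)
  nets <- lapply(thr, function(t) build_network(expr, d$gene_ids, t))
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(key(nets[[2]]) %in% key(nets[[1]])))
  expect_true(all(key(nets[[3]]) %in% key(nets[[2]])))
  # degree equals incident edge count, network symmetric by construction
  n1 <- nets[[1]]
  expect_equal(sum(n1$degree), 2L * nrow(n1$edges))
})
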