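# a small two-cluster graph used by the hand-worked coordinate examples:
# cluster 1 = {a, b, c, d}, cluster 2 = {e, f}
two_cluster_net <- function() {
  make_net(edge_df(c("a", "a", "a", "b", "e", "a"),
                   c("b", "c", "d", "c", "f", "e"),
                   rep(0.9, 6)))
}
two_cluster_labels <- c(a = 1L, b = 1L, c = 1L, d = 1L, e = 2L, f = 2L)

test_that("clusterphobic coefficient matches hand-worked cases", {
  net <- two_cluster_net()
  kpi <- compute_kpi(net, two_cluster_labels)
  # b: both links internal -> 0
  expect_equal(unname(kpi["b"]), 0)
  # a: 3 internal links, 1 external -> 1 - (3/4)^2
  expect_equal(unname(kpi["a"]), 1 - (3 / 4)^2)
  # e: 1 internal (f), 1 external (a) -> 1 - (1/2)^2
  expect_equal(unname(kpi["e"]), 1 - (1 / 2)^2)
  # node with most links external: 1 internal of 4 -> 1 - (1/4)^2
  net2 <- make_net(edge_df(c("x", "x", "x", "x"),
                           c("y", "p", "q", "r"), rep(0.9, 4)))
  lab2 <- c(x = 1L, y = 1L, p = 2L, q = 2L, r = 3L)
  expect_equal(unname(compute_kpi(net2, lab2)["x"]), 1 - (1 / 4)^2)
  # K_pi = 0 iff all links internal; range [0, 1]
  expect_true(all(kpi >= 0 & kpi <= 1))
  expect_identical(names(kpi)[kpi == 0], c("b", "c", "d", "f"))
})

test_that("within-module degree z-score uses the population sd", {
  # cluster 1 within-degrees: a = 3 (b, c, d), b = 2, c = 2, d = 1
  # hand z-scores with mean 2, population sd sqrt(1/2)
  net <- two_cluster_net()
  zg <- compute_zg(net, two_cluster_labels)
  expect_equal(unname(zg["a"]), (3 - 2) / sqrt(0.5))
  expect_equal(unname(zg["d"]), (1 - 2) / sqrt(0.5))
  # (2,1,1) example: z = +sqrt(2), -1/sqrt(2), -1/sqrt(2)
  net3 <- make_net(edge_df(c("u", "u"), c("v", "w"), c(0.9, 0.9)),
                   nodes = c("u", "v", "w"))
  z3 <- compute_zg(net3, c(u = 1L, v = 1L, w = 1L))
  expect_equal(unname(z3), c(sqrt(2), -1 / sqrt(2), -1 / sqrt(2)))
  # zero-variance cluster convention: all zg = 0
  expect_equal(unname(zg[c("e", "f")]), c(0, 0))
  # adding an inter-cluster edge changes no zg
  net_plus <- make_net(rbind(net$edges, edge_df("d", "f", 0.9)))
  expect_equal(compute_zg(net_plus, two_cluster_labels), zg)
  # cluster means of zg are 0 wherever the sd is nonzero
  expect_equal(mean(zg[c("a", "b", "c", "d")]), 0)
})

test_that("region assignment matches the nested-if oracle on a grid", {
  expect_identical(unname(assign_regions(0.9, 0)), "R4")
  expect_identical(unname(assign_regions(0.0, 3.0)), "R5")
  grid <- expand.grid(kpi = c(0, 0.04, 0.05, 0.3, 0.61, 0.62, 0.75, 0.799,
                              0.8, 0.95, 1),
                      zg = c(-2, 0, 2.49, 2.5, 3, 10))
  got <- assign_regions(grid$kpi, grid$zg)
  expect_identical(unname(got), oracle_region(grid$kpi, grid$zg))
  set.seed(2)
  kpi <- runif(300); zg <- rnorm(300, 1, 2)
  expect_identical(unname(assign_regions(kpi, zg)), oracle_region(kpi, zg))
})

test_that("k-means elbow selects k = 3 for three separated blobs", {
  set.seed(10)
  blob <- function(cx, cy, n = 30) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  x <- rbind(blob(0, 0), blob(10, 0), blob(5, 8))
  rownames(x) <- sprintf("n%02d", seq_len(nrow(x)))
  cl <- cluster_expression(x, k = "auto", k_max = 8L, seed = 1L)
  expect_equal(cl$k, 3L)
  expect_equal(length(unique(cl$labels)), 3L)
  # blob membership is recovered exactly (up to label permutation)
  truth <- rep(1:3, each = 30)
  expect_equal(length(unique(paste(truth, cl$labels))), 3L)
})

test_that("k-means SSE and determinism contracts hold", {
  set.seed(11)
  x <- matrix(rnorm(40 * 6), nrow = 40,
              dimnames = list(sprintf("n%02d", 1:40), NULL))
  # k = 1: SSE equals total SS around the grand centroid
  cl1 <- cluster_expression(x, k = 1L, seed = 1L)
  expect_equal(cl1$sse$sse, sum(sweep(x, 2, colMeans(x))^2))
  # same seed -> identical labels
  a <- cluster_expression(x, k = 4L, seed = 7L)
  b <- cluster_expression(x, k = 4L, seed = 7L)
  expect_identical(a$labels, b$labels)
  expect_error(cluster_expression(x, k = 41L), "between 1 and")
})

test_that("switch genes are exactly the fight-club nodes in R4", {
  # hand-built cartography: only the fight-club x R4 combination qualifies
  tab <- data.frame(
    gene_id = c("sw", "pos_r4", "fc_r3", "nh_r4"),
    cluster = 1L,
    kpi = c(0.9, 0.9, 0.7, 0.95),
    zg = c(0, 0, 0, 0),
    region = c("R4", "R4", "R3", "R4"),
    apcc = c(-0.8, 0.5, -0.8, -0.9),
    hub_class = c("fight_club", "party", "fight_club", "non_hub"),
    is_fight_club = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  tab$is_switch <- tab$is_fight_club & tab$region == "R4"
  net <- make_net(edge_df(c("sw", "sw", "pos_r4"),
                          c("fc_r3", "nh_r4", "nh_r4"),
                          c(-0.9, -0.85, 0.9)),
                  nodes = tab$gene_id)
  sw <- extract_switch_genes(tab, net)
  expect_identical(sw$switch_genes, "sw")
  expect_equal(sw$table$n_neg_partners, 2L)
  expect_equal(sw$table$n_pos_partners, 0L)
})

test_that("coordinates match naive oracles on random labelled graphs", {
  for (s in 1:100) {
    net <- random_net(n = 12L + (s %% 5L), p_edge = 0.35, seed = 200L + s)
    labels <- stats::setNames(sample(1:3, length(net$nodes), replace = TRUE),
                              net$nodes)
    kpi <- compute_kpi(net, labels)
    zg <- compute_zg(net, labels)
    expect_equal(kpi, oracle_kpi(net, labels), tolerance = 1e-12)
    expect_equal(zg, oracle_zg(net, labels), tolerance = 1e-12)
    expect_identical(unname(assign_regions(kpi, zg)),
                     oracle_region(kpi, zg))
  }
})

test_that("full cartography nests switch within fight-club within hubs", {
  d <- strong_design(seed = 2L)
  expr <- generate_expression(d)
  deg <- compute_deg(expr)
  net <- classify_hubs(build_network(expr, deg$gene_id[deg$pass]))
  carto <- build_cartography(net, expr, k = 3L, seed = 0L)
  sw <- extract_switch_genes(carto, net)
  hubs <- net$nodes[net$hub_class != "non_hub"]
  fc <- net$nodes[net$hub_class == "fight_club"]
  expect_true(all(sw$switch_genes %in% fc))
  expect_true(all(fc %in% hubs))
  expect_true(all(hubs %in% net$nodes))
  expect_true(all(carto$table$kpi >= 0 & carto$table$kpi <= 1))
})
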