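# Small fixtures built in code.

# expression matrix from a bare numeric matrix
make_expr <- function(values, condition = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(condition))
    condition <- rep(c("A", "B"), each = ncol(values) / 2)
  expression_matrix(values, stats::setNames(condition, colnames(values)))
}

# hand-built network skeleton (bypasses build_network) for topology tests
make_net <- function(edges, nodes = NULL, r_threshold = 0.8) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  net <- structure(list(nodes = nodes, edges = edges,
                        degree = NULL, apcc = NULL,
                        hub_class = stats::setNames(rep(NA_character_,
                                                        length(nodes)), nodes),
                        r_threshold = r_threshold),
                   class = "coexpression_network")
  net$degree <- network_degree(net)
  net$apcc <- compute_apcc(net)
  net
}

edge_df <- function(a, b, r) {
  data.frame(gene_a = a, gene_b = b, r = r, stringsAsFactors = FALSE)
}

# two rows with an exact target Pearson correlation
correlated_pair <- function(r, n = 20L, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y0 <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  y0 <- stats::residuals(stats::lm(y0 ~ x))
  y0 <- (y0 - mean(y0)) / stats::sd(y0)
  rbind(x, r * x + sqrt(1 - r^2) * y0)
}

# random small network via an Erdos-Renyi draw with random signed weights
random_net <- function(n = 15L, p_edge = 0.3, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- edge_df(ids[pairs[1L, keep]], ids[pairs[2L, keep]],
                   stats::runif(sum(keep), -1, 1))
  make_net(edges, nodes = ids)
}

# standard strong planted design shared by recovery tests
strong_design <- function(seed = 1L) synthetic_design(seed = seed)
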