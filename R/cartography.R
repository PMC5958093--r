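#' Cluster node expression profiles with k-means
#'
#' Clusters the genes (as points, samples as dimensions) with k-means,
#' choosing the best of `n_restarts` random starts by total within-cluster
#' sum of squares (SSE). With `k = "auto"` the SSE curve is computed for
#' k = 1..`k_max` and the elbow -- the k maximising the second difference
#' SSE(k-1) - 2 SSE(k) + SSE(k+1) -- is selected. Results are deterministic
#' given `seed`.
#'
#' @param x numeric matrix of node profiles (nodes x samples), or an
#'   [expression_matrix()] (all genes used).
#' @param k number of clusters, or `"auto"` for SSE-elbow selection.
#' @param k_max largest k scanned when `k = "auto"`.
#' @param n_restarts random restarts per k.
#' @param seed integer seed.
#' @return list with `labels` (named integer cluster per node), `k`, and
#'   `sse` (data.frame `k`, `sse` over the scanned range; a single row when
#'   `k` was given).
#' @export
cluster_expression <- function(x, k = "auto", k_max = 10L, n_restarts = 10L,
                               seed = 0L) {
  if (inherits(x, "expression_matrix")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  auto <- identical(k, "auto")
  if (!auto && (k < 1L || k > n)) stop("k must be between 1 and the number of nodes")
  set.seed(seed)
  sse_at <- function(kk) {
    if (kk == 1L) {
      centre <- colMeans(x)
      return(list(sse = sum(sweep(x, 2L, centre)^2),
                  labels = rep(1L, n)))
    }
    fit <- stats::kmeans(x, centers = kk, nstart = n_restarts,
                         iter.max = 100L)
    list(sse = fit$tot.withinss, labels = fit$cluster)
  }
  if (auto) {
    k_max <- min(k_max, n - 1L)
    if (k_max < 3L) stop("too few nodes for automatic k selection")
    fits <- lapply(seq_len(k_max), sse_at)
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    d2 <- sse[seq_len(k_max - 2L)] - 2 * sse[seq_len(k_max - 2L) + 1L] +
      sse[seq_len(k_max - 2L) + 2L]
    k_sel <- which.max(d2) + 1L
    labels <- fits[[k_sel]]$labels
    sse_df <- data.frame(k = seq_len(k_max), sse = sse)
    k <- k_sel
  } else {
    fit <- sse_at(as.integer(k))
    labels <- fit$labels
    sse_df <- data.frame(k = as.integer(k), sse = fit$sse)
  }
  list(labels = stats::setNames(as.integer(labels), rownames(x)),
       k = as.integer(k), sse = sse_df)
}

#' Clusterphobic coefficient K_pi
#'
#' K_pi(i) = 1 - (k_in / k_i)^2, where k_i is the node's degree in the
#' thresholded network and k_in the number of its links that stay inside its
#' own cluster. K_pi = 0 when every link is internal ("no fear" of being
#' confined to its cluster) and approaches 1 when almost all links leave the
#' cluster. Degree-0 nodes get K_pi = 0 by convention.
#'
#' @param net a `coexpression_network`.
#' @param labels named integer cluster label per node (all nodes covered).
#' @return named numeric vector in \[0, 1\].
#' @export
compute_kpi <- function(net, labels) {
  .check_labels(net, labels)
  lab <- labels[net$nodes]
  nb <- .neighbor_index(net)
  k <- net$degree
  k_in <- vapply(seq_along(net$nodes), function(i) {
    sum(lab[nb[[i]]] == lab[i])
  }, integer(1))
  kpi <- ifelse(k > 0, 1 - (k_in / k)^2, 0)
  stats::setNames(kpi, net$nodes)
}

#' Within-module degree z-score Z_g
#'
#' Z_g(i) = (kappa_i - mean(kappa, own cluster)) / sd(kappa, own cluster),
#' where kappa is the within-own-cluster degree on the thresholded network
#' and sd is the population standard deviation over the cluster's nodes.
#' Clusters with sd = 0 (all members equally connected) get Z_g = 0.
#'
#' @inheritParams compute_kpi
#' @return named numeric vector.
#' @export
compute_zg <- function(net, labels) {
  .check_labels(net, labels)
  lab <- labels[net$nodes]
  nb <- .neighbor_index(net)
  kappa <- vapply(seq_along(net$nodes), function(i) {
    sum(lab[nb[[i]]] == lab[i])
  }, integer(1))
  zg <- numeric(length(kappa))
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    m <- mean(kappa[idx])
    s <- sqrt(mean((kappa[idx] - m)^2))  # population sd
    zg[idx] <- if (s > 0) (kappa[idx] - m) / s else 0
  }
  stats::setNames(zg, net$nodes)
}

.check_labels <- function(net, labels) {
  if (is.null(names(labels)) || !all(net$nodes %in% names(labels)))
    stop("`labels` must be named and cover every network node")
}

#' Assign heat-cartography regions R1-R7
#'
#' Non-hubs (`zg < z_hub_cut`) fall into R1-R4 by K_pi; local hubs
#' (`zg >= z_hub_cut`) into R5-R7. Intervals are half-open and
#' lower-inclusive: with the default bounds, R1 = \[0, 0.05), R2 =
#' \[0.05, 0.62), R3 = \[0.62, 0.80), R4 = \[0.80, 1\] and R5 = \[0, 0.30),
#' R6 = \[0.30, 0.75), R7 = \[0.75, 1\]. R4 is the non-local-hub, highly
#' clusterphobic region where switch genes live.
#'
#' @param kpi,zg numeric vectors from [compute_kpi()] / [compute_zg()].
#' @param z_hub_cut Z_g boundary separating local hubs from non-hubs.
#' @param r_bounds_nonhub increasing K_pi cut points splitting R1|R2|R3|R4.
#' @param r_bounds_hub increasing K_pi cut points splitting R5|R6|R7.
#' @return character vector of regions (`"R1"`..`"R7"`), named like `kpi`.
#' @export
assign_regions <- function(kpi, zg, z_hub_cut = 2.5,
                           r_bounds_nonhub = c(0.05, 0.62, 0.80),
                           r_bounds_hub = c(0.30, 0.75)) {
  stopifnot(length(kpi) == length(zg))
  region <- character(length(kpi))
  nonhub <- zg < z_hub_cut
  region[nonhub] <- paste0("R", findInterval(kpi[nonhub], r_bounds_nonhub) + 1L)
  region[!nonhub] <- paste0("R", findInterval(kpi[!nonhub], r_bounds_hub) + 5L)
  stats::setNames(region, names(kpi))
}

#' Build the full heat-cartography table for a network
#'
#' Runs k-means on the node expression profiles, computes K_pi and Z_g on
#' the thresholded topology, assigns regions, and carries over APCC and the
#' hub classification.
#'
#' @param net a `coexpression_network` after [classify_hubs()].
#' @param expr the [expression_matrix()] the network was built from.
#' @param k clusters for [cluster_expression()] (`"auto"` or integer).
#' @param seed seed for the clustering.
#' @param ... further arguments to [assign_regions()].
#' @return list with `table` (data.frame: `gene_id`, `cluster`, `kpi`, `zg`,
#'   `region`, `apcc`, `hub_class`, `is_fight_club`, `is_switch`),
#'   `clustering` (the [cluster_expression()] result) and `labels`.
#' @export
build_cartography <- function(net, expr, k = 3L, seed = 0L, ...) {
  stopifnot(inherits(net, "coexpression_network"))
  if (all(is.na(net$hub_class)))
    stop("run classify_hubs() before build_cartography()")
  clus <- cluster_expression(expr$values[net$nodes, , drop = FALSE],
                             k = k, seed = seed)
  kpi <- compute_kpi(net, clus$labels)
  zg <- compute_zg(net, clus$labels)
  region <- assign_regions(kpi, zg, ...)
  tab <- data.frame(
    gene_id = net$nodes,
    cluster = as.integer(clus$labels[net$nodes]),
    kpi = as.numeric(kpi),
    zg = as.numeric(zg),
    region = as.character(region),
    apcc = as.numeric(net$apcc),
    hub_class = as.character(net$hub_class),
    is_fight_club = net$hub_class == "fight_club",
    is_switch = net$hub_class == "fight_club" & region == "R4",
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, clustering = clus, labels = clus$labels)
}

#' Extract switch genes from a cartography table
#'
#' Switch genes are the fight-club hubs (negative APCC, degree >= hub cut)
#' that fall in region R4 of the map: anti-correlated with their partners,
#' mostly inter-module links, not local hubs. For each switch gene the
#' numbers of negatively and positively correlated network partners are
#' reported.
#'
#' @param cartography result of [build_cartography()] (or its `$table`).
#' @param net the `coexpression_network` the cartography was computed on.
#' @return list with `switch_genes` (character vector) and `table`
#'   (data.frame `gene_id`, `kpi`, `zg`, `apcc`, `degree`, `n_neg_partners`,
#'   `n_pos_partners`).
#' @export
extract_switch_genes <- function(cartography, net) {
  tab <- if (is.data.frame(cartography)) cartography else cartography$table
  sw <- tab$gene_id[tab$is_switch]
  e <- net$edges
  n_neg <- vapply(sw, function(g) {
    sum(e$r < 0 & (e$gene_a == g | e$gene_b == g))
  }, integer(1))
  n_pos <- vapply(sw, function(g) {
    sum(e$r > 0 & (e$gene_a == g | e$gene_b == g))
  }, integer(1))
  idx <- match(sw, tab$gene_id)
  list(switch_genes = sw,
       table = data.frame(gene_id = sw,
                          kpi = tab$kpi[idx], zg = tab$zg[idx],
                          apcc = tab$apcc[idx],
                          degree = as.integer(net$degree[sw]),
                          n_neg_partners = unname(n_neg),
                          n_pos_partners = unname(n_pos),
                          stringsAsFactors = FALSE, row.names = NULL))
}
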