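#' Degree-preserving rewiring of a co-expression network
#'
#' Runs a double-edge-swap Markov chain: repeatedly pick two edges (a,b) and
#' (c,d), and replace them with (a,d),(c,b) (or (a,c),(b,d), chosen at
#' random) provided the move creates no self-loop and no multi-edge. Every
#' node keeps its exact degree. The chain runs until
#' `n_swaps_per_edge * |E|` swaps are accepted (or an attempt cap is hit,
#' with a warning -- e.g. a triangle admits no legal swap and is returned
#' unchanged).
#'
#' The expression data are untouched; only the topology shuffles. Each
#' rewired edge's signed weight is re-computed as the Pearson r between its
#' two endpoints' actual profiles when `expr` is supplied (default policy;
#' the null deliberately breaks the correlation-topology coupling, so
#' `|r| >= r_threshold` need not hold), or drawn by permuting the original
#' r values over edges when `sign_policy = "permute"`.
#'
#' @param net a `coexpression_network`.
#' @param expr the [expression_matrix()] the network came from (needed for
#'   `sign_policy = "recompute"`).
#' @param n_swaps_per_edge target accepted swaps per edge (chain length).
#' @param seed integer seed.
#' @param sign_policy `"recompute"` (Pearson r of the new endpoint pair) or
#'   `"permute"` (shuffle the original edge weights onto the new edges).
#' @return the rewired `coexpression_network` (degree identical, APCC and
#'   hub class recomputed on the new neighbour sets), with attributes
#'   `swap_attempts` and `swaps_accepted`.
#' @export
rewire_network <- function(net, expr = NULL, n_swaps_per_edge = 10,
                           seed = 0L, sign_policy = c("recompute", "permute")) {
  stopifnot(inherits(net, "coexpression_network"))
  sign_policy <- match.arg(sign_policy)
  if (sign_policy == "recompute" && is.null(expr))
    stop("sign_policy = 'recompute' needs the expression matrix")
  m <- nrow(net$edges)
  if (m < 2L) {
    warning("fewer than 2 edges; network returned unchanged")
    return(net)
  }
  set.seed(seed)
  n <- length(net$nodes)
  ea <- match(net$edges$gene_a, net$nodes)
  eb <- match(net$edges$gene_b, net$nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE
  target <- ceiling(n_swaps_per_edge * m)
  max_attempts <- max(200L * target, 1000L)
  accepted <- 0L
  attempts <- 0L
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(m, 2L)
    a <- ea[ij[1L]]; b <- eb[ij[1L]]
    c_ <- ea[ij[2L]]; d <- eb[ij[2L]]
    if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # proposed new edges: (a,d) and (c_,b)
    if (a == d || c_ == b) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    ea[ij[1L]] <- a; eb[ij[1L]] <- d
    ea[ij[2L]] <- c_; eb[ij[2L]] <- b
    accepted <- accepted + 1L
  }
  if (accepted < target)
    warning(sprintf("rewiring stopped after %d attempts with %d/%d accepted swaps",
                    attempts, accepted, target))
  ga <- net$nodes[pmin(ea, eb)]
  gb <- net$nodes[pmax(ea, eb)]
  r <- if (sign_policy == "recompute") {
    x <- expr$values
    vapply(seq_len(m), function(i) stats::cor(x[ga[i], ], x[gb[i], ]),
           numeric(1))
  } else {
    sample(net$edges$r, m)
  }
  out <- net
  out$edges <- data.frame(gene_a = ga, gene_b = gb, r = r,
                          stringsAsFactors = FALSE)
  out$degree <- network_degree(out)
  out$apcc <- compute_apcc(out)
  if (!is.null(out$hub_degree))
    out <- classify_hubs(out, out$hub_degree, out$party_cut)
  attr(out, "swap_attempts") <- attempts
  attr(out, "swaps_accepted") <- accepted
  out
}

#' Switch-gene counts under the degree-preserving null
#'
#' For each replicate: rewire the network, recompute APCC over the new
#' neighbour sets from the original expression profiles, re-classify hubs,
#' recompute K_pi and Z_g on the rewired topology while KEEPING the original
#' expression-based k-means clusters (rewiring does not change expression,
#' so the clustering is unchanged), re-assign regions and count switch
#' genes. The observed switch set should exceed the null counts when the
#' anti-correlated inter-module structure is real.
#'
#' @param net a classified `coexpression_network`.
#' @param expr the [expression_matrix()] behind it.
#' @param labels named cluster labels from the observed cartography.
#' @param n_replicates number of rewired replicates.
#' @param n_swaps_per_edge chain length per replicate (see
#'   [rewire_network()]).
#' @param seed integer seed; replicate i uses `seed + i`.
#' @param sign_policy edge-weight policy for the rewired networks (see
#'   [rewire_network()]). The default `"permute"` shuffles the observed
#'   signed weights onto the rewired edges: it preserves the network's
#'   weight distribution while breaking the weight-topology coupling, so
#'   the null isolates the contribution of the topology. `"recompute"`
#'   instead re-derives each rewired edge's r from the endpoint profiles;
#'   note that in strongly mean-shifted two-condition data this
#'   re-introduces the block anti-correlations between up- and
#'   down-regulated genes and the null is no longer flat.
#' @param ... passed on to [assign_regions()].
#' @return data.frame with one row per replicate: `replicate_id`,
#'   `n_switch_null`, `n_fight_club_null`, `swap_attempts`,
#'   `swaps_accepted`, `seed`; plus attribute `null_switch_ids` (list of the
#'   null switch-gene sets).
#' @export
null_switch_count <- function(net, expr, labels, n_replicates = 20L,
                              n_swaps_per_edge = 10, seed = 0L,
                              sign_policy = c("permute", "recompute"), ...) {
  sign_policy <- match.arg(sign_policy)
  rows <- vector("list", n_replicates)
  sets <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    rseed <- seed + i
    rnet <- rewire_network(net, expr, n_swaps_per_edge = n_swaps_per_edge,
                           seed = rseed, sign_policy = sign_policy)
    kpi <- compute_kpi(rnet, labels)
    zg <- compute_zg(rnet, labels)
    region <- assign_regions(kpi, zg, ...)
    is_sw <- rnet$hub_class == "fight_club" & region == "R4"
    rows[[i]] <- data.frame(
      replicate_id = i,
      n_switch_null = sum(is_sw),
      n_fight_club_null = sum(rnet$hub_class == "fight_club"),
      swap_attempts = attr(rnet, "swap_attempts"),
      swaps_accepted = attr(rnet, "swaps_accepted"),
      seed = rseed)
    sets[[i]] <- rnet$nodes[is_sw]
  }
  out <- if (n_replicates > 0L) do.call(rbind, rows) else
    data.frame(replicate_id = integer(0), n_switch_null = integer(0),
               n_fight_club_null = integer(0), swap_attempts = integer(0),
               swaps_accepted = integer(0), seed = integer(0))
  attr(out, "null_switch_ids") <- sets
  out
}
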