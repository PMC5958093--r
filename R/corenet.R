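#' Build the signed Pearson co-expression network over the DEGs
#'
#' Computes all-pairs Pearson correlation between the expression profiles of
#' the given genes over ALL samples (both conditions pooled -- the
#' anti-correlation that defines switch genes only emerges in the pooled
#' profile) and keeps an edge wherever `|r| >= r_threshold`, storing the
#' signed r. Isolated genes stay in the node set with degree 0. Genes with
#' zero variance across samples have no defined correlation and are excluded
#' from the node set with a warning.
#'
#' The per-node Average Pearson Correlation Coefficient (APCC) -- the mean
#' signed r over a node's neighbours -- is computed here; it is `NA` for
#' degree-0 nodes.
#'
#' @param expr an [expression_matrix()].
#' @param deg_ids gene identifiers to include (typically the DEG call set);
#'   must be a subset of `expr`'s genes.
#' @param r_threshold absolute-correlation threshold for drawing an edge
#'   (kept when `|r| >= r_threshold`).
#' @return an object of class `coexpression_network`: list with `nodes`
#'   (character), `edges` (data.frame `gene_a`, `gene_b`, `r`; each unordered
#'   pair once, `gene_a < gene_b`), `degree`, `apcc` and `hub_class` (all
#'   named by node; `hub_class` is NA until [classify_hubs()]), and
#'   `r_threshold`.
#' @export
build_network <- function(expr, deg_ids, r_threshold = 0.8) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing_g <- setdiff(deg_ids, expr$gene_ids)
  if (length(missing_g))
    stop("deg_ids not in expression matrix: ", missing_g[1L])
  if (ncol(expr$values) < 3L) stop("need >= 3 samples for a correlation network")
  x <- expr$values[deg_ids, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from the network: ",
            paste(utils::head(deg_ids[sds == 0], 5L), collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(x)
  n <- length(nodes)
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  if (n >= 2L) {
    cm <- stats::cor(t(x))
    keep <- abs(cm) >= r_threshold & upper.tri(cm)
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(gene_a = nodes[idx[, 1L]],
                          gene_b = nodes[idx[, 2L]],
                          r = cm[idx], stringsAsFactors = FALSE)
    }
  }
  net <- structure(list(nodes = nodes, edges = edges,
                        degree = NULL, apcc = NULL,
                        hub_class = stats::setNames(rep(NA_character_, n), nodes),
                        r_threshold = r_threshold),
                   class = "coexpression_network")
  net$degree <- network_degree(net)
  net$apcc <- compute_apcc(net)
  net
}

#' Per-node degree of a co-expression network
#'
#' @param net a `coexpression_network`.
#' @return named integer vector over all nodes (0 for isolated nodes).
#' @export
network_degree <- function(net) {
  d <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                    levels = net$nodes))
  stats::setNames(as.integer(d), net$nodes)
}

#' Average Pearson Correlation Coefficient per node
#'
#' Mean of the signed edge correlations over each node's neighbours;
#' NA for isolated nodes.
#'
#' @param net a `coexpression_network`.
#' @return named numeric vector in \[-1, 1\].
#' @export
compute_apcc <- function(net) {
  ends <- factor(c(net$edges$gene_a, net$edges$gene_b), levels = net$nodes)
  s <- tapply(c(net$edges$r, net$edges$r), ends, sum, default = 0)
  d <- network_degree(net)
  out <- as.numeric(s) / ifelse(d > 0, d, NA_real_)
  stats::setNames(out, net$nodes)
}

#' Classify hubs as date, party or fight-club by APCC
#'
#' A hub is a node with degree at least `hub_degree`. Hubs with negative
#' APCC -- mainly anti-correlated with their neighbours -- are fight-club
#' hubs; hubs with APCC at or above `party_cut` are party hubs; the
#' remaining hubs are date hubs. Nodes below the degree cut are `non_hub`.
#'
#' @param net a `coexpression_network` (APCC already computed).
#' @param hub_degree minimum degree of a hub.
#' @param party_cut APCC boundary between date and party hubs.
#' @return the network with `hub_class` filled in
#'   (`party` / `date` / `fight_club` / `non_hub`).
#' @export
classify_hubs <- function(net, hub_degree = 5L, party_cut = 0.8) {
  stopifnot(inherits(net, "coexpression_network"))
  cls <- rep("non_hub", length(net$nodes))
  hub <- net$degree >= hub_degree
  cls[hub & net$apcc < 0] <- "fight_club"
  cls[hub & net$apcc >= party_cut] <- "party"
  cls[hub & net$apcc >= 0 & net$apcc < party_cut] <- "date"
  net$hub_class <- stats::setNames(cls, net$nodes)
  net$hub_degree <- hub_degree
  net$party_cut <- party_cut
  net
}

#' Summary counts of a co-expression network
#'
#' @param object a `coexpression_network`.
#' @param ... unused.
#' @return list with `n_nodes`, `n_edges`, `n_hubs` and per-class hub counts.
#' @export
summary.coexpression_network <- function(object, ...) {
  cls <- object$hub_class
  list(n_nodes = length(object$nodes),
       n_edges = nrow(object$edges),
       n_hubs = sum(cls %in% c("party", "date", "fight_club")),
       n_party = sum(cls == "party", na.rm = TRUE),
       n_date = sum(cls == "date", na.rm = TRUE),
       n_fight_club = sum(cls == "fight_club", na.rm = TRUE))
}

#' @export
print.coexpression_network <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("coexpression_network: %d nodes, %d edges (|r| >= %g)\n",
              s$n_nodes, s$n_edges, x$r_threshold))
  if (!all(is.na(x$hub_class)))
    cat(sprintf("hubs: %d (%d party, %d date, %d fight-club)\n",
                s$n_hubs, s$n_party, s$n_date, s$n_fight_club))
  invisible(x)
}

#' Write the edge list of a network as TSV
#'
#' @param net a `coexpression_network`.
#' @param path output path; columns `gene_a`, `gene_b`, `r`.
#' @export
write_edges <- function(net, path) write_table(net$edges, path)

# adjacency list used by the cartography / null-model internals
.neighbor_index <- function(net) {
  n <- length(net$nodes)
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  nb <- vector("list", n)
  if (length(ia)) {
    ends <- c(ia, ib); other <- c(ib, ia)
    o <- order(ends)
    nb_split <- split(other[o], factor(ends[o], levels = seq_len(n)))
    nb <- unname(nb_split)
  } else nb <- rep(list(integer(0)), n)
  nb
}
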