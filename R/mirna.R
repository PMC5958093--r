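#' Read a miRNA -> target map from a two-column TSV
#'
#' The lingua-franca format exportable from target-prediction databases:
#' one interaction per row, columns miRNA ID and target gene ID. The map's
#' universe M is the set of all distinct target genes appearing in it.
#'
#' @param path TSV path (header required).
#' @return a `target_map` data.frame with columns `mirna`, `target`.
#' @export
read_target_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("target map needs two columns (mirna, target)")
  out <- data.frame(mirna = as.character(tab[[1L]]),
                    target = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$mirna) || anyNA(out$target) || any(!nzchar(out$mirna)))
    stop("empty miRNA identifier or target in target map")
  class(out) <- c("target_map", "data.frame")
  out
}

# upper-tail hypergeometric probability P(overlap >= X) computed as the
# printed formula p = 1 - sum_{i=0}^{X-1} C(K,i) C(M-K,N-i) / C(M,N),
# with each term evaluated in log space so genome-scale M does not overflow.
.hyper_tail <- function(X, K, M, N) {
  if (X <= 0L) return(1)
  i <- 0:(X - 1L)
  valid <- (N - i) >= 0L & (N - i) <= (M - K) & i <= K
  if (!any(valid)) return(1)  # overlap < X impossible nowhere: all mass >= X
  terms <- exp(lchoose(K, i[valid]) + lchoose(M - K, N - i[valid]) -
                 lchoose(M, N))
  max(0, min(1, 1 - sum(terms)))
}

#' Hypergeometric miRNA-target enrichment of a gene list
#'
#' For each miRNA in the map, tests whether the input gene list is enriched
#' in that miRNA's targets. With M the size of the map's target universe,
#' K the miRNA's target count, N the number of input genes present in the
#' universe and X the number of input genes targeted by the miRNA, the
#' p-value is the upper-tail hypergeometric probability
#' `p = 1 - sum_{i=0}^{X-1} C(K,i) C(M-K,N-i) / C(M,N)`,
#' i.e. the probability of an overlap at least as large as observed when N
#' genes are drawn from the universe at random. Significance is judged on
#' the raw p at `alpha`; a BH-adjusted column is reported alongside.
#'
#' @param gene_list character vector of gene identifiers (e.g. the switch
#'   genes). Genes absent from the map's universe are dropped from N with a
#'   message.
#' @param map a `target_map` (see [read_target_map()] /
#'   [generate_target_map()]).
#' @param alpha raw-p significance threshold.
#' @return data.frame sorted by increasing p: `mirna_id`, `M`, `K`, `N`,
#'   `X`, `p`, `adjusted_p`, `significant`.
#' @export
enrich_targets <- function(gene_list, map, alpha = 0.05) {
  stopifnot(is.data.frame(map), all(c("mirna", "target") %in% names(map)))
  if (!nrow(map)) stop("empty target map")
  universe <- unique(map$target)
  M <- length(universe)
  in_map <- unique(gene_list[gene_list %in% universe])
  dropped <- length(unique(gene_list)) - length(in_map)
  if (dropped > 0L)
    message(dropped, " input gene(s) absent from the target universe dropped")
  N <- length(in_map)
  if (N == 0L) {
    warning("no input gene is in the target universe; empty result")
    return(data.frame(mirna_id = character(0), M = integer(0), K = integer(0),
                      N = integer(0), X = integer(0), p = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  }
  sets <- split(map$target, map$mirna)
  K <- vapply(sets, function(s) length(unique(s)), integer(1))
  X <- vapply(sets, function(s) sum(in_map %in% s), integer(1))
  p <- vapply(seq_along(sets), function(i) .hyper_tail(X[i], K[i], M, N),
              numeric(1))
  out <- data.frame(mirna_id = names(sets), M = M, K = unname(K), N = N,
                    X = unname(X), p = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    significant = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$mirna_id), , drop = FALSE]
}
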