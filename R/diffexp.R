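#' Differentially expressed genes between the two conditions
#'
#' Per-gene Welch two-sample t-test on the log2 values, two-sided, with
#' Benjamini-Hochberg adjustment across all tested genes. A gene is called
#' differentially expressed when `adjusted_p < alpha` AND its linear-scale
#' fold change `2^|log2FC|` is at least `fc_threshold`. The full table is
#' returned, passers flagged, so the adjustment universe is visible.
#'
#' `log2_fold_change` is mean(condition A) - mean(condition B), where A is
#' the first condition level of `expr`. Genes with zero variance in both
#' groups get p = 1 when the group means are equal (retained, so the BH `m`
#' matches the tested universe) and p = 0 when they differ.
#'
#' @param expr an [expression_matrix()] on the log2 scale.
#' @param alpha adjusted-p significance threshold.
#' @param fc_threshold linear-scale fold-change threshold (a value of 3.3
#'   corresponds to `|log2FC| >= log2(3.3) ~ 1.72`).
#' @return data.frame with one row per gene: `gene_id`, `log2_fold_change`,
#'   `fold_change` (linear, >= 1), `raw_p`, `adjusted_p`, `direction`
#'   (`up_in_A` / `down_in_A`) and logical `pass`.
#' @export
compute_deg <- function(expr, alpha = 0.05, fc_threshold = 3.3) {
  stopifnot(inherits(expr, "expression_matrix"))
  lev <- levels(expr$condition)
  ia <- expr$condition == lev[1L]
  ib <- expr$condition == lev[2L]
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("each condition needs >= 2 samples for the Welch test")
  xa <- expr$values[, ia, drop = FALSE]
  xb <- expr$values[, ib, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  p <- numeric(length(lfc))
  pos <- se2 > 0
  tt <- lfc[pos] / sqrt(se2[pos])
  df <- se2[pos]^2 / ((va[pos] / na)^2 / (na - 1L) +
                      (vb[pos] / nb)^2 / (nb - 1L))
  p[pos] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # degenerate genes: no within-group variance at all
  p[!pos] <- ifelse(lfc[!pos] == 0, 1, 0)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = expr$gene_ids,
    log2_fold_change = lfc,
    fold_change = 2^abs(lfc),
    raw_p = p,
    adjusted_p = adj,
    direction = ifelse(lfc >= 0, "up_in_A", "down_in_A"),
    pass = adj < alpha & 2^abs(lfc) >= fc_threshold,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "conditions") <- lev
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  out
}

#' Up/down breakdown of a DEG table
#'
#' Counts and integer percentages of passing genes by direction, e.g. a
#' 1428-gene call set with 879 down-regulated genes is 62% down / 38% up.
#'
#' @param table a table from [compute_deg()] (only `pass` rows are counted),
#'   or any data.frame with `direction` and optional `pass` columns.
#' @return list with `n_up`, `n_down`, `pct_up`, `pct_down` (percent,
#'   rounded to the nearest integer; all zero for an empty call set).
#' @export
deg_direction_summary <- function(table) {
  stopifnot(is.data.frame(table), "direction" %in% names(table))
  if ("pass" %in% names(table)) table <- table[table$pass, , drop = FALSE]
  n_up <- sum(table$direction == "up_in_A")
  n_down <- sum(table$direction == "down_in_A")
  n <- n_up + n_down
  list(n_up = n_up, n_down = n_down,
       pct_up = if (n) round(100 * n_up / n) else 0,
       pct_down = if (n) round(100 * n_down / n) else 0)
}
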