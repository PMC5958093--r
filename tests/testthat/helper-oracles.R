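# Independent oracles: deliberately naive step-by-step reimplementations
# used to cross-check the package's vectorized code paths.

# Benjamini-Hochberg by the step-up definition: sort p, find the largest i
# with p_(i) <= i * alpha / m, reject ranks 1..i.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# textbook Pearson r, scalar loops only
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all-pairs double loop edge list at a threshold
oracle_edges <- function(mat, thr) {
  ids <- rownames(mat)
  out <- list()
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in (i + 1L):nrow(mat)) {
      r <- oracle_pearson(mat[i, ], mat[j, ])
      if (abs(r) >= thr)
        out[[length(out) + 1L]] <- data.frame(gene_a = ids[i], gene_b = ids[j],
                                              r = r)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(0), gene_b = character(0), r = numeric(0))
}

# per-node naive hub classification
oracle_hub_class <- function(net, hub_degree, party_cut) {
  vapply(net$nodes, function(g) {
    inc <- net$edges$gene_a == g | net$edges$gene_b == g
    k <- sum(inc)
    if (k < hub_degree) return("non_hub")
    apcc <- mean(net$edges$r[inc])
    if (apcc < 0) "fight_club" else if (apcc >= party_cut) "party" else "date"
  }, character(1))
}

# naive clusterphobic coefficient: 1 - (k_in / k)^2
oracle_kpi <- function(net, labels) {
  vapply(net$nodes, function(g) {
    nb <- c(net$edges$gene_b[net$edges$gene_a == g],
            net$edges$gene_a[net$edges$gene_b == g])
    if (!length(nb)) return(0)
    1 - (sum(labels[nb] == labels[g]) / length(nb))^2
  }, numeric(1))
}

# naive within-module degree z-score with population sd
oracle_zg <- function(net, labels) {
  kappa <- vapply(net$nodes, function(g) {
    nb <- c(net$edges$gene_b[net$edges$gene_a == g],
            net$edges$gene_a[net$edges$gene_b == g])
    sum(labels[nb] == labels[g])
  }, numeric(1))
  out <- numeric(length(kappa))
  names(out) <- net$nodes
  for (cl in unique(labels[net$nodes])) {
    idx <- names(which(labels[net$nodes] == cl))
    mu <- mean(kappa[idx])
    sdev <- sqrt(sum((kappa[idx] - mu)^2) / length(idx))
    out[idx] <- if (sdev > 0) (kappa[idx] - mu) / sdev else 0
  }
  out
}

# nested-if region oracle encoding the documented bounds
oracle_region <- function(kpi, zg, z_hub_cut = 2.5) {
  mapply(function(kp, z) {
    if (z < z_hub_cut) {
      if (kp < 0.05) "R1"
      else if (kp < 0.62) "R2"
      else if (kp < 0.80) "R3"
      else "R4"
    } else {
      if (kp < 0.30) "R5"
      else if (kp < 0.75) "R6"
      else "R7"
    }
  }, kpi, zg, USE.NAMES = FALSE)
}

# exhaustive hypergeometric upper tail: enumerate all C(M, N) draws of N
# from a universe 1..M whose first K elements are the miRNA's targets
oracle_hyper_tail <- function(X, K, M, N) {
  if (N == 0L) return(if (X <= 0L) 1 else 0)
  draws <- utils::combn(M, N)
  overlap <- colSums(draws <= K)
  mean(overlap >= X)
}

# textbook log-rank: O - E and hypergeometric variance summed over the
# distinct event times
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
  }
  chisq <- (O1 - E1)^2 / V
  list(statistic = chisq, p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

# hand product-limit estimator at the distinct observed times
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}
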