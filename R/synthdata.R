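#' Design of a planted two-condition expression experiment
#'
#' Describes a synthetic dataset with the statistical structure the
#' switch-gene pipeline assumes: two conditions, blocks of condition-up and
#' condition-down genes organised into positively co-expressed modules
#' (latent-factor model), and a planted set of "switch" genes that are
#' anti-correlated with the first module's latent factor and shifted in the
#' opposite direction between conditions. Remaining genes are unstructured
#' background noise.
#'
#' Each module member is generated as `loading * factor + noise`, with the
#' loading solved from `within_module_rho` so that the expected pairwise
#' Pearson correlation of two members equals `within_module_rho` within a
#' condition. Planted switch genes load negatively on module 1's factor with
#' a loading solved so that their expected correlation with module-1 members
#' equals `switch_anticorr_rho`; this requires
#' `abs(switch_anticorr_rho) <= sqrt(within_module_rho)`.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_condition samples per condition (two conditions).
#' @param module_sizes integer vector of module sizes; modules alternate
#'   up/down regulation between conditions starting with up.
#' @param n_switch number of planted switch genes (anti-correlated with
#'   module 1, regulated opposite to it).
#' @param fold_change_signal linear-scale mean ratio between conditions for
#'   the differentially expressed blocks; planted as an additive shift of
#'   `log2(fold_change_signal)` on the log2 scale. 1 = no signal.
#' @param within_module_rho target pairwise correlation inside a module,
#'   in \[0, 1\].
#' @param switch_anticorr_rho target correlation of a planted switch gene
#'   with module-1 members, in \[-1, 0\].
#' @param noise_sd standard deviation of the per-gene noise term (log2
#'   units). Note the between-condition mean shift alone induces a pooled
#'   correlation of `(d/2)^2 / ((d/2)^2 + v)` (d = log2 fold change, v =
#'   within-condition variance) between any two co-directional DE genes;
#'   `noise_sd` must be large enough relative to the shift that this
#'   baseline stays clear of the network's edge threshold, otherwise whole
#'   cross-module blocks join the network. The default keeps it near 0.47
#'   with the default fold change (threshold 0.8, margin > 4 sampling sds).
#' @param base_mean grand mean expression on the log2 scale.
#' @param seed integer seed; each generator derives an independent substream
#'   from it, so adding a generator call does not perturb earlier outputs.
#' @return an object of class `synthetic_design` (a list of the validated
#'   fields plus `gene_ids`, `module_members` (list of ID vectors),
#'   `module_directions` (+1 up / -1 down in condition A),
#'   `planted_switch_ids` and `background_ids`).
#' @export
synthetic_design <- function(n_genes = 300L,
                             n_samples_per_condition = 20L,
                             module_sizes = c(60L, 60L, 60L),
                             n_switch = 15L,
                             fold_change_signal = 8,
                             within_module_rho = 0.9,
                             switch_anticorr_rho = -0.9,
                             noise_sd = 0.5,
                             base_mean = 6,
                             seed = 1L) {
  if (n_genes < 1L || n_samples_per_condition < 2L)
    stop("non-positive or too-small sizes: need n_genes >= 1 and ",
         "n_samples_per_condition >= 2")
  if (any(module_sizes < 1L) || n_switch < 0L)
    stop("non-positive sizes in module_sizes / n_switch")
  if (sum(module_sizes) + n_switch > n_genes)
    stop("sum(module_sizes) + n_switch exceeds n_genes")
  if (within_module_rho < 0 || within_module_rho > 1)
    stop("within_module_rho outside [0, 1]")
  if (switch_anticorr_rho < -1 || switch_anticorr_rho > 0)
    stop("switch_anticorr_rho outside [-1, 0]")
  if (abs(switch_anticorr_rho) > sqrt(within_module_rho) + 1e-12)
    stop("abs(switch_anticorr_rho) cannot exceed sqrt(within_module_rho) ",
         "under the latent-factor model")
  if (fold_change_signal <= 0) stop("fold_change_signal must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  k <- length(module_sizes)
  ends <- cumsum(module_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  module_members <- lapply(seq_len(k),
                           function(m) gene_ids[starts[m]:ends[m]])
  names(module_members) <- paste0("module", seq_len(k))
  planted <- if (n_switch > 0L)
    gene_ids[(ends[k] + 1L):(ends[k] + n_switch)] else character(0)
  background <- setdiff(gene_ids, c(unlist(module_members), planted))

  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    gene_ids = gene_ids,
    n_modules = k,
    module_sizes = as.integer(module_sizes),
    module_members = module_members,
    module_directions = rep_len(c(1, -1), k),
    planted_switch_ids = planted,
    background_ids = background,
    fold_change_signal = fold_change_signal,
    within_module_rho = within_module_rho,
    switch_anticorr_rho = switch_anticorr_rho,
    noise_sd = noise_sd,
    base_mean = base_mean,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

# Independent substreams: one global seed, fixed offset per generator, so the
# expression draw is identical whether or not a target map is also generated.
.substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
}

# Module factors: standard-normal draws that are then centered within each
# condition, decorrelated across modules (QR) and standardized to unit
# sample variance. The planted structure (pairwise correlations, fold
# changes) is thereby realized exactly in every draw instead of only in
# expectation: no factor carries a spurious condition difference that would
# shift a whole block's observed fold change, and no two modules share a
# sampling correlation that could push an entire cross-module block over
# the network's edge threshold.
.draw_factors <- function(n_modules, n_s, cond_sign) {
  n_tot <- 2L * n_s
  if (n_tot < n_modules + 3L)
    stop("need at least n_modules + 3 samples for decorrelated factors")
  f <- matrix(stats::rnorm(n_modules * n_tot), nrow = n_tot)
  for (cond in unique(cond_sign))
    f[cond_sign == cond, ] <- scale(f[cond_sign == cond, , drop = FALSE],
                                    center = TRUE, scale = FALSE)
  q <- qr.Q(qr(f))
  t(q) * sqrt(n_tot - 1)
}

#' Generate a two-condition expression matrix from a planted design
#'
#' Samples the latent-factor model described in [synthetic_design()]: one
#' factor per module (standard-normal draws, centered within each condition
#' and decorrelated across modules, so the planted correlation and
#' fold-change structure is realized exactly in every draw); module members
#' load positively on their module's factor, planted switch genes load
#' negatively on module 1's factor; differential expression enters as an
#' additive log2-scale mean shift of `+/- log2(fold_change_signal)/2` per
#' condition. Condition labels are `"A"` and `"B"`.
#'
#' @param design a [synthetic_design()].
#' @return an [expression_matrix()] (log2 scale).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  .substream(design$seed, 0L)
  n_s <- design$n_samples_per_condition
  n <- design$n_genes
  sample_ids <- c(sprintf("A_s%02d", seq_len(n_s)),
                  sprintf("B_s%02d", seq_len(n_s)))
  condition <- rep(c("A", "B"), each = n_s)
  cond_sign <- rep(c(1, -1), each = n_s)  # +1 in A, -1 in B

  sigma <- design$noise_sd
  rho <- design$within_module_rho
  # loading a with corr(member_i, member_j) = a^2 / (a^2 + sigma^2) = rho
  a_mod <- if (rho < 1) sigma * sqrt(rho / (1 - rho)) else Inf
  # switch loading: corr(switch, member) = c_m * a_s / sqrt(a_s^2 + sigma^2)
  # with c_m = sqrt(rho); solve for a_s given target t = |switch_anticorr_rho|
  t_abs <- abs(design$switch_anticorr_rho)
  a_sw <- if (t_abs == 0 || rho == 0) 0 else {
    frac <- t_abs / sqrt(rho)           # = a_s / sqrt(a_s^2 + sigma^2)
    sigma * frac / sqrt(1 - frac^2)
  }

  delta <- log2(design$fold_change_signal)
  x <- matrix(stats::rnorm(n * 2L * n_s, sd = sigma), nrow = n,
              dimnames = list(design$gene_ids, sample_ids))
  factors <- .draw_factors(design$n_modules, n_s, cond_sign)
  for (m in seq_len(design$n_modules)) {
    idx <- match(design$module_members[[m]], design$gene_ids)
    x[idx, ] <- x[idx, , drop = FALSE] +
      rep(a_mod * factors[m, ], each = length(idx)) +
      rep(design$module_directions[m] * cond_sign * delta / 2,
          each = length(idx))
  }
  if (length(design$planted_switch_ids)) {
    idx <- match(design$planted_switch_ids, design$gene_ids)
    sw_dir <- -design$module_directions[1L]
    x[idx, ] <- x[idx, , drop = FALSE] +
      rep(-a_sw * factors[1L, ], each = length(idx)) +
      rep(sw_dir * cond_sign * delta / 2, each = length(idx))
  }
  x <- x + design$base_mean
  expression_matrix(x, stats::setNames(condition, sample_ids))
}

#' Generate a miRNA -> target map with one enriched miRNA
#'
#' Every miRNA receives `targets_per_mirna` target genes sampled without
#' replacement from the design's full gene universe. The first miRNA
#' (`"miR-01"`, the designated enriched one) samples with weight
#' `enrich_factor` on the planted switch genes and weight 1 elsewhere;
#' all other miRNAs sample uniformly. `enrich_factor = 1` therefore yields
#' the hypergeometric null for every miRNA.
#'
#' @param design a [synthetic_design()].
#' @param n_mirnas number of miRNAs (>= 1).
#' @param enrich_factor sampling weight multiplier (>= 1) of planted switch
#'   genes for the designated miRNA.
#' @param targets_per_mirna target-set size per miRNA; default 10% of the
#'   gene universe.
#' @return a data.frame with columns `mirna` and `target` (class
#'   `target_map` layered on data.frame), one row per interaction; attribute
#'   `designated` names the enriched miRNA.
#' @export
generate_target_map <- function(design, n_mirnas = 30L, enrich_factor = 20,
                                targets_per_mirna = max(1L, round(0.1 * design$n_genes))) {
  stopifnot(inherits(design, "synthetic_design"))
  if (n_mirnas < 1L) stop("n_mirnas must be >= 1")
  if (enrich_factor < 1) stop("enrich_factor must be >= 1")
  universe <- design$gene_ids
  if (!length(universe)) stop("empty gene universe")
  if (targets_per_mirna > length(universe))
    stop("targets_per_mirna exceeds the gene universe")
  .substream(design$seed, 1L)
  mirna_ids <- sprintf("miR-%02d", seq_len(n_mirnas))
  w <- ifelse(universe %in% design$planted_switch_ids, enrich_factor, 1)
  rows <- lapply(seq_len(n_mirnas), function(i) {
    prob <- if (i == 1L) w else NULL
    data.frame(mirna = mirna_ids[i],
               target = sample(universe, targets_per_mirna, prob = prob),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "designated") <- mirna_ids[1L]
  class(out) <- c("target_map", "data.frame")
  out
}

#' Generate an exponential survival cohort driven by one gene
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^I(expression > median)`. Censoring is
#' independent of group: each subject is censored with probability
#' `censor_rate`, at a time drawn uniformly on (0, event time), so
#' `censor_rate = 1` yields an all-censored cohort.
#'
#' @param gene_expr numeric vector of per-patient expression for one gene.
#' @param hazard_ratio hazard multiplier (> 0) for the above-median group.
#' @param baseline_hazard exponential event rate (> 0) of the below-median
#'   group (per unit follow-up time).
#' @param censor_rate probability in \[0, 1\] that a subject is censored.
#' @param seed integer seed.
#' @param gene_id column name used for the expression column.
#' @return a data.frame (`survival_cohort`) with columns `patient_id`,
#'   `time`, `event` (1 = death observed, 0 = censored) and one expression
#'   column named `gene_id`.
#' @export
generate_survival <- function(gene_expr, hazard_ratio = 4,
                              baseline_hazard = 0.1, censor_rate = 0.1,
                              seed = 1L, gene_id = "gene") {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate outside [0, 1]")
  n <- length(gene_expr)
  if (n < 2L) stop("need at least 2 patients")
  .substream(seed, 2L)
  high <- gene_expr > stats::median(gene_expr)
  rate <- baseline_hazard * hazard_ratio^as.numeric(high)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  out <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                    time = time,
                    event = as.integer(!censored),
                    stringsAsFactors = FALSE)
  out[[gene_id]] <- gene_expr
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Generate a survival cohort with one prognostic driver and decoy genes
#'
#' Convenience wrapper for ranking experiments: survival depends on a single
#' driver gene via [generate_survival()]; `n_decoys` additional genes are
#' independent standard-normal expression columns with no effect on hazard.
#'
#' @inheritParams generate_survival
#' @param n_patients cohort size.
#' @param n_decoys number of null genes added.
#' @return a `survival_cohort` data.frame with gene columns `driver`,
#'   `decoy01`, `decoy02`, ...
#' @export
generate_survival_cohort <- function(n_patients = 200L, n_decoys = 50L,
                                     hazard_ratio = 4, baseline_hazard = 0.1,
                                     censor_rate = 0.1, seed = 1L) {
  .substream(seed, 3L)
  driver <- stats::rnorm(n_patients)
  decoys <- matrix(stats::rnorm(n_patients * n_decoys), nrow = n_patients,
                   dimnames = list(NULL, sprintf("decoy%02d", seq_len(n_decoys))))
  cohort <- generate_survival(driver, hazard_ratio = hazard_ratio,
                              baseline_hazard = baseline_hazard,
                              censor_rate = censor_rate, seed = seed,
                              gene_id = "driver")
  cohort <- cbind(cohort, as.data.frame(decoys))
  class(cohort) <- c("survival_cohort", "data.frame")
  cohort
}
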