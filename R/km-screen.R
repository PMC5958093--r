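#' Median split of a cohort on one gene's expression
#'
#' High-expression patients are those with expression strictly greater than
#' the 50th percentile; ties at the median go to the low group (keeping
#' "greater than" literal for the high group).
#'
#' @param cohort a `survival_cohort` data.frame (columns `patient_id`,
#'   `time`, `event`, plus gene columns).
#' @param gene_id name of the expression column to split on.
#' @return list with `low` and `high` (row indices), `n_low`, `n_high`,
#'   and `median`. If all values are tied one group is empty; callers are
#'   expected to skip such genes.
#' @export
median_split <- function(cohort, gene_id) {
  stopifnot(is.data.frame(cohort), gene_id %in% names(cohort))
  x <- cohort[[gene_id]]
  if (length(x) < 2L) stop("need >= 2 patients")
  med <- stats::median(x)
  high <- which(x > med)
  low <- which(x <= med)
  list(low = low, high = high, n_low = length(low), n_high = length(high),
       median = med)
}

#' Kaplan-Meier survival curve of a patient group
#'
#' Product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i / n_i) over the
#' distinct event times; censored subjects leave the risk set without
#' producing a step.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = death observed, 0 = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `surv` (the estimate just after `time`).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

# restricted mean survival time: area under the KM curve up to tau
.rmean <- function(time, event, tau) {
  km <- km_curve(time, event)
  tt <- c(0, km$time[km$time <= tau], tau)
  ss <- c(1, km$surv[km$time <= tau])
  sum(diff(tt) * ss)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the survival
#' of two groups (via `survival::survdiff`).
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier median-split screening of a gene list
#'
#' For every gene: split the cohort at the median expression, compare the
#' low- and high-expression groups with the log-rank test, and report the
#' p-value, with direction judged by the groups' restricted mean survival
#' (up to the longest follow-up). Genes whose expression cannot split the
#' cohort (constant, or no events in total) are skipped and listed
#' separately. The output is sorted by increasing p: the genes best at
#' separating the two prognosis groups come first.
#'
#' @param cohort a `survival_cohort` data.frame.
#' @param gene_ids gene columns to screen; defaults to every column other
#'   than `patient_id`, `time`, `event`.
#' @return data.frame sorted by increasing p: `gene_id`, `n_low`, `n_high`,
#'   `logrank_stat`, `p`, `adjusted_p`, `direction`
#'   (`high_expr_worse` / `low_expr_worse`); attribute `skipped` lists the
#'   genes that could not be tested.
#' @export
screen_switch_genes <- function(cohort,
                                gene_ids = setdiff(names(cohort),
                                                   c("patient_id", "time", "event"))) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  missing_g <- setdiff(gene_ids, names(cohort))
  if (length(missing_g))
    stop("gene not in cohort: ", missing_g[1L])
  tau <- max(cohort$time)
  rows <- list(); skipped <- character(0)
  for (g in gene_ids) {
    sp <- median_split(cohort, g)
    if (sp$n_low == 0L || sp$n_high == 0L || sum(cohort$event) == 0L) {
      skipped <- c(skipped, g)
      next
    }
    grp <- rep("low", nrow(cohort)); grp[sp$high] <- "high"
    lr <- logrank_test(cohort$time, cohort$event, grp)
    rm_low <- .rmean(cohort$time[sp$low], cohort$event[sp$low], tau)
    rm_high <- .rmean(cohort$time[sp$high], cohort$event[sp$high], tau)
    rows[[g]] <- data.frame(
      gene_id = g, n_low = sp$n_low, n_high = sp$n_high,
      logrank_stat = lr$statistic, p = lr$p,
      direction = if (rm_high < rm_low) "high_expr_worse" else "low_expr_worse",
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped gene(s) with a degenerate split or no events: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_low = integer(0), n_high = integer(0),
               logrank_stat = numeric(0), p = numeric(0),
               direction = character(0))
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$gene_id),
             c("gene_id", "n_low", "n_high", "logrank_stat", "p",
               "adjusted_p", "direction")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
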