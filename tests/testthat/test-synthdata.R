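test_that("generators are bitwise-reproducible under a fixed seed", {
  d <- synthetic_design(seed = 11L)
  expect_identical(generate_expression(d)$values,
                   generate_expression(d)$values)
  expect_identical(generate_target_map(d), generate_target_map(d))
  expr <- rnorm(40)
  expect_identical(generate_survival(expr, seed = 3L),
                   generate_survival(expr, seed = 3L))
  # substreams are independent: interleaving a target-map call does not
  # perturb the expression draw
  a <- generate_expression(d)
  invisible(generate_target_map(d))
  b <- generate_expression(d)
  expect_identical(a$values, b$values)
})

test_that("design validation rejects out-of-range parameters", {
  expect_error(synthetic_design(n_genes = 0), "sizes")
  expect_error(synthetic_design(within_module_rho = 1.2), "within_module_rho")
  expect_error(synthetic_design(switch_anticorr_rho = 0.5),
               "switch_anticorr_rho")
  expect_error(synthetic_design(switch_anticorr_rho = -0.99,
                                within_module_rho = 0.5),
               "sqrt")
  expect_error(synthetic_design(noise_sd = 0), "noise_sd")
  expect_error(synthetic_design(module_sizes = c(200, 200)), "exceeds")
  # planted ids are disjoint from module member sets
  d <- synthetic_design()
  expect_length(intersect(d$planted_switch_ids,
                          unlist(d$module_members)), 0L)
})

test_that("null design produces no fold-change signal", {
  d <- synthetic_design(fold_change_signal = 1, within_module_rho = 0,
                        switch_anticorr_rho = 0, seed = 5L)
  deg <- compute_deg(generate_expression(d))
  expect_lte(sum(deg$pass), ceiling(0.05 * nrow(deg)))
  expect_lt(mean(deg$fold_change >= 3.3), 0.02)
})

test_that("module members reach the designed pairwise correlation", {
  # rho = 0.95, no condition shift so the 20 condition-A columns are a
  # clean window on the within-module correlation
  d <- synthetic_design(within_module_rho = 0.95, noise_sd = 0.1,
                        fold_change_signal = 1, seed = 7L)
  expr <- generate_expression(d)
  cm <- cor(t(expr$values[d$module_members$module1, ]))
  mean_r <- mean(cm[upper.tri(cm)])
  expect_gte(mean_r, 0.95 - 0.05)
  # planted switch genes load negatively on module 1
  cross <- cor(t(expr$values[d$planted_switch_ids, , drop = FALSE]),
               t(expr$values[d$module_members$module1, , drop = FALSE]))
  expect_lt(mean(cross), -0.8)
})

test_that("strong fold-change blocks pass the DEG filter, null blocks do not", {
  d <- synthetic_design(fold_change_signal = 4, noise_sd = 0.1, seed = 9L)
  deg <- compute_deg(generate_expression(d))
  block <- c(unlist(d$module_members), d$planted_switch_ids)
  expect_gte(mean(deg$pass[deg$gene_id %in% block]), 0.95)
  expect_lte(mean(deg$pass[deg$gene_id %in% d$background_ids]), 0.05)
})

test_that("target map enrichment behaves at both extremes", {
  d <- synthetic_design(seed = 21L)
  expect_error(generate_target_map(d, enrich_factor = 0.5), "enrich_factor")
  expect_error(generate_target_map(d, n_mirnas = 0), "n_mirnas")
  expect_error(generate_target_map(synthetic_design(seed = 1L),
                                   targets_per_mirna = 1000),
               "exceeds the gene universe")
  # strong enrichment: the designated miRNA covers the planted set
  tm <- generate_target_map(d, n_mirnas = 10L, enrich_factor = 1e6)
  des <- attr(tm, "designated")
  expect_true(all(d$planted_switch_ids %in% tm$target[tm$mirna == des]))
  res <- enrich_targets(d$planted_switch_ids, tm)
  expect_lt(res$p[res$mirna_id == des], 0.05)
  expect_identical(res$mirna_id[1L], des)
})

test_that("unenriched target maps follow the hypergeometric null", {
  # with enrich_factor = 1 the designated miRNA is exchangeable with the
  # rest: its p-value should be significant at about the nominal rate
  hits <- vapply(1:150, function(s) {
    d <- synthetic_design(seed = 1000L + s)
    tm <- generate_target_map(d, n_mirnas = 20L, enrich_factor = 1)
    res <- suppressMessages(enrich_targets(d$planted_switch_ids, tm))
    res$p[res$mirna_id == attr(tm, "designated")] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("survival generator produces the designed hazard structure", {
  expect_error(generate_survival(rnorm(10), hazard_ratio = 0), "hazard_ratio")
  expect_error(generate_survival(rnorm(10), censor_rate = 2), "censor_rate")
  # null hazard: log-rank p roughly uniform over replicates
  ps <- vapply(1:200, function(s) {
    co <- generate_survival(rnorm(60), hazard_ratio = 1, censor_rate = 0.1,
                            seed = s)
    sp <- median_split(co, "gene")
    grp <- rep("low", nrow(co)); grp[sp$high] <- "high"
    logrank_test(co$time, co$event, grp)$p
  }, numeric(1))
  expect_gte(median(ps), 0.3)
  expect_lte(median(ps), 0.7)
  # strong hazard: detected nearly always
  sig <- vapply(1:100, function(s) {
    co <- generate_survival(rnorm(200), hazard_ratio = 4, censor_rate = 0.1,
                            seed = 5000L + s)
    sp <- median_split(co, "gene")
    grp <- rep("low", nrow(co)); grp[sp$high] <- "high"
    logrank_test(co$time, co$event, grp)$p < 0.01
  }, logical(1))
  expect_gte(mean(sig), 0.9)
  # censor_rate = 1: every record censored, KM curve stays at 1
  co <- generate_survival(rnorm(30), censor_rate = 1, seed = 2L)
  expect_true(all(co$event == 0L))
  expect_true(all(km_curve(co$time, co$event)$surv == 1))
})
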