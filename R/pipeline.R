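#' Pipeline configuration
#'
#' Bundles every stage parameter with the published defaults: adjusted-p
#' 0.05 and linear fold change 3.3 for the DEG stage, |r| >= 0.8 for the
#' network, hub degree 5, k = 3 expression clusters, hub line Z_g = 2.5 and
#' the standard R1-R7 K_pi bounds for the cartography.
#'
#' @param alpha DEG adjusted-p threshold.
#' @param fc_threshold DEG linear fold-change threshold.
#' @param r_threshold network absolute-correlation threshold.
#' @param hub_degree minimum hub degree.
#' @param party_cut APCC boundary between date and party hubs.
#' @param k number of expression clusters (or `"auto"`).
#' @param z_hub_cut Z_g hub line of the cartography.
#' @param r_bounds_nonhub,r_bounds_hub K_pi region bounds (see
#'   [assign_regions()]).
#' @param n_swaps_per_edge rewiring chain length for the null model.
#' @param seed clustering / null-model seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, fc_threshold = 3.3,
                            r_threshold = 0.8, hub_degree = 5L,
                            party_cut = 0.8, k = 3L, z_hub_cut = 2.5,
                            r_bounds_nonhub = c(0.05, 0.62, 0.80),
                            r_bounds_hub = c(0.30, 0.75),
                            n_swaps_per_edge = 10, seed = 0L) {
  stopifnot(alpha > 0, alpha <= 1, fc_threshold >= 1,
            r_threshold >= 0, r_threshold <= 1, hub_degree >= 1,
            party_cut >= 0, party_cut <= 1,
            identical(k, "auto") || k >= 1,
            !is.unsorted(r_bounds_nonhub), !is.unsorted(r_bounds_hub))
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 r_threshold = r_threshold, hub_degree = as.integer(hub_degree),
                 party_cut = party_cut, k = k, z_hub_cut = z_hub_cut,
                 r_bounds_nonhub = r_bounds_nonhub,
                 r_bounds_hub = r_bounds_hub,
                 n_swaps_per_edge = n_swaps_per_edge,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the switch-gene discovery pipeline
#'
#' Executes the stages in order: differential expression -> signed Pearson
#' co-expression network over the DEGs -> hub classification by APCC ->
#' k-means heat cartography (K_pi, Z_g, regions) -> switch-gene extraction
#' (fight-club hubs in R4). Fully deterministic given the configuration and
#' its seed. With `out_dir` set, writes `deg.tsv`, `edges.tsv`, `carto.tsv`,
#' `switch_genes.txt` and `run_log.txt` (effective parameters and
#' per-stage counts).
#'
#' A run with no DEGs (e.g. an infinite fold-change threshold) completes
#' cleanly with empty downstream tables.
#'
#' @param expr an [expression_matrix()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @param quiet suppress the per-stage messages.
#' @return list with `deg` (full DEG table), `deg_ids`, `network`,
#'   `cartography` (or NULL when the network is empty), `labels`,
#'   `switch_genes`, `switch_table` and `counts` (named list used in the
#'   run log).
#' @export
run_pipeline <- function(expr, config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  deg <- compute_deg(expr, alpha = config$alpha,
                     fc_threshold = config$fc_threshold)
  deg_ids <- deg$gene_id[deg$pass]
  ds <- deg_direction_summary(deg)
  say("stage deg: %d DEGs of %d genes (%d%% down, %d%% up)",
      length(deg_ids), nrow(deg), ds$pct_down, ds$pct_up)

  empty_switch <- list(switch_genes = character(0),
                       table = data.frame(gene_id = character(0)))
  net <- NULL; carto <- NULL; labels <- NULL; sw <- empty_switch
  if (length(deg_ids) >= 2L) {
    net <- build_network(expr, deg_ids, r_threshold = config$r_threshold)
    net <- classify_hubs(net, hub_degree = config$hub_degree,
                         party_cut = config$party_cut)
    s <- summary(net)
    say("stage network: %d nodes, %d edges; %d hubs (%d party, %d date, %d fight-club)",
        s$n_nodes, s$n_edges, s$n_hubs, s$n_party, s$n_date, s$n_fight_club)
    k_eff <- config$k
    if (!identical(k_eff, "auto")) k_eff <- min(k_eff, length(net$nodes))
    carto <- build_cartography(net, expr, k = k_eff, seed = config$seed,
                               z_hub_cut = config$z_hub_cut,
                               r_bounds_nonhub = config$r_bounds_nonhub,
                               r_bounds_hub = config$r_bounds_hub)
    labels <- carto$labels
    sw <- extract_switch_genes(carto, net)
    say("stage cartography: k = %d clusters; identified %d switch genes out of %d fight-club hubs",
        carto$clustering$k, length(sw$switch_genes), s$n_fight_club)
  } else {
    say("stage network: skipped (fewer than 2 DEGs)")
  }

  s <- if (is.null(net)) list(n_nodes = 0L, n_edges = 0L, n_hubs = 0L,
                              n_party = 0L, n_date = 0L, n_fight_club = 0L)
       else summary(net)
  counts <- c(list(n_genes = nrow(deg), n_deg = length(deg_ids),
                   n_deg_up = ds$n_up, n_deg_down = ds$n_down), s,
              list(n_switch = length(sw$switch_genes)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(deg, file.path(out_dir, "deg.tsv"))
    write_table(if (is.null(net)) data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             r = numeric(0)) else net$edges,
                file.path(out_dir, "edges.tsv"))
    write_table(if (is.null(carto)) data.frame(gene_id = character(0))
                else carto$table, file.path(out_dir, "carto.tsv"))
    writeLines(sw$switch_genes, file.path(out_dir, "switch_genes.txt"))
    cfg_lines <- vapply(names(unclass(config)), function(nm)
      sprintf("param %s = %s", nm, paste(config[[nm]], collapse = ",")),
      character(1))
    cnt_lines <- vapply(names(counts), function(nm)
      sprintf("count %s = %s", nm, counts[[nm]]), character(1))
    writeLines(c(cfg_lines, cnt_lines), file.path(out_dir, "run_log.txt"))
  }

  list(deg = deg, deg_ids = deg_ids, network = net, cartography = carto,
       labels = labels, switch_genes = sw$switch_genes,
       switch_table = sw$table, counts = counts)
}
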