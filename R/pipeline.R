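#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline. Sections: `simulate`
#' (arguments of [simulationConfig()]), `dbscan` (`eps`, `min_pts`),
#' `pairing` (arguments of [pairingParams()]), `render` (arguments of
#' [renderConfig()] plus `enabled`), `register` (`enabled`, `ref_channel`,
#' `n_beads`), and a top-level `seed` that overrides the simulation seed.
#'
#' @param ... named sections merged over the defaults (one level deep)
#' @return nested configuration list
#' @export
pipelineConfig <- function(...) {
  base <- list(
    seed = 1,
    simulate = list(),
    dbscan = list(eps = 100, min_pts = 50),
    pairing = list(max_center_distance_nm = 500, search_radius_nm = 500,
                   nn_cutoff_nm = 500, histogram_bin_nm = 10),
    register = list(enabled = TRUE, ref_channel = "GLT1", n_beads = 12),
    render = list(enabled = TRUE, mode = "histogram", pixel_nm = 20))
  over <- list(...)
  for (sec in names(over)) {
    if (is.list(over[[sec]]) && is.list(base[[sec]])) {
      for (k in names(over[[sec]])) base[[sec]][[k]] <- over[[sec]][[k]]
    } else base[[sec]] <- over[[sec]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' simulate -> register -> cluster -> pair -> distances -> render, driven by
#' one configuration and one seed; every stage writes its outputs into the
#' run directory and the run ends with a machine-readable `summary.json`.
#' The run is a pure function of (config, seed): identical inputs give
#' byte-identical summaries.
#'
#' @param config nested list, see [pipelineConfig()]; a path to a YAML file
#'   is also accepted
#' @param out_dir run directory (created if needed)
#' @return invisibly, the summary list
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir) {
  if (is.character(config)) config <- readConfigYaml(config)
  config <- do.call(pipelineConfig, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cfg <- do.call(simulationConfig, sim_args)

  logf("simulate", "generating scene (n_synapses = %g, seed = %g)",
       cfg@n_synapses, cfg@seed)
  scene <- makeScene(cfg)
  table <- imageScene(scene)
  writeLocalizations(table, file.path(out_dir, "localizations.csv"))
  utils::write.csv(truthTable(table), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  logf("simulate", "%d localisations in %d channels", nLocs(table),
       length(channels(table)))

  if (isTRUE(config$register$enabled)) {
    beads <- makeBeadTable(cfg, n_beads = config$register$n_beads)
    trs <- registerChannels(beads, config$register$ref_channel)
    writeTransforms(trs, file.path(out_dir, "transforms.json"))
    table <- applyTransform(table, trs)
    res <- vapply(trs, function(t) t@residual_nm, numeric(1))
    logf("register", "channels aligned to %s (max RMS residual %.2f nm)",
         config$register$ref_channel, max(res))
  }

  roles <- cfg@channels@roles
  pre_ch <- names(roles)[roles == "presynaptic"]
  post_ch <- names(roles)[roles == "postsynaptic"]
  peri_ch <- names(roles)[roles == "perisynaptic"][1]
  eps <- config$dbscan$eps
  min_pts <- config$dbscan$min_pts
  pre <- clusterChannel(table, pre_ch, eps, min_pts)
  post <- clusterChannel(table, post_ch, eps, min_pts)
  writeClusters(list(pre$clusters, post$clusters),
                file.path(out_dir, "clusters.csv"))
  logf("cluster", "%s: %d clusters; %s: %d clusters (eps=%g, min_pts=%d)",
       pre_ch, nrow(clusterSummary(pre$clusters)),
       post_ch, nrow(clusterSummary(post$clusters)), eps, min_pts)

  params <- do.call(pairingParams, config$pairing)
  pairs <- pairSynapses(pre$clusters, post$clusters, params)
  utils::write.csv(pairs, file.path(out_dir, "synapses.csv"),
                   row.names = FALSE)
  logf("pair", "%d synapses identified", nrow(pairs))

  nn <- nnDistances(pre$table, post$table, params$nn_cutoff_nm,
                    params$histogram_bin_nm)
  glt1 <- filterByChannel(table, peri_ch)
  peri <- perisynapticDistances(glt1, pairs, pre, post, params)
  dsets <- c(list(nn), unname(peri))
  writeDistances(dsets, file.path(out_dir, "distances.csv"))

  if (isTRUE(config$render$enabled)) {
    rcfg_args <- config$render
    rcfg_args$enabled <- NULL
    rcfg <- do.call(renderConfig, rcfg_args)
    rend <- render2d(table, rcfg)
    for (ch in names(rend$channels))
      writeImage(rend$channels[[ch]], file.path(out_dir, paste0("render_", ch)))
    exportPointCloud(table, rcfg, file.path(out_dir, "pointcloud.ply"))
    logf("render", "images + point cloud written")
  }

  modeOrNA <- function(ds) if (length(ds@distances_nm)) histogramMode(ds)
                           else NA_real_
  clusterStats <- function(cs) {
    s <- clusterSummary(cs)
    list(n_clusters = nrow(s),
         n_locs = unname(stats::quantile(s$n_locs,
                                         c(0, 0.25, 0.5, 0.75, 1))),
         hull_volume_nm3 = unname(stats::quantile(s$hull_volume_nm3,
                                                  c(0, 0.25, 0.5, 0.75, 1))),
         density_per_um3 = unname(stats::quantile(s$density_per_um3,
                                                  c(0, 0.25, 0.5, 0.75, 1),
                                                  na.rm = TRUE)))
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  summary <- list(
    package = "TriSynapse",
    version = as.character(utils::packageVersion("TriSynapse")),
    seed = config$seed,
    config_hash = contentHash(as.character(cfg_json)),
    n_locs = as.list(table(locData(table)$channel)),
    n_clusters = stats::setNames(
      list(nrow(clusterSummary(pre$clusters)),
           nrow(clusterSummary(post$clusters))), c(pre_ch, post_ch)),
    n_synapses = nrow(pairs),
    n_true_synapses = nrow(scene@synapses),
    histogram_modes_nm = list(
      pre_post_nn = modeOrNA(nn),
      glt1_to_center = modeOrNA(peri$glt1_to_center),
      glt1_to_pre = modeOrNA(peri$glt1_to_pre),
      glt1_to_post = modeOrNA(peri$glt1_to_post)),
    median_distances_nm = list(
      pre_post_nn = if (length(nn@distances_nm))
        stats::median(nn@distances_nm) else NA_real_,
      glt1_to_pre = if (length(peri$glt1_to_pre@distances_nm))
        stats::median(peri$glt1_to_pre@distances_nm) else NA_real_,
      glt1_to_post = if (length(peri$glt1_to_post@distances_nm))
        stats::median(peri$glt1_to_post@distances_nm) else NA_real_),
    cluster_stats = stats::setNames(
      list(clusterStats(pre$clusters), clusterStats(post$clusters)),
      c(pre_ch, post_ch)))
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  con <- file(file.path(out_dir, "summary.json"), open = "wb")
  writeLines(json, con, sep = "\n")
  close(con)
  logf("summary", "run complete: %d synapses, NN mode %s nm",
       nrow(pairs), format(summary$histogram_modes_nm$pre_post_nn))
  invisible(summary)
}
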