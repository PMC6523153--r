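#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: response weighting,
#' the per-trait BayesB chains, significance thresholds, AWM construction
#' rules and promoter-scan cutoff. Chain length defaults here are the
#' desk-scale demo settings; production runs should raise `n_iter`/`burn_in`
#' to the [chain_config()] defaults.
#'
#' @param key_trait key phenotype for AWM row selection.
#' @param h2_by_trait named heritabilities used for weighting; taken from
#'   the simulation config when the bundle carries one.
#' @param c_gen proportion of genetic variance not captured by markers.
#' @param min_r2 reliability filter threshold.
#' @param weight_form `"ratio"` or `"literal"`, see [compute_weight()].
#' @param pi prior zero-effect fraction of the sampler.
#' @param n_iter,burn_in,thin chain length settings.
#' @param gv_threshold window variance share threshold (percent).
#' @param bf_threshold SNP Bayes-factor threshold for informative regions.
#' @param bf_min AWM significance cutoff.
#' @param d_min,d_max AWM distance bounds in bp.
#' @param awm_mode `"literal"` or `"proximal"` distance rule.
#' @param p_max promoter-scan p-value cutoff.
#' @param seed master seed; per-trait chain seeds are derived from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(key_trait = "BFAT", h2_by_trait = NULL,
                            c_gen = 0.40, min_r2 = 0.10,
                            weight_form = "ratio",
                            pi = 0.99, n_iter = 3000L, burn_in = 1000L,
                            thin = 5L, gv_threshold = 1.0,
                            bf_threshold = 20, bf_min = 3.2,
                            d_min = 2500, d_max = 1.5e6,
                            awm_mode = "literal", p_max = 0.001,
                            seed = 1L) {
  structure(list(key_trait = key_trait, h2_by_trait = h2_by_trait,
                 c_gen = c_gen, min_r2 = min_r2, weight_form = weight_form,
                 pi = pi, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 gv_threshold = gv_threshold, bf_threshold = bf_threshold,
                 bf_min = bf_min, d_min = d_min, d_max = d_max,
                 awm_mode = awm_mode, p_max = p_max,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Response weighting, one weighted BayesB chain per trait, window variance
#' and Bayes-factor significance tables, AWM construction, PCIT network
#' inference, and the TF validation stage. All randomness derives from
#' `cfg$seed`, so reruns with the same bundle and config reproduce identical
#' outputs. When `outdir` is given, every result table plus a manifest JSON
#' is written there (see [write_reports()]).
#'
#' @param bundle input bundle from [simulate_all()] or [read_inputs()].
#' @param cfg a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list of class `"bfawm_run"`: `gwas` (per-trait significance
#'   tables), `windows` (per-trait window tables), `informative` (combined
#'   report), `awm`, `network`, `summary`, `tfs`, `modules`, `trio`, `cfg`.
#' @export
run_pipeline <- function(bundle, cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  G <- bundle$geno$G
  map <- bundle$map
  h2 <- cfg$h2_by_trait
  traits <- unique(bundle$response$trait)
  if (is.null(h2)) {
    if (!is.null(bundle$cfg))
      h2 <- setNames(bundle$cfg$h2_per_trait, traits)
    else stop("run_pipeline: supply h2_by_trait in the pipeline config")
  }
  if (!cfg$key_trait %in% traits)
    stop("run_pipeline: key trait '", cfg$key_trait, "' has no records")

  resp <- prepare_response(bundle$response, h2, c_gen = cfg$c_gen,
                           min_r2 = cfg$min_r2, form = cfg$weight_form)
  message("response: ", nrow(resp), "/", nrow(bundle$response),
          " records retained across ", length(traits), " trait(s)")

  gwas <- list()
  windows <- list()
  informative <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    rt <- resp[resp$trait == tr, , drop = FALSE]
    idx <- match(rt$animal_id, rownames(G))
    if (anyNA(idx)) stop("run_pipeline: response animals missing genotypes")
    ccfg <- chain_config(pi = cfg$pi, n_iter = cfg$n_iter,
                         burn_in = cfg$burn_in, thin = cfg$thin,
                         seed = cfg$seed + 1000L * k, save_effects = TRUE)
    fit <- run_chain(G[idx, , drop = FALSE], rt$debv, rt$weight, ccfg)
    gwas[[tr]] <- snp_significance(fit, map)
    windows[[tr]] <- window_variance_table(fit, G[idx, , drop = FALSE], map)
    informative[[tr]] <- informative_regions(windows[[tr]], gwas[[tr]],
                                             cfg$gv_threshold,
                                             cfg$bf_threshold, trait = tr)
    message("gwas [", tr, "]: ",
            sum(gwas[[tr]]$bf > cfg$bf_min, na.rm = TRUE),
            " SNPs with BF > ", cfg$bf_min, "; ",
            nrow(informative[[tr]]), " informative window(s)")
  }
  informative <- do.call(rbind, informative)
  rownames(informative) <- NULL

  awm <- build_awm(gwas, map, bundle$genes, cfg$key_trait,
                   bf_min = cfg$bf_min, d_min = cfg$d_min, d_max = cfg$d_max,
                   mode = cfg$awm_mode)
  message("awm: ", nrow(awm$M), " rows x ", ncol(awm$M), " traits")
  C <- row_correlations(awm)
  net <- pcit_filter(C)
  summ <- network_summary(net)
  message("network: ", summ$n_nodes, " nodes, ", summ$n_edges,
          " edges (density ", signif(summ$density, 3), ")")

  tfs <- match_tfs(net$nodes, bundle$motifs$tf_list)
  modules <- list()
  trio <- NULL
  if (length(tfs)) {
    network_gene_proms <- bundle$motifs$promoters[
      intersect(net$nodes, names(bundle$motifs$promoters))]
    modules <- assign_targets(tfs, bundle$motifs$pwms, network_gene_proms,
                              p_max = cfg$p_max)
    if (length(modules) >= 3) trio <- select_top_trio(modules)
  }
  message("tf: ", length(tfs), " TFs in network, ", length(modules),
          " with motifs",
          if (!is.null(trio)) paste0("; top trio covers ", trio$coverage,
                                     " genes") else "")

  run <- structure(list(gwas = gwas, windows = windows,
                        informative = informative, awm = awm, network = net,
                        summary = summ, tfs = tfs, modules = modules,
                        trio = trio, cfg = cfg),
                   class = "bfawm_run")
  if (!is.null(outdir)) write_reports(run, outdir)
  run
}

#' @export
print.bfawm_run <- function(x, ...) {
  cat("bfawm pipeline run (key trait:", x$cfg$key_trait, ")\n")
  cat("  traits analysed:      ", length(x$gwas), "\n")
  cat("  informative windows:  ", nrow(x$informative), "\n")
  cat("  AWM:                  ", nrow(x$awm$M), "rows x", ncol(x$awm$M),
      "traits\n")
  cat("  network:              ", x$summary$n_nodes, "nodes,",
      x$summary$n_edges, "edges\n")
  if (!is.null(x$trio))
    cat("  top TF trio:          ", paste(x$trio$tfs, collapse = ", "),
        "( coverage", x$trio$coverage, ")\n")
  invisible(x)
}

#' Write the report files of a pipeline run
#'
#' Emits one GWAS TSV per trait, the informative-regions table (one row per
#' reported window: trait, window, GV%, best SNP, position in Mb, effect,
#' BF), the AWM with its provenance sidecar, the network edge list
#' (SIF-style), the per-TF target modules, the trio JSON, a summary JSON
#' with node/edge counts, and a manifest JSON recording parameters and seed.
#' Infinite Bayes factors are serialised as `"inf"`.
#'
#' @param run a `"bfawm_run"`.
#' @param outdir output directory, created if needed.
#' @return named vector of written paths, invisibly.
#' @export
write_reports <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tr in names(run$gwas)) {
    g <- run$gwas[[tr]]
    g$bf <- format_bf(g$bf)
    p <- file.path(outdir, paste0("gwas_", tr, ".tsv"))
    data.table::fwrite(g, p, sep = "\t")
    paths[paste0("gwas_", tr)] <- p
    w <- file.path(outdir, paste0("windows_", tr, ".tsv"))
    data.table::fwrite(run$windows[[tr]], w, sep = "\t")
    paths[paste0("windows_", tr)] <- w
  }
  inf <- run$informative
  inf$bf <- format_bf(inf$bf)
  paths["informative"] <- file.path(outdir, "informative_regions.tsv")
  data.table::fwrite(inf, paths["informative"], sep = "\t")
  paths["awm"] <- file.path(outdir, "awm.tsv")
  write_awm(run$awm, paths["awm"])
  paths["edges"] <- file.path(outdir, "network_edges.sif.tsv")
  write_edges(run$network, paths["edges"])
  if (length(run$modules)) {
    mods <- do.call(rbind, lapply(names(run$modules), function(tf) {
      m <- run$modules[[tf]]
      if (nrow(m) == 0) return(NULL)
      cbind(tf = tf, m)
    }))
    paths["modules"] <- file.path(outdir, "tf_modules.tsv")
    if (is.null(mods))
      mods <- data.frame(tf = character(), gene = character(),
                         best_score = numeric(), best_p = numeric())
    data.table::fwrite(mods, paths["modules"], sep = "\t")
  }
  if (!is.null(run$trio)) {
    paths["trio"] <- file.path(outdir, "tf_trio.json")
    jsonlite::write_json(run$trio, paths["trio"], auto_unbox = TRUE,
                         digits = NA)
  }
  paths["summary"] <- file.path(outdir, "network_summary.json")
  jsonlite::write_json(
    list(n_nodes = run$summary$n_nodes, n_edges = run$summary$n_edges,
         density = run$summary$density,
         top = run$summary$top),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  paths["manifest"] <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(package = "bfawm",
         version = as.character(utils::packageVersion("bfawm")),
         parameters = unclass(run$cfg),
         traits = names(run$gwas),
         n_awm_rows = nrow(run$awm$M),
         n_network_nodes = run$summary$n_nodes,
         n_network_edges = run$summary$n_edges),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
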