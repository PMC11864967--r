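## Pipeline orchestration: simulate -> reconstruct -> patterns -> network,
## with per-stage outputs under an output directory and a JSON run
## manifest.  All randomness flows from the single manifest seed through
## named substreams; no stage consumes global entropy.

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order.  `simulate` writes
#' the observed tables (metadata, degrees, IBD) and truth tables;
#' `reconstruct` assembles the pedigree from the observed tables;
#' `patterns` computes union/levirate/lineage/exogamy/consanguinity
#' statistics; `network` builds the binary IBD networks and fits the
#' dyad-covariate models.  A later stage reads its inputs from
#' `out_dir` when the producing stage is not part of the same run; a
#' missing input raises a dependency error naming the producer stage.
#'
#' @param config List with optional components `community` (arguments to
#'   [community_config()]), `analysis` (arguments to
#'   [analysis_config()]) and `observe` (`degree_noise`), or a path to a
#'   YAML file with those keys.
#' @param stages Character subset of
#'   `c("simulate", "reconstruct", "patterns", "network")`.
#' @param seed Integer base seed for the whole run.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (also written as `manifest.json`),
#'   invisibly; stage results are attached in `attr(, "results")`.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "reconstruct", "patterns",
                                    "network"),
                         seed = 1L, out_dir = "results") {
  t_start <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), c("community", "analysis", "observe"))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ccfg_args <- config$community %||% list()
  ccfg_args$seed <- substream_seed(seed, "community")
  ccfg <- do.call(community_config, ccfg_args)
  acfg <- do.call(analysis_config, config$analysis %||% list())
  noise <- (config$observe %||% list())$degree_noise %||% 0

  p <- function(...) file.path(out_dir, paste0(...))
  timings <- list()
  results <- list()
  outputs <- list()

  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop("missing input ", path, "; run the '", producer,
           "' stage first")
    }
    path
  }

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    com <- simulate_community(ccfg)
    com <- with_seed(substream_seed(seed, "genomes"), drop_genomes(com))
    obs <- observe(com, degree_noise = noise, include_ibd = TRUE,
                   ibd_min_cM = acfg$ibd_min_cM,
                   seed = substream_seed(seed, "noise"))
    write_tsv(obs$metadata, p("metadata.tsv"))
    write_tsv(obs$degrees, p("degrees.tsv"))
    write_tsv(obs$ibd, p("ibd.tsv"))
    write_tsv(com$unions, p("truth_unions.tsv"))
    write_tsv(com$levirates, p("truth_levirates.tsv"))
    write_pedigree(com$pedigree, fam_path = p("truth_pedigree.fam"),
                   graphml_path = p("truth_pedigree.graphml"))
    results$simulate <- list(community = com, observed = obs)
    outputs$simulate <- c("metadata.tsv", "degrees.tsv", "ibd.tsv",
                          "truth_unions.tsv", "truth_levirates.tsv",
                          "truth_pedigree.fam", "truth_pedigree.graphml")
    timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")
  }

  load_obs <- function() {
    if (!is.null(results$simulate)) return(results$simulate$observed)
    mpath <- need(p("metadata.tsv"), "simulate")
    dpath <- need(p("degrees.tsv"), "simulate")
    ipath <- need(p("ibd.tsv"), "simulate")
    list(metadata = read_metadata(mpath),
         degrees = read_degree_table(dpath),
         ibd = read_ibd_table(ipath))
  }

  if ("reconstruct" %in% stages) {
    t0 <- Sys.time()
    obs <- load_obs()
    rec <- reconstruct_pedigree(obs$degrees, obs$metadata, ibd = obs$ibd,
                                config = acfg)
    write_pedigree(rec$pedigree, fam_path = p("pedigree.fam"),
                   graphml_path = p("pedigree.graphml"))
    write_tsv(rec$subpedigrees, p("subpedigrees.tsv"))
    writeLines(rec$log, p("placement_log.txt"))
    results$reconstruct <- rec
    outputs$reconstruct <- c("pedigree.fam", "pedigree.graphml",
                             "subpedigrees.tsv", "placement_log.txt")
    timings$reconstruct <- as.numeric(Sys.time() - t0, units = "secs")
  }

  load_ped <- function() {
    if (!is.null(results$reconstruct)) return(results$reconstruct$pedigree)
    read_pedigree_graphml(need(p("pedigree.graphml"), "reconstruct"))
  }

  if ("patterns" %in% stages) {
    t0 <- Sys.time()
    ped <- load_ped()
    un <- enumerate_unions(ped)
    lev <- detect_levirate(ped, un)
    lin <- classify_lineages(ped)
    exo <- exogamy_stats(ped)
    jsr <- juvenile_sex_ratio(ped)
    con <- consanguinity_check(ped)
    write_tsv(lev$unions, p("unions.tsv"))
    write_tsv(lev$mothers, p("levirate_mothers.tsv"))
    write_tsv(lin$lines, p("lineages.tsv"))
    write_tsv(con$individuals, p("inbreeding.tsv"))
    summary <- data.frame(
      metric = c("n_relations", "n_multi_unions", "single_multi_ratio",
                 "n_levirate", "patrilineage_prop", "matrilineage_prop",
                 "bilineage_prop", "mothers_total",
                 "mothers_without_ancestors", "exogamy_fraction",
                 "juvenile_sex_ratio", "consanguinity_verdict"),
      value = c(un$summary$n_relations, un$summary$n_multi,
                un$summary$ratio_label, lev$n_levirate,
                round(lin$proportions[["patrilineage"]] %||% NA, 4),
                round(lin$proportions[["matrilineage"]] %||% NA, 4),
                round(lin$proportions[["bilineage"]] %||% NA, 4),
                exo$mothers_total, exo$mothers_without_ancestors,
                round(exo$fraction, 4), jsr$ratio_label, con$verdict),
      stringsAsFactors = FALSE)
    write_tsv(summary, p("pattern_summary.tsv"))
    results$patterns <- list(unions = un, levirate = lev, lineages = lin,
                             exogamy = exo, sex_ratio = jsr,
                             consanguinity = con)
    outputs$patterns <- c("unions.tsv", "levirate_mothers.tsv",
                          "lineages.tsv", "inbreeding.tsv",
                          "pattern_summary.tsv")
    timings$patterns <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("network" %in% stages) {
    t0 <- Sys.time()
    obs <- load_obs()
    fits <- list()
    for (rule in c("long_segments", "sum_threshold")) {
      net <- build_binary_network(obs$ibd, obs$metadata, rule = rule,
                                  config = acfg)
      fit <- select_model(net, candidates = list(
        "sex_pairing", "status_count", c("sex_pairing", "status_count")))
      utils::write.csv(cbind(rule = rule, fit$coefficients),
                       p("ergm_", rule, ".csv"), row.names = FALSE)
      utils::write.csv(sexed_between_site_summary(net),
                       p("tie_rates_", rule, ".csv"), row.names = FALSE)
      write_network(net, obs$metadata,
                    csv_path = p("network_", rule, ".csv"),
                    graphml_path = p("network_", rule, ".graphml"))
      fits[[rule]] <- list(network = net, fit = fit)
    }
    results$network <- fits
    outputs$network <- c(outer(c("ergm_", "tie_rates_", "network_"),
                               c("long_segments", "sum_threshold"),
                               paste0))
    timings$network <- as.numeric(Sys.time() - t0, units = "secs")
  }

  files <- unlist(lapply(outputs, function(o) file.path(out_dir, o)))
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "kinweave",
    version = as.character(utils::packageVersion("kinweave")),
    seed = seed,
    stages = stages,
    config = list(community = ccfg[setdiff(names(ccfg), "mortality_table")],
                  analysis = unclass(acfg), degree_noise = noise),
    outputs = outputs,
    digests = as.list(tools::md5sum(files)),
    timings = timings,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
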