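pipeline_defaults <- list(
  evalue_cutoff = 1e-5, host_clade = 85823, symbiont_clade = 2611341,
  tolerance_bp = 30, min_consensus_hits = 5,
  min_cpm = 1.0, min_samples = 10,
  fc = 2.0, alpha = 0.05,
  beta = 12, strong_threshold = 0.5, weight = "tom",
  cut_height = 0.995, min_module_size = 10,
  cv_folds = 10, seed = 1,
  enrich_alpha = 0.05, enrich_min_transcripts = 5,
  propagate = FALSE)

#' Validate a pipeline run configuration
#'
#' Reads (or accepts) a structured configuration, fills defaults,
#' type- and range-checks every parameter, and verifies that all input
#' paths resolve. Unknown keys are an error.
#'
#' @param config path to a YAML file or a named list. Required keys:
#'   `hits`, `taxonomy`, `counts`, `castes`, `annotations` (input paths)
#'   and `outdir`. All stage parameters are optional with documented
#'   defaults.
#' @return validated configuration list of class `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("hits", "taxonomy", "counts", "castes", "annotations",
                "outdir")
  known <- c(required, names(pipeline_defaults))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  for (key in setdiff(required, "outdir")) {
    if (!file.exists(config[[key]]))
      stop("input path for '", key, "' not found: ", config[[key]])
  }
  for (key in names(pipeline_defaults))
    if (is.null(config[[key]])) config[[key]] <- pipeline_defaults[[key]]
  with(config, {
    stopifnot(evalue_cutoff > 0, tolerance_bp >= 0, min_cpm >= 0,
              min_samples >= 0, fc > 1, alpha > 0, alpha < 1,
              strong_threshold >= 0, strong_threshold <= 1,
              cv_folds >= 2, enrich_alpha > 0)
    if (beta <= 0) stop("beta must be positive")
  })
  config$seed <- as.integer(config$seed)
  class(config) <- c("run_config", "list")
  config
}

stage_log <- function(name, t0, msg) {
  message(sprintf("[%s] %.2fs %s", name,
                  as.numeric(Sys.time()) - t0, msg))
}

#' Run the full analysis pipeline
#'
#' Executes classify, normalize, differential abundance, biomarkers,
#' network and enrichment in dependency order on one input bundle,
#' writing per-stage TSV outputs and a JSON manifest (input hashes,
#' parameters, per-stage row counts) under `config$outdir`.
#'
#' @param config a `run_config` (or anything [validate_run_config()]
#'   accepts).
#' @return the manifest, invisibly; stage results are attached as
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  manifest <- list(
    inputs = lapply(config[c("hits", "taxonomy", "counts", "castes",
                             "annotations")],
                    function(p) unname(tools::md5sum(p))),
    parameters = config[names(pipeline_defaults)],
    stages = list())
  results <- list()

  tax <- load_taxonomy(config$taxonomy)
  counts <- read_counts(config$counts, config$castes)

  # 1. classify
  hit_map <- parse_hits(config$hits, config$evalue_cutoff)
  params <- classify_params(config$host_clade, config$symbiont_clade,
                            config$tolerance_bp,
                            min_consensus_hits = config$min_consensus_hits)
  calls <- classify_transcripts(hit_map, tax, params,
                                all_ids = rownames(counts$counts))
  calls_out <- calls
  calls_out$order_name <- ifelse(is.na(calls$order), "",
                                 vapply(calls$order, function(t)
                                   if (is.na(t)) "" else taxon_name(t, tax),
                                   character(1)))
  calls_out$genus_name <- ifelse(is.na(calls$genus), "",
                                 vapply(calls$genus, function(t)
                                   if (is.na(t)) "" else taxon_name(t, tax),
                                   character(1)))
  utils::write.table(calls_out, file.path(config$outdir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$classify <- list(rows = nrow(calls),
                                   sources = as.list(table(calls$source)))
  stage_log("classify", t0, paste(nrow(calls), "transcripts"))

  # 2. normalize
  filtered <- filter_low_expression(counts, config$min_cpm,
                                    config$min_samples)
  tmm <- tmm_normalize(filtered)
  write_matrix_tsv(tmm$tmm, file.path(config$outdir, "tmm.tsv"))
  utils::write.table(data.frame(sample = names(tmm$factors),
                                factor = tmm$factors,
                                effective_libsize = tmm$effective_libsize),
                     file.path(config$outdir, "factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$normalize <- list(rows = nrow(tmm$tmm),
                                    reference = tmm$reference)
  stage_log("normalize", t0, paste(nrow(tmm$tmm), "transcripts kept"))

  # 3. differential abundance
  phi <- estimate_dispersion(filtered, tmm)
  de <- nb_wald_test(filtered, tmm, phi)
  de <- call_dets(de, config$fc, config$alpha, calls)
  utils::write.table(de, file.path(config$outdir, "de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$de <- list(rows = nrow(de),
                             det = as.list(table(de$status)))
  stage_log("de", t0, paste(sum(de$status != "ns"), "DETs"))

  # 4. biomarkers
  X <- t(log2(tmm$tmm + 1))
  std <- standardize_features(X)
  y <- as.integer(tmm$caste == "soldier")
  cv <- cv_select_lambda(std$X, y, k = min(config$cv_folds, nrow(std$X)),
                         seed = config$seed)
  biomarkers <- report_biomarkers(cv, tmm, calls, de)
  utils::write.table(biomarkers,
                     file.path(config$outdir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$biomarkers <- list(rows = nrow(biomarkers),
                                     lambda = cv$lambda)
  stage_log("biomarkers", t0, paste(nrow(biomarkers), "selected"))

  # 5. network
  net <- build_caste_networks(tmm, beta = config$beta,
                              cut_height = config$cut_height,
                              min_size = config$min_module_size,
                              weight = config$weight)
  pw <- strong_pairs(net$weight_worker, calls, config$strong_threshold)
  ps <- strong_pairs(net$weight_soldier, calls, config$strong_threshold)
  shared <- shared_pairs(pw, ps)
  utils::write.table(pw, file.path(config$outdir, "edges_worker.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ps, file.path(config$outdir, "edges_soldier.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(shared, file.path(config$outdir, "shared_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(transcript = names(net$modules),
                                module = net$modules),
                     file.path(config$outdir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$network <- list(worker_pairs = nrow(pw),
                                  soldier_pairs = nrow(ps),
                                  shared_pairs = nrow(shared),
                                  weight = config$weight)
  stage_log("network", t0, paste(nrow(pw), "worker /", nrow(ps),
                                 "soldier strong pairs"))

  # 6. enrichment (worker- and soldier-biased termite transcripts vs all
  # termite transcripts)
  annot <- read_annotations(config$annotations)
  termite_ids <- intersect(calls$transcript[calls$source == "termite"],
                           de$transcript)
  enrich <- list()
  for (side in c("worker-biased", "soldier-biased")) {
    fg <- intersect(de$transcript[de$status == side], termite_ids)
    rows <- hypergeom_enrich(fg, termite_ids, annot)
    enrich[[side]] <- rows
    utils::write.table(rows, file.path(config$outdir,
                                       paste0("enrich_", sub("-.*", "",
                                                             side),
                                              ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$enrich <- list(
    worker_sig = sum(enrich[["worker-biased"]]$q < config$enrich_alpha),
    soldier_sig = sum(enrich[["soldier-biased"]]$q < config$enrich_alpha))
  stage_log("enrich", t0, "done")

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  out <- manifest
  attr(out, "results") <- list(calls = calls, tmm = tmm, de = de,
                               biomarkers = biomarkers, network = net,
                               pairs_worker = pw, pairs_soldier = ps,
                               shared = shared, enrich = enrich)
  invisible(out)
}
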