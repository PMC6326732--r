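# End-to-end pipeline driver: simulate (or load) a cohort, compute lead
# matrices and spectra, then run any of the fingerprinting, selection,
# classification and graph stages, writing delimited-text outputs.

#' Default pipeline configuration
#'
#' Every stochastic stage carries an explicit seed derived from the master
#' seed, so reruns with the same configuration are identical.
#'
#' @param seed master integer seed.
#' @param out output directory.
#' @param stages character subset of
#'   \code{c("stability", "select", "classify", "graph")}; lead matrices,
#'   spectra and features are always computed.
#' @param cohort a [cohort_spec()] (defaults to the study-sized cohort).
#' @param select_trials,select_top_k,select_n trial count and cutoffs for
#'   stability selection.
#' @param classify_trials Monte Carlo trials per classification protocol.
#' @param classifiers classifier names to run.
#' @return configuration list.
#' @export
pipeline_config <- function(seed = 1L, out = tempfile("cyclicity_"),
                            stages = c("stability", "select", "classify",
                                       "graph"),
                            cohort = cohort_spec(seed = seed),
                            select_trials = 1000L, select_top_k = 20L,
                            select_n = 10L, classify_trials = 100L,
                            classifiers = c("linear_svm", "lda", "plsda")) {
  list(seed = as.integer(seed), out = out, stages = stages, cohort = cohort,
       select_trials = as.integer(select_trials),
       select_top_k = as.integer(select_top_k),
       select_n = as.integer(select_n),
       classify_trials = as.integer(classify_trials),
       classifiers = classifiers)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()]; the
#' \code{cohort} block is passed to [cohort_spec()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_spec, c(y$cohort,
                                   if (is.null(y$cohort$seed))
                                     list(seed = y$seed %||% 1L)))
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipeline_config, c(args, list(cohort = cohort)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate -> lead matrices -> spectra -> features, then the configured
#' stages.  All result tables are written as CSV under \code{config$out};
#' a provenance log (seed, stage parameters, package version) is written
#' as JSON.
#'
#' @param config list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param cohort optionally, a pre-generated cohort (skips simulation).
#' @return results bundle (invisibly): cohort features, spectra,
#'   stability/selection/classification/graph outputs as configured.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- gen_cohort(config$cohort)
  cf <- cohort_features(cohort)
  res <- list(config = config, features = cf)

  spectra <- t(vapply(cohort$timecourse, function(x)
    spectral_decomposition(lead_matrix(x))$strengths[, 1L],
    numeric(nrow(cohort$timecourse[[1L]]))))
  res$strength_ranking <- strength_ranking(spectra, cf$meta$group)
  utils::write.csv(res$strength_ranking,
                   file.path(config$out, "strength_ranking.csv"))

  if ("stability" %in% config$stages) {
    id <- knn_session_identification(cf$features, cf$meta$subject_id,
                                     cf$meta$session)
    res$stability <- id
    utils::write.csv(id$confusion, file.path(config$out, "confusion_knn.csv"))
    jsonlite::write_json(list(overall_accuracy = id$overall_accuracy,
                              per_subject_correct = as.list(id$per_subject_correct)),
                         file.path(config$out, "stability.json"),
                         auto_unbox = TRUE)
  }
  if (any(c("select", "classify", "graph") %in% config$stages)) {
    rk <- rank_pairs(cf$features, cf$meta$group)
    mc <- monte_carlo_stability(cf$features, cf$meta$group,
                                cf$meta$subject_id,
                                n_trials = config$select_trials,
                                top_k = config$select_top_k,
                                seed = config$seed + 1L)
    stable <- select_stable(mc$counts, config$select_n, rk$lambda)
    res$selection <- list(ranking = rk, stability = mc, stable = stable)
    utils::write.csv(data.frame(pair = rk$pairs, lambda = rk$lambda,
                                rank = order(rk$ranks), count = mc$counts),
                     file.path(config$out, "selection.csv"), row.names = FALSE)
  }
  if ("classify" %in% config$stages) {
    res$classification <- lapply(config$classifiers, function(cl) {
      pr <- classification_protocol(feature_mode = "pca10", classifier = cl,
                                    n_trials = config$classify_trials,
                                    seed = config$seed + 2L)
      monte_carlo_classification(cf$features, cf$meta, pr)
    })
    names(res$classification) <- config$classifiers
    acc <- vapply(res$classification, `[[`, 0, "overall_accuracy")
    utils::write.csv(data.frame(classifier = names(acc),
                                overall_accuracy = acc),
                     file.path(config$out, "classification.csv"),
                     row.names = FALSE)
  }
  if ("graph" %in% config$stages) {
    top20 <- res$selection$ranking$ranks[seq_len(min(20L,
                length(res$selection$ranking$ranks)))]
    pidx <- pair_index(nrow(cohort$timecourse[[1L]]))[top20, , drop = FALSE]
    lm_all <- lapply(cohort$timecourse, lead_matrix)
    res$graphs <- lapply(c(a = "a", b = "b"), function(g) {
      keep <- cf$meta$group == g
      consistency_graph(lm_all[keep], cf$meta$subject_id[keep], pidx)
    })
    res$flips <- flipped_edges(res$graphs$a, res$graphs$b)
    for (g in names(res$graphs)) {
      e <- res$graphs[[g]]$edges
      e$layer_source <- res$graphs[[g]]$layers[e$from]
      e$layer_target <- res$graphs[[g]]$layers[e$to]
      utils::write.csv(e, file.path(config$out, paste0("graph_", g, ".csv")),
                       row.names = FALSE)
    }
  }
  prov <- list(seed = config$seed, stages = config$stages,
               cohort = unclass(config$cohort),
               package_version = as.character(utils::packageVersion("cyclicity")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(config$out, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
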