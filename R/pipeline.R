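#' Pipeline configuration
#'
#' Validated bundle of the hyper-parameters and thresholds of the full
#' repositioning pipeline. Defaults are the learning-curve optimum for the
#' classifier (learning rate 0.06, training threshold 0.30, validation
#' threshold 0.06, regularisation weight 1, at least 200 iterations with
#' the last 100 averaged) and the published network thresholds (pruning
#' grid 0.20--0.95, star threshold 0.9, correlation threshold 0.4).
#'
#' @param learning_rate,lambda,batch_size,iterations,averaging_window,training_threshold
#'   passed to [softmax_train()].
#' @param validation_threshold probability cut-off for validation accuracy.
#' @param k_folds number of drug-level cross-validation folds (>= 2).
#' @param kmeans_k number of k-means groups in [credible_set()].
#' @param er_thresholds DTN-T pruning grid for [er_threshold_stability()].
#' @param combine_thresholds thresholds averaged by [combined_er()].
#' @param star_threshold star-call probability cut-off (strict `>`).
#' @param rho_threshold cross-network correlation cut-off (strict `>`).
#' @param cv whether to run drug-level cross-validation.
#' @param synthetic optional [synthetic_spec()]: generate the cohort rather
#'   than reading it.
#' @param expression,labels,side_effects,fingerprints input paths (GCT /
#'   TSV) used when `synthetic` is `NULL`; the two feature-set paths are
#'   optional.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(learning_rate = 0.06, lambda = 1,
                            batch_size = 32L, iterations = 200L,
                            averaging_window = 100L,
                            training_threshold = 0.30,
                            validation_threshold = 0.06,
                            k_folds = 5L, kmeans_k = 2L,
                            er_thresholds = seq(0.20, 0.95, by = 0.05),
                            combine_thresholds = seq(0.70, 0.95, by = 0.05),
                            star_threshold = 0.9, rho_threshold = 0.4,
                            cv = TRUE, synthetic = NULL,
                            expression = NULL, labels = NULL,
                            side_effects = NULL, fingerprints = NULL) {
  cfg <- list(
    learning_rate = learning_rate, lambda = lambda,
    batch_size = as.integer(batch_size), iterations = as.integer(iterations),
    averaging_window = as.integer(averaging_window),
    training_threshold = training_threshold,
    validation_threshold = validation_threshold,
    k_folds = as.integer(k_folds), kmeans_k = as.integer(kmeans_k),
    er_thresholds = er_thresholds, combine_thresholds = combine_thresholds,
    star_threshold = star_threshold, rho_threshold = rho_threshold,
    cv = isTRUE(cv), synthetic = synthetic,
    expression = expression, labels = labels,
    side_effects = side_effects, fingerprints = fingerprints
  )
  thr <- c(cfg$training_threshold, cfg$validation_threshold,
           cfg$star_threshold, cfg$er_thresholds, cfg$combine_thresholds)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  if (cfg$averaging_window > cfg$iterations) {
    stop("averaging_window must not exceed iterations")
  }
  if (cfg$averaging_window < 1L) stop("averaging_window must be at least 1")
  if (cfg$k_folds < 2L) stop("k_folds must be at least 2")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (!is.null(cfg$synthetic)) stopifnot(inherits(cfg$synthetic, "synthetic_spec"))
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$expression) || is.null(cfg$labels))) {
    stop("either `synthetic` or both `expression` and `labels` paths are required")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping of [pipeline_config()] arguments; a `synthetic`
#' sub-mapping is passed to [synthetic_spec()].
#'
#' @param path path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

# Deterministically formatted TSV writers: the acceptance surface of the
# pipeline is diffable text, probabilities at 6 decimals.
write_matrix_tsv <- function(m, path, digits = 6L) {
  fmt <- sprintf("%%.%df", digits)
  lines <- c(
    paste(c("id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      cells <- ifelse(is.na(m[i, ]), "NA", sprintf(fmt, m[i, ]))
      paste(c(rownames(m)[i], cells), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

write_df_tsv <- function(df, path, digits = 6L) {
  num <- vapply(df, is.numeric, NA)
  for (cl in names(df)[num]) {
    if (!all(df[[cl]] == round(df[[cl]]), na.rm = TRUE)) {
      df[[cl]] <- sprintf(sprintf("%%.%df", digits), df[[cl]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_feature_sets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
}

write_feature_sets <- function(sets, path) {
  df <- data.frame(
    drug_id = rep(names(sets), lengths(sets)),
    item_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full repositioning pipeline
#'
#' Drives every stage end to end: acquire the cohort (synthetic or from
#' files), collapse trials into credible sets, cross-validate and train
#' the softmax classifier, average the last iterations into the
#' probability matrix, build DTN-T and its enrichment-ratio analysis,
#' project the side-effect / fingerprint similarity networks onto the ATC
#' communities, and call star drugs. All outputs are written as TSV (plus
#' a GCT for expression data and a JSON run log) under `out_dir`; given
#' the same configuration and seed the outputs are byte-identical across
#' runs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; every stage derives its own sub-seed
#'   from it.
#' @return Invisibly, a list bundle: the cohort pieces, the fit, the
#'   probability matrix, `dtnt`, ER matrices, projections and
#'   correlations, star tables, and the metrics log.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p6 <- function(name) file.path(out_dir, name)

  # -- stage: data ----------------------------------------------------------
  data <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic, seed = seed)
      se_sets <- generate_side_effect_sets(cohort$labels, config$synthetic,
                                           truth = cohort$truth,
                                           seed = seed + 1000L)
      fp_sets <- generate_fingerprints(cohort$labels, config$synthetic,
                                       truth = cohort$truth,
                                       seed = seed + 2000L)
      write_gct(cohort$expression, p6("expression.gct"))
      write_label_table(cohort$labels, p6("labels.tsv"))
      write_feature_sets(se_sets, p6("side_effects.tsv"))
      write_feature_sets(fp_sets, p6("fingerprints.tsv"))
      jsonlite::write_json(cohort$truth, p6("truth.json"))
      list(expr = cohort$expression, labels = cohort$labels,
           classes = cohort$classes, truth = cohort$truth,
           se_sets = se_sets, fp_sets = fp_sets)
    } else {
      expr <- read_gct(config$expression)
      labels <- read_label_table(config$labels)
      missing <- setdiff(unique(expr$drugs), names(labels))
      if (length(missing)) {
        stop("drug(s) without labels: ", paste(missing, collapse = ", "))
      }
      list(
        expr = expr, labels = labels, classes = atc_letters(), truth = NULL,
        se_sets = if (!is.null(config$side_effects)) read_feature_sets(config$side_effects),
        fp_sets = if (!is.null(config$fingerprints)) read_feature_sets(config$fingerprints)
      )
    }
  })

  # -- stage: preprocess ----------------------------------------------------
  credible <- run_stage("preprocess", {
    cs <- credible_expression(data$expr, k = config$kmeans_k,
                              seed = seed + 100L)
    write_gct(cs, p6("credible_set.gct"))
    cs
  })

  # -- stage: train ---------------------------------------------------------
  trained <- run_stage("train", {
    y <- label_matrix(as.list(data$labels[credible$drugs]), data$classes)
    rownames(y) <- credible$sample_ids
    cv_tab <- NULL
    if (config$cv) {
      cv_tab <- cross_validate(
        credible$values, y, credible$drugs, k = config$k_folds,
        training_threshold = config$training_threshold,
        validation_threshold = config$validation_threshold,
        seed = seed + 200L,
        learning_rate = config$learning_rate, lambda = config$lambda,
        batch_size = config$batch_size, iterations = config$iterations,
        averaging_window = config$averaging_window
      )
    }
    fit <- softmax_train(
      credible$values, y,
      learning_rate = config$learning_rate, lambda = config$lambda,
      batch_size = config$batch_size, iterations = config$iterations,
      averaging_window = config$averaging_window,
      training_threshold = config$training_threshold, seed = seed + 300L
    )
    prob <- averaged_probability_matrix(fit, credible$drugs)
    write_matrix_tsv(prob, p6("probability_matrix.tsv"))

    p_samples <- predict(fit, credible$values, type = "prob")
    cm <- confusion_matrix_counts(y, max.col(p_samples, ties.method = "first"))
    write_matrix_tsv(cm, p6("confusion_matrix.tsv"), digits = 0L)

    log <- list(
      seed = seed,
      hyper_parameters = config[c("learning_rate", "lambda", "batch_size",
                                  "iterations", "averaging_window",
                                  "training_threshold", "validation_threshold",
                                  "k_folds", "kmeans_k", "star_threshold",
                                  "rho_threshold")],
      per_iteration = fit$history,
      cross_validation = cv_tab
    )
    jsonlite::write_json(log, p6("metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    list(fit = fit, prob = prob, y = y, cv = cv_tab)
  })

  # -- stage: networks ------------------------------------------------------
  networks <- run_stage("networks", {
    dtnt <- build_dtn_t(trained$prob, data$labels)
    write_matrix_tsv(dtnt$p, p6("dtn_t.tsv"))
    stability <- er_threshold_stability(dtnt, config$er_thresholds)
    write_matrix_tsv(stability, p6("er_stability.tsv"))
    er_comb <- combined_er(dtnt, config$combine_thresholds)
    write_matrix_tsv(er_comb, p6("er_combined.tsv"))

    partition <- community_partition(data$labels, data$classes)
    projections <- list()
    rho <- list()
    if (!is.null(data$se_sets)) {
      sim_se <- similarity_network(data$se_sets, "jaccard")
      projections$se <- node_to_community(sim_se, partition)
      rho$se <- cross_network_spearman(dtnt, projections$se)
      write_matrix_tsv(projections$se, p6("dtn_se.tsv"))
      write_df_tsv(data.frame(drug = names(rho$se), rho = unname(rho$se)),
                   p6("rho_se.tsv"))
    }
    if (!is.null(data$fp_sets)) {
      sim_st <- similarity_network(data$fp_sets, "tanimoto")
      projections$st <- node_to_community(sim_st, partition)
      rho$st <- cross_network_spearman(dtnt, projections$st)
      write_matrix_tsv(projections$st, p6("dtn_st.tsv"))
      write_df_tsv(data.frame(drug = names(rho$st), rho = unname(rho$st)),
                   p6("rho_st.tsv"))
    }
    list(dtnt = dtnt, stability = stability, er_combined = er_comb,
         projections = projections, rho = rho)
  })

  # -- stage: stars ---------------------------------------------------------
  stars <- run_stage("stars", {
    calls <- find_stars(networks$dtnt, config$star_threshold)
    s1 <- sd1(calls)
    s2 <- if (!is.null(networks$rho$se)) {
      sd_by_correlation(calls, networks$rho$se, config$rho_threshold)
    } else {
      character()
    }
    s3 <- if (!is.null(networks$rho$st)) {
      sd_by_correlation(calls, networks$rho$st, config$rho_threshold)
    } else {
      character()
    }
    credible_set <- credible_star_set(s1, s2, s3)
    write_df_tsv(calls, p6("star_calls.tsv"))
    write_df_tsv(credible_set, p6("credible_stars.tsv"))
    list(calls = calls, sd1 = s1, sd2 = s2, sd3 = s3,
         credible = credible_set)
  })

  invisible(list(
    config = config, seed = seed, data = data, credible = credible,
    fit = trained$fit, probability = trained$prob, cv = trained$cv,
    networks = networks, stars = stars, out_dir = out_dir
  ))
}
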