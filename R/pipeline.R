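#' Pipeline configuration
#'
#' Defaults are the method's standard operating point: smoothing window 7,
#' maximum gap 13, 80 latent topics, five folds, 10 preferred topics and
#' up to 20 words per topic per class.
#'
#' @param sequences path to the input protein FASTA.
#' @param labels path to a two-column TSV (`id`, `label`); required for
#'   `train` / `signatures` / `evaluate`.
#' @param profiles directory of `<id>.pssm` PSI-BLAST ASCII profiles, or
#'   `NULL` to rely on the pseudo-profile fallback.
#' @param out output directory.
#' @param window odd smoothing window size.
#' @param d_max maximum gapped-dipeptide gap.
#' @param topics number of latent topics.
#' @param folds cross-validation folds.
#' @param topics_per_class,words_per_topic signature selection sizes.
#' @param mode `"plsi"` or `"signatures"`.
#' @param seed master seed; all stage seeds are derived from it.
#' @param strict_profiles if `TRUE`, a missing profile file is an error
#'   instead of triggering the pseudo-profile fallback.
#' @param grid SVM tuning grid.
#' @param tune_folds inner SVM tuning folds.
#' @param plsi_max_iter,plsi_tol aspect-model EM controls.
#' @export
pipeline_config <- function(sequences = NULL, labels = NULL,
                            profiles = NULL, out = "nucsig_out",
                            window = 7L, d_max = 13L, topics = 80L,
                            folds = 5L, topics_per_class = 10L,
                            words_per_topic = 20L,
                            mode = c("plsi", "signatures"), seed = 1L,
                            strict_profiles = FALSE,
                            grid = default_svm_grid(), tune_folds = 3L,
                            plsi_max_iter = 200L, plsi_tol = 1e-6) {
  mode <- match.arg(mode)
  cfg <- list(sequences = sequences, labels = labels, profiles = profiles,
              out = out, window = as.integer(window),
              d_max = as.integer(d_max), topics = as.integer(topics),
              folds = as.integer(folds),
              topics_per_class = as.integer(topics_per_class),
              words_per_topic = as.integer(words_per_topic),
              mode = mode, seed = as.integer(seed),
              strict_profiles = isTRUE(strict_profiles),
              grid = grid, tune_folds = as.integer(tune_folds),
              plsi_max_iter = as.integer(plsi_max_iter),
              plsi_tol = plsi_tol,
              # recorded for users who run PSI-BLAST themselves; the
              # pipeline itself never invokes it
              psiblast = list(iterations = 3L, evalue = 1e-3,
                              database = "nr"))
  class(cfg) <- "pipeline_config"
  cfg
}

read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$label, df$id)
}

# Load sequences, resolve profiles (file cache or pseudo-profile
# fallback), smooth, and build feature vectors.  Per-protein profile
# failures are collected, not fatal, unless strict_profiles is set.
pipeline_features <- function(config) {
  records <- read_proteins(config$sequences)
  failures <- character(0)
  fvs <- list()
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    seq <- records$sequence[k]
    prof <- NULL
    pssm_path <- if (!is.null(config$profiles)) {
      file.path(config$profiles, paste0(id, ".pssm"))
    } else ""
    if (nzchar(pssm_path) && file.exists(pssm_path)) {
      prof <- tryCatch(read_pssm(pssm_path, seq, protein_id = id),
                       error = function(e) {
                         failures <<- c(failures,
                                        paste0(id, ": ", conditionMessage(e)))
                         NULL
                       })
    } else if (config$strict_profiles) {
      failures <- c(failures, paste0(id, ": profile file missing (",
                                     pssm_path, ")"))
    }
    if (is.null(prof) && !config$strict_profiles) {
      prof <- tryCatch(pseudo_profile(id, seq), error = function(e) {
        failures <<- c(failures, paste0(id, ": ", conditionMessage(e)))
        NULL
      })
    }
    if (is.null(prof)) next
    fvs[[id]] <- build_feature_vector(smooth_profile(prof, config$window),
                                      d_max = config$d_max)
  }
  if (length(fvs) == 0L) stop("no protein could be processed")
  list(features = fvs, records = records, failures = failures)
}

log_run <- function(config, command, extra = list()) {
  cfg <- unclass(config)
  cfg$grid <- NULL
  c(list(command = command,
         package_version = as.character(utils::packageVersion("nucsig")),
         r_version = as.character(getRversion()),
         config = cfg),
    extra)
}

#' Run the prediction pipeline
#'
#' Orchestrates the five pipeline stages (profile, smooth, weight, reduce,
#' classify) behind five commands:
#' \describe{
#'   \item{features}{write the sparse gapped-dipeptide feature TSV.}
#'   \item{train}{fit the aspect model and classifier; write the model
#'     bundle (and, in signature mode, the signature TSV).}
#'   \item{signatures}{fit the aspect model and write the signature TSV.}
#'   \item{predict}{load a trained bundle and classify new sequences.}
#'   \item{evaluate}{run the stratified cross-validation harness and write
#'     the per-fold / pooled report.}
#' }
#' Every run writes `run_info.json` (command, config, seed, versions,
#' per-protein failures) into the output directory.
#'
#' @param config a [pipeline_config()].
#' @param command one of `features`, `train`, `signatures`, `predict`,
#'   `evaluate`.
#' @param model_dir for `predict`: directory holding a bundle written by
#'   `train`.
#' @return invisibly, a list of produced artifact paths plus command
#'   results.
#' @export
run_pipeline <- function(config,
                         command = c("features", "train", "signatures",
                                     "predict", "evaluate"),
                         model_dir = NULL) {
  command <- match.arg(command)
  if (is.null(config$sequences)) stop("config error: sequences path unset")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  fp <- pipeline_features(config)
  artifacts <- list()
  info_extra <- list(n_proteins = length(fp$features),
                     failures = fp$failures)

  if (command == "features") {
    path <- file.path(config$out, "features.tsv")
    write_feature_tsv(fp$features, path)
    artifacts$features <- path
  }

  if (command %in% c("train", "signatures", "evaluate")) {
    if (is.null(config$labels)) stop("config error: labels path unset")
    labels <- read_labels_tsv(config$labels)
  }

  if (command %in% c("train", "signatures")) {
    corpus <- build_corpus(fp$features)
    model <- train_plsi(corpus, K = config$topics,
                        max_iter = config$plsi_max_iter,
                        tol = config$plsi_tol, seed = config$seed)
    prefs <- compute_topic_preferences(model,
                                       labels[names(fp$features)])
    sigs <- select_signatures(model, prefs,
                              topics_per_class = config$topics_per_class,
                              words_per_topic = config$words_per_topic)
    sig_path <- file.path(config$out, "signatures.tsv")
    write_signatures(sigs, sig_path)
    artifacts$signatures <- sig_path
    if (command == "train") {
      plsi_path <- file.path(config$out, "plsi_model.json")
      write_plsi(model, plsi_path)
      artifacts$plsi_model <- plsi_path
      if (config$mode == "plsi") {
        # fold training documents in with frozen P(w|t) so training and
        # prediction features share one geometry
        x <- t(vapply(fp$features, function(fv) {
          fold_in(model, fv$weights)
        }, numeric(model$K)))
        colnames(x) <- paste0("t", seq_len(model$K))
        fm <- "plsi_topics"
      } else {
        x <- signature_matrix(fp$features, sigs)
        fm <- "signatures"
      }
      clf <- tune_and_train(x, labels[names(fp$features)],
                            grid = config$grid,
                            folds = config$tune_folds, seed = config$seed,
                            feature_mode = fm)
      clf_path <- file.path(config$out, "classifier.json")
      write_classifier(clf, clf_path)
      artifacts$classifier <- clf_path
    }
  }

  if (command == "predict") {
    if (is.null(model_dir)) stop("config error: model_dir required")
    clf <- read_classifier(file.path(model_dir, "classifier.json"))
    if (clf$feature_mode == "plsi_topics") {
      model <- read_plsi(file.path(model_dir, "plsi_model.json"))
      x <- t(vapply(fp$features, function(fv) {
        suppressWarnings(fold_in(model, fv$weights))
      }, numeric(model$K)))
      low_conf <- vapply(fp$features, function(fv) {
        !any(names(fv$weights) %in% model$vocabulary)
      }, logical(1))
    } else {
      sigs <- read_signatures(file.path(model_dir, "signatures.tsv"))
      x <- signature_matrix(fp$features, sigs)
      low_conf <- rowSums(x) == 0
    }
    pr <- predict_localization(clf, x)
    out <- data.frame(id = names(fp$features), class = pr$class,
                      probability = pr$probability,
                      out_of_vocabulary = unname(low_conf),
                      stringsAsFactors = FALSE)
    path <- file.path(config$out, "predictions.tsv")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$predictions <- path
  }

  if (command == "evaluate") {
    cv <- cross_validate(fp$features, labels[names(fp$features)],
                         mode = config$mode, folds = config$folds,
                         seed = config$seed, topics = config$topics,
                         topics_per_class = config$topics_per_class,
                         words_per_topic = config$words_per_topic,
                         grid = config$grid,
                         tune_folds = config$tune_folds,
                         plsi_max_iter = config$plsi_max_iter,
                         plsi_tol = config$plsi_tol)
    write_cv_report(cv, file.path(config$out, "cv_report.tsv"),
                    file.path(config$out, "cv_report.json"))
    pred_path <- file.path(config$out, "cv_predictions.tsv")
    utils::write.table(cv$predictions, pred_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$cv_report <- file.path(config$out, "cv_report.tsv")
    artifacts$cv_predictions <- pred_path
    artifacts$cv <- cv
  }

  jsonlite::write_json(log_run(config, command, info_extra),
                       file.path(config$out, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  artifacts$run_info <- file.path(config$out, "run_info.json")
  invisible(artifacts)
}
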