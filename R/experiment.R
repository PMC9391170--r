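#' Run the full pipeline on a ranges table and patient cohort
#'
#' Orchestrates the complete protocol: build the indicator-value knowledge
#' graph, train translational embeddings (holding out a slice of triples for
#' link-prediction evaluation), encode the patients as relation matrices,
#' split them into stratified train/test portions (a single 80/20 holdout or
#' full k-fold cross-validation), optionally rebalance the training portion
#' with SMOTE in measurement space, train the attention-convolution
#' classifier, and report classification metrics per fold together with the
#' embedding ranking metrics and loss histories.
#'
#' All stage seeds are derived from `seed`, so the whole experiment is
#' reproducible from one integer.
#'
#' @param ranges List of [reference_range()] objects.
#' @param patients Data frame with one column per indicator plus a binary
#'   `label` column; empty cells are missing values.
#' @param model Embedding model: `"TransH"` (default), `"TransE"`, `"TransR"`.
#' @param dim Embedding dimension.
#' @param norm_order 1 or 2.
#' @param trans_cfg [trans_config()] for the embedding stage (its seed is
#'   overridden by `seed`).
#' @param sac_cfg [sac_config()] for the classifier (seed likewise
#'   overridden).
#' @param encoder `"knowledge"` uses the graph embeddings (relation vectors);
#'   `"learned"` is the ablation that trains a free embedding table jointly
#'   with the classifier.
#' @param split `"holdout"` (single stratified 80/20 split, the default) or
#'   `"cv"` (all `folds` folds).
#' @param folds Number of folds (also sets the holdout test fraction to
#'   `1/folds`).
#' @param use_smote Rebalance the training portion with [smote()]?
#' @param smote_test Also rebalance the held-out portion (off by default;
#'   resampling test data inflates apparent performance and is supported only
#'   for protocol parity).
#' @param ranking_fraction Fraction of triples held out for link-prediction
#'   evaluation (capped at `ranking_max`).
#' @param ranking_max Maximum number of held-out triples to rank.
#' @param ranking_side `"head"` or `"tail"` corruption for ranking.
#' @param seed Master integer seed.
#' @return An object of class `"kgdx_experiment"`: a list with `config`,
#'   `graph_summary`, `ranking`, `folds` (per-fold metrics and histories),
#'   and `aggregate` (metrics from the pooled confusion matrix).
#' @export
run_experiment <- function(ranges, patients, model = "TransH", dim = 256,
                           norm_order = 2, trans_cfg = trans_config(),
                           sac_cfg = sac_config(),
                           encoder = c("knowledge", "learned"),
                           split = c("holdout", "cv"), folds = 5,
                           use_smote = FALSE, smote_test = FALSE,
                           ranking_fraction = 0.1, ranking_max = 200,
                           ranking_side = "head", seed = 1L) {
  encoder <- match.arg(encoder)
  split <- match.arg(split)
  stopifnot("label" %in% names(patients))
  y_all <- patients$label
  stopifnot(all(y_all %in% c(0, 1)))

  graph <- build_graph(ranges)
  catalog <- graph$catalog
  order <- catalog$indicators

  # hold out triples for link prediction, train embeddings on the rest
  n_tr <- nrow(graph$triples)
  set.seed(seed)
  n_test <- min(ranking_max, max(1L, floor(ranking_fraction * n_tr)))
  test_idx <- sample.int(n_tr, n_test)
  triples_train <- graph$triples[-test_idx, , drop = FALSE]
  triples_test <- graph$triples[test_idx, , drop = FALSE]

  trans_cfg$seed <- seed + 11L
  params <- NULL
  ranking <- NULL
  if (encoder == "knowledge") {
    params <- train_trans(triples_train, catalog, model = model, dim = dim,
                          norm_order = norm_order, config = trans_cfg)
    ranking <- evaluate_ranking(params, triples_test, catalog,
                                side = ranking_side)
  }

  feature_cols <- patients[, order, drop = FALSE]
  if (encoder == "knowledge") {
    E_all <- encode_cohort(patients, catalog, params, order)
  } else {
    set.seed(seed + 13L)
    table0 <- matrix(stats::runif(n_entities(catalog) * dim, -0.1, 0.1),
                     n_entities(catalog), dim)
    enc <- encode_learned(patients, catalog, table0, order)
  }

  fold_idx <- kfold_split(nrow(patients), k = folds, labels = y_all,
                          seed = seed + 17L)
  eval_folds <- if (split == "holdout") 1L else seq_len(folds)

  fold_reports <- list()
  pooled <- matrix(0, 2, 2)
  for (f in eval_folds) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(nrow(patients)), te)
    sac_cfg$seed <- seed + 23L + f

    if (use_smote || smote_test) {
      train_pat <- feature_cols[tr, , drop = FALSE]
      y_tr <- y_all[tr]
      if (use_smote) {
        sm <- smote(train_pat, y_tr, seed = seed + 29L + f)
        train_pat <- as.data.frame(sm$x)
        names(train_pat) <- order
        y_tr <- sm$y
      }
      test_pat <- feature_cols[te, , drop = FALSE]
      y_te <- y_all[te]
      if (smote_test) {
        sm <- smote(test_pat, y_te, seed = seed + 31L + f)
        test_pat <- as.data.frame(sm$x)
        names(test_pat) <- order
        y_te <- sm$y
      }
      if (encoder == "knowledge") {
        E_tr <- encode_cohort(train_pat, catalog, params, order)
        E_te <- encode_cohort(test_pat, catalog, params, order)
        fit <- train_sac(E_tr, y_tr, sac_cfg, test = list(E = E_te, y = y_te))
        pred <- predict(fit, E_te)
      } else {
        enc_tr <- encode_learned(train_pat, catalog, table0, order)
        enc_te <- encode_learned(test_pat, catalog, table0, order)
        fit <- train_sac(enc_tr$E, y_tr, sac_cfg,
                         test = list(E = enc_te$E, y = y_te,
                                     index = enc_te$index),
                         table = table0, index = enc_tr$index)
        pred <- predict_with_table(fit, catalog, test_pat, order)
      }
    } else {
      y_tr <- y_all[tr]
      y_te <- y_all[te]
      if (encoder == "knowledge") {
        E_tr <- E_all[, , tr, drop = FALSE]
        E_te <- E_all[, , te, drop = FALSE]
        fit <- train_sac(E_tr, y_tr, sac_cfg, test = list(E = E_te, y = y_te))
        pred <- predict(fit, E_te)
      } else {
        fit <- train_sac(enc$E[, , tr, drop = FALSE], y_tr, sac_cfg,
                         test = list(E = enc$E[, , te, drop = FALSE],
                                     y = y_te,
                                     index = enc$index[, te, drop = FALSE]),
                         table = table0, index = enc$index[, tr, drop = FALSE])
        pred <- predict_with_table(fit, catalog, feature_cols[te, , drop = FALSE],
                                   order)
      }
    }
    met <- classification_metrics(y_te, pred$class)
    pooled <- pooled + met$confusion
    fold_reports[[f]] <- list(fold = f, n_train = length(y_tr),
                              n_test = length(y_te), metrics = met,
                              history = fit$history, model = fit)
  }
  fold_reports <- fold_reports[!vapply(fold_reports, is.null, TRUE)]

  aggregate <- metrics_from_confusion(pooled)
  structure(
    list(config = list(model = model, dim = dim, norm_order = norm_order,
                       encoder = encoder, split = split, folds = folds,
                       use_smote = use_smote, smote_test = smote_test,
                       seed = seed, trans = unclass(trans_cfg),
                       sac = unclass(sac_cfg)),
         graph_summary = list(n_entities = n_entities(catalog),
                              n_relations = length(catalog$relation_to_int),
                              n_triples = n_tr),
         ranking = ranking,
         folds = fold_reports,
         aggregate = aggregate),
    class = "kgdx_experiment"
  )
}

# re-encode with the jointly trained table and predict
predict_with_table <- function(fit, catalog, patients, order) {
  enc <- encode_learned(patients, catalog, fit$table, order)
  predict(fit, enc$E)
}

metrics_from_confusion <- function(cm) {
  tn <- cm[1, 1]; fn <- cm[2, 1]; fp <- cm[1, 2]; tp <- cm[2, 2]
  n <- sum(cm)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / n, recall = recall, precision = precision,
       f1 = f1, confusion = cm)
}

#' @export
print.kgdx_experiment <- function(x, ...) {
  cat(sprintf("<kgdx_experiment> %s/%s encoder, %s split\n",
              x$config$model, x$config$encoder, x$config$split))
  if (!is.null(x$ranking)) {
    cat(sprintf("  link prediction: MR %.1f, Hit@10 %.1f%%\n",
                x$ranking$mean_rank, x$ranking$hit_at_10))
  }
  cat(sprintf("  classification: accuracy %.4f, recall %.4f, F1 %.4f\n",
              x$aggregate$accuracy, x$aggregate$recall, x$aggregate$f1))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param experiment A `kgdx_experiment` from [run_experiment()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(experiment, path) {
  rep <- list(
    config = experiment$config,
    graph = experiment$graph_summary,
    ranking = if (!is.null(experiment$ranking)) {
      list(mean_rank = experiment$ranking$mean_rank,
           hit_at_10 = experiment$ranking$hit_at_10)
    },
    folds = lapply(experiment$folds, function(f) {
      list(fold = f$fold, n_train = f$n_train, n_test = f$n_test,
           accuracy = f$metrics$accuracy, recall = f$metrics$recall,
           f1 = f$metrics$f1,
           confusion = as.vector(f$metrics$confusion),
           history = f$history)
    }),
    aggregate = list(accuracy = experiment$aggregate$accuracy,
                     recall = experiment$aggregate$recall,
                     f1 = experiment$aggregate$f1)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
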