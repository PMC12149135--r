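#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` folds stratified jointly by label and
#' subtype, trains on k-1 folds (each training run holds out its own
#' inner validation split for early stopping) and scores the held-out
#' fold. With `n_rounds > 1` the fold assignment is reshuffled each
#' round with a round-specific derived seed, and means/standard
#' deviations are reported across all fold-round combinations.
#'
#' @param data windows tibble or `nm_encoded`
#' @param config an [nm_config()]
#' @param k number of folds (5 or 10 in the standard protocol)
#' @param n_rounds repetition rounds (default 1)
#' @param seed master seed; all fold splits and training runs derive
#'   their seeds from it
#' @param keep_models keep the per-fold fitted models (needed to reuse
#'   the CV in [permutation_importance()])
#' @param ... passed to [nm_train()] (e.g. `max_epochs`)
#' @return Object of class `nm_cv` with per-fold metrics (`folds`),
#'   summary statistics (`summary`), per-sample held-out predictions
#'   (`predictions`), per-fold metric reports (`reports`) and, if
#'   requested, `models` and `fold_assignments`.
#' @export
cross_validate <- function(data, config = nm_config(), k = 5, n_rounds = 1,
                           seed = 1, keep_models = FALSE, ...) {
  enc <- as_encoded(data)
  n <- length(enc$label)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  folds <- list(); preds <- list(); reports <- list()
  models <- list(); assignments <- list()
  for (r in seq_len(n_rounds)) {
    fold <- stratified_folds(enc$label, enc$subtype, k,
                             derive_seed(seed, paste0("cvround", r)))
    assignments[[r]] <- fold
    for (f in seq_len(k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      fit <- nm_train(subset_encoded(enc, tr), config,
                      seed = derive_seed(seed, sprintf("cv_r%d_f%d", r, f)),
                      ...)
      probs <- predict_probs(fit, subset_encoded(enc, te))
      m <- compute_metrics(probs, enc$label[te])
      key <- sprintf("r%d_f%d", r, f)
      folds[[key]] <- dplyr::bind_cols(
        tibble::tibble(round = r, fold = f), tidy(m))
      preds[[key]] <- tibble::tibble(round = r, fold = f, index = te,
                                     prob = as.numeric(probs),
                                     label = enc$label[te])
      reports[[key]] <- m
      if (keep_models) models[[key]] <- fit
    }
  }
  folds <- dplyr::bind_rows(folds)
  metric_cols <- c("acc", "f1", "precision", "recall", "mcc", "auc", "aupr")
  summary <- tidyr::pivot_longer(folds[metric_cols], dplyr::everything(),
                                 names_to = "metric")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value), .groups = "drop")
  summary <- summary[match(metric_cols, summary$metric), ]
  structure(list(folds = folds, summary = summary,
                 predictions = dplyr::bind_rows(preds), reports = reports,
                 models = if (keep_models) models,
                 fold_assignments = assignments,
                 k = k, n_rounds = n_rounds, seed = seed, config = config),
            class = "nm_cv")
}

#' @export
print.nm_cv <- function(x, ...) {
  cat("<nm_cv> ", x$k, "-fold, ", x$n_rounds, " round(s)\n", sep = "")
  auc <- x$summary[x$summary$metric == "auc", ]
  acc <- x$summary[x$summary$metric == "acc", ]
  cat(sprintf("  mean AUC %.4f (sd %.4f), mean ACC %.4f\n",
              auc$mean, auc$sd, acc$mean))
  invisible(x)
}

#' Per-fold metrics of a cross-validation
#' @param x an `nm_cv`
#' @param ... unused
#' @export
tidy.nm_cv <- function(x, ...) x$folds

#' One-row cross-validation summary (mean and sd per metric)
#' @param x an `nm_cv`
#' @param ... unused
#' @export
glance.nm_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  sds <- stats::setNames(as.list(x$summary$sd),
                         paste0("sd_", x$summary$metric))
  tibble::as_tibble(c(wide, sds, list(k = x$k, n_rounds = x$n_rounds)))
}

#' Fold-wise ROC / PR curves of a cross-validation
#' @param object an `nm_cv`
#' @param curve `"roc"`, `"pr"` or `"both"`
#' @param ... unused
#' @export
autoplot.nm_cv <- function(object, curve = c("both", "roc", "pr"), ...) {
  curve <- match.arg(curve)
  dfs <- purrr::imap(object$reports, function(m, key) {
    roc <- dplyr::mutate(m$roc_points, panel = "ROC", x = .data$fpr,
                         y = .data$tpr, fold = key)
    pr <- dplyr::mutate(m$pr_points, panel = "Precision-Recall",
                        x = .data$recall, y = .data$precision, fold = key)
    cols <- c("panel", "x", "y", "fold")
    switch(curve, roc = roc[cols], pr = pr[cols],
           both = dplyr::bind_rows(roc[cols], pr[cols]))
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(.data$x, .data$y, colour = .data$fold)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "fold") +
    ggplot2::theme_minimal()
}

permute_view <- function(enc, view, pos, perm) {
  if (view == "seq") {
    # position p's base identity enters the network twice: as the CNN
    # input row and as the structure graph's node feature; the probe
    # permutes both, or the graph would leak the identity back in
    enc$x_seq[pos, , ] <- enc$x_seq[pos, , perm, drop = FALSE]
    enc$x_node[pos, , ] <- enc$x_node[pos, , perm, drop = FALSE]
  } else if (view == "chem") {
    enc$x_chem[pos, , ] <- enc$x_chem[pos, , perm, drop = FALSE]
  } else {
    # permute row and column `pos` with the same sample permutation,
    # which preserves symmetry and the zero diagonal
    enc$x_str[pos, , ] <- enc$x_str[pos, , perm, drop = FALSE]
    enc$x_str[, pos, ] <- enc$x_str[, pos, perm, drop = FALSE]
  }
  enc
}

#' Per-position permutation importance of one feature view
#'
#' For every window position p, the rows of the chosen view at p are
#' permuted across the held-out samples of each cross-validation fold
#' (breaking the position-feature association while preserving its
#' marginal distribution), the model is re-scored, and the importance is
#' the drop `AUC_standard - AUC_permuted`, averaged over folds. Positive
#' values mean the position matters; the vector has one entry per
#' window position (51 for the default window).
#'
#' For the structure view, row and column p of the base-pair matrix are
#' permuted together with one sample permutation, which keeps each
#' matrix symmetric with a zero diagonal.
#'
#' @param data windows tibble or `nm_encoded`
#' @param config an [nm_config()]
#' @param view `"seq"`, `"chem"` or `"str"`; must be enabled in `config`
#' @param n_folds CV folds to train (ignored when `cv` is given)
#' @param seed master seed
#' @param cv optionally an `nm_cv` trained with `keep_models = TRUE` on
#'   the same `data` (single round), to reuse its fold models
#' @param mode `"across"` permutes a position across samples (standard
#'   permutation importance); `"within"` instead swaps each sample's
#'   position-p rows with a random other position of the same sample
#' @param ... passed to [cross_validate()] when `cv` is not supplied
#' @return Object of class `nm_importance`: tibble with `view`,
#'   `position` (0-based) and `importance` (delta AUC).
#' @export
permutation_importance <- function(data, config = nm_config(),
                                   view = c("seq", "chem", "str"),
                                   n_folds = 5, seed = 1, cv = NULL,
                                   mode = c("across", "within"), ...) {
  view <- match.arg(view)
  mode <- match.arg(mode)
  enabled <- switch(view, seq = config$use_seq, chem = config$use_chem,
                    str = config$use_str)
  if (!enabled) stop("view '", view, "' is disabled in config", call. = FALSE)
  enc <- as_encoded(data)
  L <- dim(enc$x_seq)[1]
  if (is.null(cv)) {
    cv <- cross_validate(enc, config, k = n_folds, n_rounds = 1,
                         seed = seed, keep_models = TRUE, ...)
  }
  if (is.null(cv$models)) {
    stop("cv must be run with keep_models = TRUE", call. = FALSE)
  }
  fold <- cv$fold_assignments[[1]]
  k <- cv$k
  imp <- numeric(L)
  set.seed(derive_seed(seed, "perm"))
  for (f in seq_len(k)) {
    te <- which(fold == f)
    fit <- cv$models[[sprintf("r1_f%d", f)]]
    enc_te <- subset_encoded(enc, te)
    base_auc <- compute_metrics(predict_probs(fit, enc_te),
                                enc_te$label)$auc
    for (p in seq_len(L)) {
      enc_p <- if (mode == "across") {
        permute_view(enc_te, view, p, sample(length(te)))
      } else {
        q <- sample(setdiff(seq_len(L), p), 1)
        e <- enc_te
        if (view == "seq") {
          e$x_seq[c(p, q), , ] <- e$x_seq[c(q, p), , , drop = FALSE]
          e$x_node[c(p, q), , ] <- e$x_node[c(q, p), , , drop = FALSE]
        } else if (view == "chem") {
          e$x_chem[c(p, q), , ] <- e$x_chem[c(q, p), , , drop = FALSE]
        } else {
          e$x_str[c(p, q), , ] <- e$x_str[c(q, p), , , drop = FALSE]
          e$x_str[, c(p, q), ] <- e$x_str[, c(q, p), , drop = FALSE]
        }
        e
      }
      auc_p <- compute_metrics(predict_probs(fit, enc_p), enc_te$label)$auc
      imp[p] <- imp[p] + (base_auc - auc_p) / k
    }
  }
  structure(tibble::tibble(view = view, position = seq_len(L) - 1L,
                           importance = imp),
            class = c("nm_importance", "tbl_df", "tbl", "data.frame"))
}

#' Importance profile plot
#' @param object an `nm_importance`
#' @param ... unused
#' @export
autoplot.nm_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "window position (0-based)",
                  y = "importance (AUC drop when permuted)",
                  title = paste0("Permutation importance: ",
                                 object$view[1], " view")) +
    ggplot2::theme_minimal()
}

#' Cross-subtype train/test matrix
#'
#' Holds out a stratified test portion, then trains one model per
#' training set (each single subtype, plus all subtypes pooled) and
#' evaluates every model on every subtype's held-out test set, yielding
#' the 5 x 4 grid of AUC/AUPR. Train and test sets are disjoint by
#' construction (verified).
#'
#' @param data windows tibble or `nm_encoded` with subtypes
#' @param config an [nm_config()]
#' @param seed master seed
#' @param test_frac held-out test fraction (default 0.25)
#' @param ... passed to [nm_train()]
#' @return Object of class `nm_crosstype`: tibble with `train_subtype`
#'   (Am/Cm/Gm/Um/all), `test_subtype`, `auc`, `aupr`, `n_train`,
#'   `n_test`.
#' @export
cross_type_matrix <- function(data, config = nm_config(), seed = 1,
                              test_frac = 0.25, ...) {
  enc <- as_encoded(data)
  if (anyNA(enc$subtype)) stop("data must carry subtypes", call. = FALSE)
  k <- max(2L, round(1 / test_frac))
  fold <- stratified_folds(enc$label, enc$subtype, k,
                           derive_seed(seed, "crosstype"))
  te_all <- which(fold == 1L)
  tr_all <- which(fold != 1L)
  stopifnot(length(intersect(te_all, tr_all)) == 0)
  train_sets <- c(stats::setNames(
    lapply(NM_SUBTYPES, function(st) tr_all[enc$subtype[tr_all] == st]),
    NM_SUBTYPES), list(all = tr_all))
  test_sets <- stats::setNames(
    lapply(NM_SUBTYPES, function(st) te_all[enc$subtype[te_all] == st]),
    NM_SUBTYPES)
  rows <- list()
  for (tr_name in names(train_sets)) {
    tr <- train_sets[[tr_name]]
    fit <- nm_train(subset_encoded(enc, tr), config,
                    seed = derive_seed(seed, paste0("ct_", tr_name)), ...)
    for (te_name in names(test_sets)) {
      te <- test_sets[[te_name]]
      stopifnot(length(intersect(tr, te)) == 0)
      m <- compute_metrics(predict_probs(fit, subset_encoded(enc, te)),
                           enc$label[te])
      rows[[paste(tr_name, te_name)]] <- tibble::tibble(
        train_subtype = tr_name, test_subtype = te_name,
        auc = m$auc, aupr = m$aupr,
        n_train = length(tr), n_test = length(te))
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("nm_crosstype", "tbl_df", "tbl", "data.frame"))
}

#' Heatmap of the cross-subtype matrix
#' @param object an `nm_crosstype`
#' @param metric `"auc"` or `"aupr"`
#' @param ... unused
#' @export
autoplot.nm_crosstype <- function(object, metric = c("auc", "aupr"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$train_subtype, .data$test_subtype,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data[[metric]])), colour = "white") +
    ggplot2::labs(x = "trained on", y = "tested on",
                  fill = toupper(metric)) +
    ggplot2::theme_minimal()
}

ABLATION_GRID <- tibble::tribble(
  ~method,      ~use_seq, ~use_chem, ~use_str,
  "Seq",        TRUE,     FALSE,     FALSE,
  "Che",        FALSE,    TRUE,      FALSE,
  "Str",        FALSE,    FALSE,     TRUE,
  "Seq+Che",    TRUE,     TRUE,      FALSE,
  "Seq+Str",    TRUE,     FALSE,     TRUE,
  "Che+Str",    FALSE,    TRUE,      TRUE,
  "All",        TRUE,     TRUE,      TRUE
)

#' Feature-view ablation study
#'
#' Cross-validates the seven feature-view combinations (each single
#' view, each pair, and all three) under one shared fold scheme, so
#' differences between rows reflect the views, not the splits.
#'
#' @param data windows tibble or `nm_encoded`
#' @param config base [nm_config()]; the view switches are overridden
#'   row by row
#' @param seed master seed
#' @param k CV folds per combination
#' @param ... passed to [cross_validate()]
#' @return Object of class `nm_ablation`: tibble with one row per
#'   combination and its mean cross-validated metrics.
#' @export
run_ablation <- function(data, config = nm_config(), seed = 1, k = 5, ...) {
  enc <- as_encoded(data)
  rows <- list()
  for (i in seq_len(nrow(ABLATION_GRID))) {
    g <- ABLATION_GRID[i, ]
    cfg <- config
    cfg$use_seq <- g$use_seq; cfg$use_chem <- g$use_chem
    cfg$use_str <- g$use_str
    cv <- cross_validate(enc, cfg, k = k, seed = seed, ...)
    rows[[g$method]] <- dplyr::bind_cols(g, glance(cv)[
      c("acc", "f1", "precision", "recall", "mcc", "auc", "aupr", "sd_auc")])
  }
  structure(dplyr::bind_rows(rows),
            class = c("nm_ablation", "tbl_df", "tbl", "data.frame"))
}

#' Ablation results plot
#' @param object an `nm_ablation`
#' @param ... unused
#' @export
autoplot.nm_ablation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("method", "auc", "aupr", "acc", "mcc")],
    -"method", names_to = "metric")
  long$method <- factor(long$method, levels = ABLATION_GRID$method)
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
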