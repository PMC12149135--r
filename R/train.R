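# derive a child seed (< 2^31) from the master seed and a string key
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

config_for_cpp <- function(config) {
  lapply(unclass(config), function(v) if (is.logical(v)) v else as.numeric(v))
}

as_encoded <- function(data) {
  if (inherits(data, "nm_encoded")) data else encode_windows(data)
}

# stratified fold assignment: labels (and subtypes, when present) are
# balanced across folds; returns integer fold id per sample
stratified_folds <- function(label, subtype, k, seed) {
  strata <- paste(label, ifelse(is.na(subtype), "", subtype))
  fold <- integer(length(label))
  set.seed(seed)
  cursor <- 0L
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    # continue the fold cycle across strata so overall fold sizes
    # differ by at most one
    fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- cursor + length(idx)
  }
  fold
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    dim(g) <- dim(params[[nm]])  # arma returns vectors as n x 1
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the multi-view Nm classifier
#'
#' Minimises the mean binary cross-entropy with Adam (learning rate
#' 0.0005, default moment decays) on mini-batches of 64. A stratified
#' 10% split of the training data is held out for validation; training
#' stops when the validation loss has not improved by more than
#' `min_delta` for `patience` consecutive epochs (or at `max_epochs`),
#' and the parameters of the best validation epoch are kept. Fully
#' deterministic given `seed` under single-threaded BLAS: parameter
#' initialisation, the validation split, batch order and dropout all
#' flow from seeds derived from it.
#'
#' @param data a windows tibble (with `dotbracket` attached) or an
#'   `nm_encoded` object
#' @param config an [nm_config()]
#' @param seed master seed
#' @param lr,batch_size,max_epochs,patience,min_delta,val_frac optimiser
#'   settings
#' @param verbose print per-epoch losses
#' @return An object of class `nm_fit`: trained parameters, config and a
#'   per-epoch `history` tibble.
#' @export
nm_train <- function(data, config = nm_config(), seed = 1, lr = 5e-4,
                     batch_size = 64, max_epochs = 100, patience = 10,
                     min_delta = 1e-4, val_frac = 0.1, verbose = FALSE) {
  enc <- as_encoded(data)
  n <- length(enc$label)
  if (length(unique(enc$label)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  L <- dim(enc$x_seq)[1]
  cfgc <- config_for_cpp(config)

  # stratified validation split
  n_val_folds <- max(2L, round(1 / val_frac))
  fold <- stratified_folds(enc$label, enc$subtype, n_val_folds,
                           derive_seed(seed, "valsplit"))
  val_idx <- which(fold == 1L)
  tr_idx <- which(fold != 1L)
  enc_val <- subset_encoded(enc, val_idx)
  enc_tr <- subset_encoded(enc, tr_idx)

  set.seed(derive_seed(seed, "init"))
  params <- nm_init_params(config, window_len = L)
  state <- adam_init(params)

  val_loss_of <- function(p) {
    probs <- cpp_predict_probs(enc_val$x_seq, enc_val$x_chem, enc_val$x_str,
                               enc_val$x_node, p, cfgc)
    bce_loss(probs, enc_val$label)
  }
  best_val <- val_loss_of(params)
  init_val <- best_val
  best_params <- params
  wait <- 0L
  history <- list()

  set.seed(derive_seed(seed, "epochs"))
  n_tr <- length(tr_idx)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(n_tr)
    ep_loss <- 0
    n_batches <- ceiling(n_tr / batch_size)
    for (b in seq_len(n_batches)) {
      bi <- ord[((b - 1) * batch_size + 1):min(b * batch_size, n_tr)]
      res <- cpp_batch_grad(
        enc_tr$x_seq[, , bi, drop = FALSE],
        enc_tr$x_chem[, , bi, drop = FALSE],
        enc_tr$x_str[, , bi, drop = FALSE],
        enc_tr$x_node[, , bi, drop = FALSE],
        enc_tr$label[bi], params, cfgc, TRUE)
      ep_loss <- ep_loss + res$loss * length(bi)
      upd <- adam_step(params, res$grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
    vl <- val_loss_of(params)
    history[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / n_tr,
                          val_loss = vl)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / n_tr, vl))
    }
    if (vl < best_val - min_delta) {
      best_val <- vl
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  structure(list(
    params = best_params, config = config, window_len = L,
    history = tibble::as_tibble(do.call(rbind, history)),
    best_val_loss = best_val, initial_val_loss = init_val,
    n_val = length(val_idx), seed = seed
  ), class = "nm_fit")
}

#' @export
print.nm_fit <- function(x, ...) {
  views <- c("seq", "chem", "str")[c(x$config$use_seq, x$config$use_chem,
                                     x$config$use_str)]
  cat("<nm_fit> views: ", paste(views, collapse = "+"),
      "; ", nrow(x$history), " epochs; best val loss ",
      signif(x$best_val_loss, 4), "\n", sep = "")
  invisible(x)
}

# evaluation-mode probabilities for an encoded set
predict_probs <- function(fit, enc) {
  cpp_predict_probs(enc$x_seq, enc$x_chem, enc$x_str, enc$x_node,
                    fit$params, config_for_cpp(fit$config))
}

#' Predict methylation probabilities
#'
#' @param object an `nm_fit`
#' @param newdata windows tibble or `nm_encoded`
#' @param threshold classification threshold (default 0.5)
#' @param ... unused
#' @return Tibble with `prob` and `label_hat` per sample (plus `label`
#'   and `subtype` when present in the input).
#' @export
predict.nm_fit <- function(object, newdata, threshold = 0.5, ...) {
  enc <- as_encoded(newdata)
  probs <- predict_probs(object, enc)
  tibble::tibble(prob = as.numeric(probs),
                 label_hat = as.integer(probs >= threshold),
                 label = enc$label, subtype = enc$subtype)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#' @param x an `nm_fit`
#' @param ... unused
#' @return tibble with `epoch`, `train_loss`, `val_loss`
#' @export
tidy.nm_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x an `nm_fit`
#' @param ... unused
#' @export
glance.nm_fit <- function(x, ...) {
  tibble::tibble(n_epochs = nrow(x$history),
                 best_val_loss = x$best_val_loss,
                 initial_val_loss = x$initial_val_loss,
                 n_val = x$n_val, seed = x$seed)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the named parameter arrays
#' together with the configuration block.
#' @param fit an `nm_fit`
#' @param path file path
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params, config = unclass(fit$config),
               window_len = fit$window_len), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(params = ck$params,
                 config = do.call(nm_config, ck$config),
                 window_len = ck$window_len,
                 history = tibble::tibble(), best_val_loss = NA_real_,
                 initial_val_loss = NA_real_, n_val = NA_integer_,
                 seed = NA_integer_),
            class = "nm_fit")
}
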