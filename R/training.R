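#' Train a terminator CNN with early stopping
#'
#' Minimises binary cross-entropy with Adamax on shuffled minibatches.
#' After each epoch the accuracy on the test set is evaluated; training
#' stops once it has not improved for `patience` epochs and the weights of
#' the best epoch are restored. Training accuracy is accumulated over the
#' minibatches of the epoch.
#'
#' @param model a [build_model()] result (fresh, or carrying pre-trained
#'   weights to fine-tune).
#' @param train,test data frames with columns `sequence` and `label`.
#' @param seed integer seed controlling weight initialisation, shuffling
#'   and dropout; identical seeds give identical runs.
#' @param epochs,patience,batch_size override the config defaults.
#' @param verbose print per-epoch accuracy.
#' @return the trained model; `$history` holds a `training_history` data
#'   frame (epoch, train_acc, test_acc, loss) with attributes `best_epoch`
#'   and `stop_epoch`.
#' @export
train_model <- function(model, train, test, seed = 1L, epochs = NULL,
                        patience = NULL, batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "termscan_model"))
  if (NROW(train) == 0 || NROW(test) == 0)
    stop("train and test sets must be non-empty", call. = FALSE)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  patience <- patience %||% cfg$patience
  batch_size <- batch_size %||% cfg$batch_size
  enc <- if (cfg$topology == "onehot_cnn") "onehot" else "matrix"
  if (any(nchar(train$sequence) != cfg$input_length) ||
      any(nchar(test$sequence) != cfg$input_length))
    stop("sequence lengths do not match the model input length",
         call. = FALSE)

  xtr <- input_matrix(train$sequence, enc)
  xte <- input_matrix(test$sequence, enc)
  ytr <- as.numeric(train$label)
  yte <- as.numeric(test$label)
  n <- length(ytr)
  flat <- arch_flat(model$arch)

  with_seed(seed, {
    params <- copy_params(model$params %||% init_params(model$arch))
    state_m <- lapply(params, function(p) p * 0)
    state_u <- lapply(params, function(p) p * 0)
    t <- 0L
    best_acc <- -Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    hist <- data.frame(epoch = integer(0), train_acc = numeric(0),
                       test_acc = numeric(0), loss = numeric(0))

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      correct <- 0L
      loss_sum <- 0
      for (lo in seq(1L, n, by = batch_size)) {
        hi <- min(lo + batch_size - 1L, n)
        idx <- ord[lo:hi]
        B <- length(idx)
        mask <- matrix((runif(flat * B) >= cfg$dropout) / (1 - cfg$dropout),
                       flat, B)
        res <- nn_fwdbwd_cpp(xtr[, idx, drop = FALSE], ytr[idx],
                             params, model$arch, mask)
        t <- t + 1L
        adamax_update_cpp(params, res$grads[names(params)], state_m,
                          state_u, cfg$learning_rate / (1 - cfg$beta1^t),
                          cfg$beta1, cfg$beta2, cfg$epsilon)
        correct <- correct + sum((res$yhat > 0.5) == ytr[idx])
        loss_sum <- loss_sum + res$loss * B
      }
      train_acc <- correct / n
      test_pred <- predict_params(xte, params, model$arch)
      test_acc <- mean((test_pred > 0.5) == yte)
      hist <- rbind(hist, data.frame(epoch = epoch, train_acc = train_acc,
                                     test_acc = test_acc,
                                     loss = loss_sum / n))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  test %.4f  loss %.4f",
                        epoch, train_acc, test_acc, loss_sum / n))
      if (test_acc >= best_acc - 1e-12) {
        # at equal accuracy keep the later epoch's weights (the loss keeps
        # improving on accuracy plateaus); patience counts epochs without a
        # strict improvement
        wait <- if (test_acc > best_acc + 1e-12) 0L else wait + 1L
        best_acc <- max(best_acc, test_acc)
        best_params <- copy_params(params)
        best_epoch <- epoch
      } else {
        wait <- wait + 1L
      }
      if (wait >= patience) break
    }
    model$params <- best_params
    attr(hist, "best_epoch") <- best_epoch
    attr(hist, "stop_epoch") <- nrow(hist)
    class(hist) <- c("training_history", class(hist))
    model$history <- hist
    model
  })
}

predict_params <- function(x, params, arch, batch_size = 512L) {
  n <- ncol(x)
  out <- numeric(n)
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    out[lo:hi] <- nn_predict_cpp(x[, lo:hi, drop = FALSE], params, arch)
  }
  out
}

#' Pre-train on structure-equivalent data, then fine-tune
#'
#' Trains the model first on an inverse-folding based pre-training set
#' (early-stopped on its held-out partition), then continues training from
#' the learned weights on the main terminator data. With `pretraining =
#' NULL` this reduces to plain [train_model()].
#'
#' @param config a [model_config()].
#' @param pretraining result of [generate_pretraining_set()] (list with
#'   `pretrain` and `earlystop` data frames), or NULL to skip.
#' @param train,test main training and early-stopping sets.
#' @param seed integer seed.
#' @param pretrain_epochs,epochs,patience,batch_size overrides.
#' @return trained `termscan_model`; `$pretrain_history` holds the
#'   pre-training phase history when pre-training was run.
#' @export
pretrain_finetune <- function(config, pretraining, train, test, seed = 1L,
                              pretrain_epochs = NULL, epochs = NULL,
                              patience = NULL, batch_size = NULL) {
  model <- build_model(config)
  pre_hist <- NULL
  if (!is.null(pretraining)) {
    if (any(nchar(pretraining$pretrain$sequence) != config$input_length))
      stop("pre-training sequence length does not match the model input ",
           "length", call. = FALSE)
    model <- train_model(model, pretraining$pretrain, pretraining$earlystop,
                         seed = subseed(seed, 17L),
                         epochs = pretrain_epochs %||% epochs,
                         patience = patience, batch_size = batch_size)
    pre_hist <- model$history
  }
  model <- train_model(model, train, test, seed = seed, epochs = epochs,
                       patience = patience, batch_size = batch_size)
  model$pretrain_history <- pre_hist
  model
}

#' Average precision (area under the precision-recall curve)
#'
#' Stepwise sum over distinct score thresholds in decreasing order:
#' `AP = sum (R_i - R_{i-1}) P_i`.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Point metrics and PR curve for a classifier
#'
#' @param scores model outputs in `[0, 1]` (or a trained model, in which
#'   case `validation` is scored with it).
#' @param validation data frame with `sequence` and `label`; or the label
#'   vector when scores are given directly.
#' @param threshold decision threshold for the point metrics (default 0.5).
#' @return object of class `eval_metrics`: precision, recall, specificity,
#'   f1, auprc, and the PR curve (data frame `recall`, `precision`,
#'   `threshold`).
#' @export
evaluate_model <- function(scores, validation, threshold = 0.5) {
  if (inherits(scores, "termscan_model")) {
    labels <- validation$label
    scores <- predict(scores, validation)
  } else {
    labels <- if (is.data.frame(validation)) validation$label else validation
  }
  if (length(unique(labels)) < 2)
    stop("validation set must contain both classes", call. = FALSE)

  pred <- scores > threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp_c <- cumsum(y == 1)[keep]
  fp_c <- cumsum(y == 0)[keep]
  curve <- data.frame(recall = tp_c / sum(labels == 1),
                      precision = tp_c / (tp_c + fp_c),
                      threshold = s[keep])

  structure(list(precision = precision, recall = recall,
                 specificity = specificity, f1 = f1,
                 auprc = average_precision(scores, labels),
                 pr_curve = curve, n = length(labels)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0("precision %.3f  recall %.3f  specificity %.3f  ",
                     "F1 %.3f  AUPRC %.3f  (n = %d)\n"),
              x$precision, x$recall, x$specificity, x$f1, x$auprc, x$n))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison of two score samples
#'
#' Exact permutation distribution of the rank-sum statistic (tie-aware) for
#' combined sample sizes up to `exact_max`; tie-corrected normal
#' approximation without continuity correction otherwise.
#'
#' @param scores_a,scores_b numeric vectors (e.g. per-replicate AUPRC of two
#'   model variants).
#' @param exact_max largest combined n for the exact path (default 12).
#' @return list with `p_value`, `statistic` (rank sum of the first sample)
#'   and `method`.
#' @export
compare_models <- function(scores_a, scores_b, exact_max = 12L) {
  if (length(scores_a) == 0 || length(scores_b) == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  m <- length(scores_a)
  n <- length(scores_b)
  pooled <- c(scores_a, scores_b)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])

  if (m + n <= exact_max) {
    combs <- utils::combn(m + n, m)
    stats <- colSums(matrix(r[combs], nrow = m))
    mu <- m * (m + n + 1) / 2
    p_low <- mean(stats <= W + 1e-9)
    p_high <- mean(stats >= W - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact permutation"
  } else {
    N <- m + n
    mu <- m * (N + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(p_value = 1, statistic = W,
                                 method = "normal approximation"))
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = W, method = method)
}
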