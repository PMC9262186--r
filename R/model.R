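#' Configuration of a terminator CNN
#'
#' Both topologies share one head: a convolution with 30 filters (kernel
#' size 10, ReLU), max pooling (pool size 5), dropout 0.2, then dense layers
#' of 360 (ReLU) and 30 (sigmoid) units and a single sigmoid output. The
#' one-hot CNN convolves along the sequence over 4 input channels; the
#' matrix CNN applies a 10 x 10 convolution and 5 x 5 pooling to the L x L
#' pairing matrix, all other parameters unchanged.
#'
#' @param topology `"onehot_cnn"` or `"matrix_cnn"`.
#' @param input_length input sequence length L in nt (default 75).
#' @param filters,kernel_size,pool_size convolution/pooling geometry.
#' @param dropout dropout rate applied to the pooled features.
#' @param dense1,dense2 dense layer widths.
#' @param batch_size minibatch size for training (default 32).
#' @param learning_rate,beta1,beta2,epsilon Adamax hyper-parameters
#'   (defaults 0.002, 0.9, 0.999, 1e-7).
#' @param epochs epoch cap.
#' @param patience early-stopping patience in epochs (default 5); training
#'   stops when test accuracy has not improved for this many epochs and the
#'   best-epoch weights are restored.
#' @return object of class `model_config`.
#' @export
model_config <- function(topology = c("onehot_cnn", "matrix_cnn"),
                         input_length = 75L, filters = 30L,
                         kernel_size = 10L, pool_size = 5L, dropout = 0.2,
                         dense1 = 360L, dense2 = 30L, batch_size = 32L,
                         learning_rate = 0.002, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, epochs = 100L, patience = 5L) {
  topology <- match.arg(topology)
  if (input_length < kernel_size)
    stop("input_length must be at least kernel_size", call. = FALSE)
  if (any(c(filters, kernel_size, pool_size, dense1, dense2) < 1))
    stop("all layer sizes must be positive", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  structure(list(topology = topology, input_length = as.integer(input_length),
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size), dropout = dropout,
                 dense1 = as.integer(dense1), dense2 = as.integer(dense2),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 patience = as.integer(patience)),
            class = "model_config")
}

# geometry handed to the C++ kernels; the one-hot topology is the 2-D
# special case whose kernel spans the full 4-channel width
config_arch <- function(config) {
  L <- config$input_length
  if (config$topology == "onehot_cnn") {
    list(H = L, W = 4L, kh = config$kernel_size, kw = 4L,
         F = config$filters, ph = config$pool_size, pw = 1L,
         d1 = config$dense1, d2 = config$dense2)
  } else {
    list(H = L, W = L, kh = config$kernel_size, kw = config$kernel_size,
         F = config$filters, ph = config$pool_size, pw = config$pool_size,
         d1 = config$dense1, d2 = config$dense2)
  }
}

arch_flat <- function(arch) {
  oh <- (arch$H - arch$kh + 1L) %/% arch$ph
  ow <- (arch$W - arch$kw + 1L) %/% arch$pw
  oh * ow * arch$F
}

#' Build an untrained model
#'
#' @param config a [model_config()].
#' @return object of class `termscan_model`; weights are initialised lazily
#'   by [train_model()] under its seed so identical seeds give identical
#'   training runs.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, arch = config_arch(config),
                 params = NULL, history = NULL),
            class = "termscan_model")
}

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(arch) {
  flat <- arch_flat(arch)
  taps <- arch$kh * arch$kw
  list(# convolution fans count every kernel tap per output filter
       Wc = glorot(taps, arch$F, fan_in = taps, fan_out = taps * arch$F),
       bc = numeric(arch$F),
       W1 = glorot(flat, arch$d1),
       b1 = numeric(arch$d1),
       W2 = glorot(arch$d1, arch$d2),
       b2 = numeric(arch$d2),
       W3 = glorot(arch$d2, 1L)[, 1],
       b3 = 0)
}

#' Number of trainable parameters
#'
#' @param model a `termscan_model`.
#' @param by_layer if TRUE, return the per-layer breakdown.
#' @return integer count (or named vector).
#' @export
count_params <- function(model, by_layer = FALSE) {
  a <- model$arch
  flat <- arch_flat(a)
  n <- c(conv = a$F * (a$kh * a$kw + 1L),
         dense1 = (flat + 1L) * a$d1,
         dense2 = (a$d1 + 1L) * a$d2,
         output = a$d2 + 1L)
  if (by_layer) n else sum(n)
}

#' @export
print.termscan_model <- function(x, ...) {
  cat("termscan CNN (", x$config$topology, "), L = ",
      x$config$input_length, ", ", count_params(x), " parameters, ",
      if (is.null(x$params)) "untrained" else "trained", "\n", sep = "")
  invisible(x)
}

#' Score sequences with a trained model
#'
#' @param object trained `termscan_model`.
#' @param seqs character vector of sequences of the model's input length
#'   (or a data frame with a `sequence` column).
#' @param batch_size scoring batch size.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.termscan_model <- function(object, seqs, batch_size = 256L, ...) {
  if (is.null(object$params))
    stop("model has no trained weights", call. = FALSE)
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (any(nchar(seqs) != object$config$input_length))
    stop("sequence length does not match the model input length ",
         object$config$input_length, call. = FALSE)
  enc <- if (object$config$topology == "onehot_cnn") "onehot" else "matrix"
  out <- numeric(length(seqs))
  for (lo in seq(1L, length(seqs), by = batch_size)) {
    hi <- min(lo + batch_size - 1L, length(seqs))
    x <- input_matrix(seqs[lo:hi], enc)
    out[lo:hi] <- nn_predict_cpp(x, object$params, object$arch)
  }
  out
}

# deep copy of a parameter list (the optimiser updates in place)
copy_params <- function(params) lapply(params, function(p) p + 0)
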