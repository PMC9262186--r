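test_that("layer parameter counts match the closed-form formulas", {
  m_oh <- build_model(model_config("onehot_cnn", input_length = 75))
  m_mx <- build_model(model_config("matrix_cnn", input_length = 75))
  # valid convolution: filters * (kernel taps + 1)
  expect_equal(count_params(m_oh, by_layer = TRUE)[["conv"]],
               30 * (10 * 4 + 1))
  expect_equal(count_params(m_mx, by_layer = TRUE)[["conv"]],
               30 * (10 * 10 + 1))
  # one-hot: (75-10+1) pooled by 5 -> 13 positions x 30 filters
  expect_equal(count_params(m_oh, by_layer = TRUE)[["dense1"]],
               (13 * 30 + 1) * 360)
  expect_equal(count_params(m_mx, by_layer = TRUE)[["dense1"]],
               (13 * 13 * 30 + 1) * 360)
  expect_error(model_config("onehot_cnn", input_length = 8), "kernel_size")
})

test_that("analytic gradients match a double-precision reference network", {
  for (topo in c("matrix_cnn", "onehot_cnn")) {
    cfg <- model_config(topo, input_length = 14, filters = 3,
                        kernel_size = 4, pool_size = 2, dense1 = 7,
                        dense2 = 4)
    m <- build_model(cfg)
    set.seed(5)
    params <- termscan:::init_params(m$arch)
    seqs <- replicate(6, random_rna_seq(14))
    enc <- if (topo == "onehot_cnn") "onehot" else "matrix"
    x <- termscan:::input_matrix(seqs, enc)
    y <- c(1, 0, 1, 0, 1, 0)
    flat <- termscan:::arch_flat(m$arch)
    mask <- matrix((runif(flat * 6) >= 0.2) / 0.8, flat, 6)
    res <- termscan:::nn_fwdbwd_cpp(x, y, params, m$arch, mask)
    ref <- ref_nn_fwdbwd(x, y, params, m$arch, mask)
    expect_equal(res$loss, ref$loss, tolerance = 1e-5)
    expect_equal(res$yhat, ref$yhat, tolerance = 1e-5)
    for (nm in names(ref$grads))
      expect_equal(as.numeric(res$grads[[nm]]),
                   as.numeric(ref$grads[[nm]]),
                   tolerance = 1e-4, info = paste(topo, nm))
  }
})

test_that("model outputs stay in [0, 1]", {
  cfg <- model_config("onehot_cnn", input_length = 20, epochs = 2)
  df <- data.frame(sequence = replicate(40, random_rna_seq(20)),
                   label = rep(c(0, 1), 20))
  mod <- train_model(build_model(cfg), df[1:30, ], df[31:40, ], seed = 1)
  p <- predict(mod, df)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training is reproducible under a fixed seed", {
  set.seed(77)
  df <- data.frame(sequence = replicate(60, random_rna_seq(20)),
                   label = rep(c(0, 1), 30))
  cfg <- model_config("matrix_cnn", input_length = 20, epochs = 3)
  a <- train_model(build_model(cfg), df[1:40, ], df[41:60, ], seed = 9)
  b <- train_model(build_model(cfg), df[1:40, ], df[41:60, ], seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("a separable toy task is learned to perfect accuracy", {
  set.seed(7)
  pos <- replicate(60, {
    s <- paste(sample(c("G", "C"), 10, TRUE), collapse = "")
    paste0(s, "AAAAA", reverse_complement(s))
  })
  neg <- replicate(60, random_rna_seq(25))
  df <- data.frame(sequence = c(pos, neg), label = rep(c(1, 0), each = 60))
  sp <- monte_carlo_split(nrow(df), n_replicates = 1, seed = 3)[[1]]
  cfg <- model_config("matrix_cnn", input_length = 25, epochs = 30,
                      patience = 5)
  mod <- train_model(build_model(cfg), df[sp$train, ], df[sp$test, ],
                     seed = 1)
  ev <- evaluate_model(mod, df[sp$validation, ])
  expect_equal(ev$recall, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auprc, 1)
})

test_that("label-shuffled data scores at chance AUPRC", {
  set.seed(13)
  df <- data.frame(sequence = replicate(120, random_rna_seq(20)),
                   label = rep(c(1, 0, 0, 0), 30))  # prevalence 0.25
  cfg <- model_config("onehot_cnn", input_length = 20, epochs = 5,
                      patience = 3)
  mod <- train_model(build_model(cfg), df[1:80, ], df[81:100, ], seed = 2)
  ev <- evaluate_model(mod, df[101:120, ])
  # AUPRC of an uninformative scorer concentrates near the prevalence
  expect_lt(abs(ev$auprc - 0.25), 0.3)
})

test_that("early stopping restores the best-epoch weights", {
  set.seed(31)
  df <- data.frame(sequence = replicate(60, random_rna_seq(15)),
                   label = rep(c(1, 0), 30))
  cfg <- model_config("onehot_cnn", input_length = 15, epochs = 40,
                      patience = 3)
  mod <- train_model(build_model(cfg), df[1:40, ], df[41:60, ], seed = 4)
  h <- mod$history
  best <- attr(h, "best_epoch")
  stopped <- attr(h, "stop_epoch")
  expect_lte(best, stopped)
  expect_lte(stopped - best, 3)
  # restored weights reproduce the best test accuracy
  xte <- termscan:::input_matrix(df$sequence[41:60], "onehot")
  acc <- mean((termscan:::nn_predict_cpp(xte, mod$params, mod$arch) > 0.5) ==
                df$label[41:60])
  expect_equal(acc, max(h$test_acc))
})

test_that("evaluation metrics follow their definitions", {
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3, 0.05, 0.15)
  ev <- evaluate_model(perfect, labels)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$auprc, 1)

  # constant scorer: AUPRC equals prevalence (average-precision closed form)
  ev2 <- evaluate_model(rep(0.7, 8), labels)
  expect_equal(ev2$auprc, 3 / 8)

  # all-negative predictions
  ev3 <- evaluate_model(rep(0.1, 8), labels)
  expect_equal(ev3$recall, 0)
  expect_equal(ev3$specificity, 1)

  expect_error(evaluate_model(perfect, rep(1, 8)), "both classes")

  # F1 identity on a mixed prediction
  scores <- c(0.9, 0.4, 0.8, 0.6, 0.2, 0.1, 0.7, 0.3)
  ev4 <- evaluate_model(scores, labels)
  expect_equal(ev4$f1,
               2 * ev4$precision * ev4$recall / (ev4$precision + ev4$recall))
})

test_that("rank-sum comparison matches exact enumeration and closed forms", {
  expect_equal(compare_models(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(compare_models(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  # invariance under a common monotone transform
  a <- c(0.3, 0.5, 0.9, 0.2)
  b <- c(0.4, 0.6, 0.7)
  expect_equal(compare_models(a, b)$p_value,
               compare_models(exp(a), exp(b))$p_value)

  set.seed(17)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    a <- round(runif(m), 2)
    b <- round(runif(n), 2)
    expect_equal(compare_models(a, b)$p_value, oracle_ranksum_p(a, b),
                 info = paste(c(a, "|", b), collapse = " "))
  }

  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(18)
  a <- rnorm(30)
  b <- rnorm(35, 0.5)
  ours <- compare_models(a, b)$p_value
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(compare_models(numeric(0), b), "non-empty")
})

test_that("skipping pre-training reduces to plain training", {
  set.seed(41)
  df <- data.frame(sequence = replicate(60, random_rna_seq(15)),
                   label = rep(c(1, 0), 30))
  cfg <- model_config("onehot_cnn", input_length = 15, epochs = 3)
  plain <- train_model(build_model(cfg), df[1:40, ], df[41:60, ], seed = 8)
  viafit <- pretrain_finetune(cfg, NULL, df[1:40, ], df[41:60, ], seed = 8)
  expect_identical(plain$params, viafit$params)
  expect_null(viafit$pretrain_history)
})

test_that("pre-training learns the structure task before fine-tuning", {
  structures <- vapply(1:5, function(k)
    make_terminator(generator_params(a_tail = c(4, 6), stem = c(4, 6),
                                     loop = c(3, 4), u_tail = c(4, 6),
                                     target_length = 40),
                    seed = 500 + k, check_fold = FALSE)$structure,
    character(1))
  pre <- generate_pretraining_set(structures, n_positive = 60, seed = 3,
                                  max_iter = 4000)
  cfg <- model_config("matrix_cnn", input_length = 40, epochs = 15,
                      patience = 4)
  model <- build_model(cfg)
  model <- train_model(model, pre$pretrain, pre$earlystop,
                       seed = 17)
  # held-out structure-only positives are separated from random negatives
  held <- pre$earlystop
  acc <- mean((predict(model, held) > 0.5) == held$label)
  expect_gt(acc, 0.9)
})
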