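# Independent reference implementations used as test oracles. These are
# deliberately written with different algorithms from the package code
# (explicit enumeration, brute-force grouping, double-precision linear
# algebra) so agreement is informative.

oracle_pair_weight <- function(a, b) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, "CG" = 3L, "AU" = 2L, "GU" = 1L, 0L)
}

# all nested structures of a sequence via explicit recursive enumeration;
# returns a list of pair matrices (1-based)
oracle_enumerate_structures <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)  # i unpaired
    ks <- if (i + min_loop + 1L > j) integer(0) else
      seq.int(i + min_loop + 1L, j)
    for (k in ks) {
      if (oracle_pair_weight(chars[i], chars[k]) == 0) next
      for (inner in rec(i + 1L, k - 1L)) {
        for (outer in rec(k + 1L, j)) {
          out <- c(out, list(rbind(c(i, k), inner, outer)))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

oracle_structure_weight <- function(pairs, seq) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0L)
  chars <- strsplit(seq, "")[[1]]
  sum(vapply(seq_len(nrow(pairs)), function(r)
    oracle_pair_weight(chars[pairs[r, 1]], chars[pairs[r, 2]]), integer(1)))
}

oracle_max_weight <- function(seq, min_loop = 3L) {
  structs <- oracle_enumerate_structures(seq, min_loop)
  max(vapply(structs, oracle_structure_weight, integer(1), seq = seq))
}

# brute-force reference for window fusion: label windows above threshold,
# group by scanning, no vectorised tricks
oracle_call_hits <- function(starts, scores, window, step, threshold = 0.5) {
  hits <- list()
  cur <- NULL
  for (i in seq_along(starts)) {
    if (scores[i] > threshold) {
      if (!is.null(cur) && starts[i] - cur$last == step) {
        cur$last <- starts[i]
        cur$score <- max(cur$score, scores[i])
      } else {
        if (!is.null(cur)) hits[[length(hits) + 1L]] <- cur
        cur <- list(first = starts[i], last = starts[i], score = scores[i])
      }
    }
  }
  if (!is.null(cur)) hits[[length(hits) + 1L]] <- cur
  do.call(rbind, lapply(hits, function(h) {
    s <- h$first
    e <- h$last + window
    data.frame(start = s, end = e, center = (s + e - 1L) %/% 2L,
               score = h$score)
  }))
}

# exact two-sided rank-sum p-value by explicit enumeration over all
# assignments of pooled observations to the first group
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  combs <- combn(length(pooled), m)
  stats <- apply(combs, 2, function(ii) sum(r[ii]))
  W <- sum(r[seq_len(m)])
  p_low <- mean(stats <= W + 1e-9)
  p_high <- mean(stats >= W - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# double-precision reference for the CNN forward/backward pass
ref_nn_fwdbwd <- function(x, y, params, arch, mask) {
  H <- arch$H; W <- arch$W; kh <- arch$kh; kw <- arch$kw; F <- arch$F
  ph <- arch$ph; pw <- arch$pw
  oh <- H - kh + 1; ow <- W - kw + 1
  poh <- oh %/% ph; pow <- ow %/% pw
  B <- ncol(x)
  flat <- poh * pow * F
  sig <- function(z) 1 / (1 + exp(-z))
  im2col <- function(xb) {
    img <- matrix(xb, H, W)
    col <- matrix(0, oh * ow, kh * kw)
    for (dj in 1:kw) for (di in 1:kh)
      col[, (dj - 1) * kh + di] <-
        as.vector(img[di:(di + oh - 1), dj:(dj + ow - 1)])
    col
  }
  cols <- lapply(1:B, function(b) im2col(x[, b]))
  Z1 <- lapply(cols, function(cb) sweep(cb %*% params$Wc, 2, params$bc, "+"))
  A1 <- lapply(Z1, function(z) pmax(z, 0))
  D <- matrix(0, flat, B); amax <- matrix(0L, flat, B)
  for (b in 1:B) for (f in 1:F) for (pj in 1:pow) for (pi in 1:poh) {
    rows <- integer(0)
    for (dj in 1:pw) for (di in 1:ph)
      rows <- c(rows, ((pj - 1) * pw + dj - 1) * oh + (pi - 1) * ph + di)
    vals <- A1[[b]][rows, f]
    fi <- (f - 1) * poh * pow + (pj - 1) * poh + pi
    D[fi, b] <- max(vals)
    amax[fi, b] <- rows[which.max(vals)]
  }
  Dm <- D * mask
  H1 <- pmax(sweep(t(params$W1) %*% Dm, 1, params$b1, "+"), 0)
  H2 <- sig(sweep(t(params$W2) %*% H1, 1, params$b2, "+"))
  yhat <- as.numeric(sig(t(params$W3) %*% H2 + params$b3))
  eps <- 1e-7
  q <- pmin(pmax(yhat, eps), 1 - eps)
  loss <- -mean(y * log(q) + (1 - y) * log(1 - q))

  dZ3 <- matrix((yhat - y) / B, 1, B)
  dW3 <- as.numeric(H2 %*% t(dZ3))
  db3 <- sum(dZ3)
  dH2 <- params$W3 %*% dZ3
  dZ2 <- dH2 * H2 * (1 - H2)
  dW2 <- H1 %*% t(dZ2); db2 <- rowSums(dZ2)
  dH1 <- params$W2 %*% dZ2
  dZ1 <- dH1 * (H1 > 0)
  dW1 <- Dm %*% t(dZ1); db1 <- rowSums(dZ1)
  dD <- (params$W1 %*% dZ1) * mask
  dWc <- matrix(0, kh * kw, F); dbc <- numeric(F)
  for (b in 1:B) {
    dA1 <- matrix(0, oh * ow, F)
    for (fi in 1:flat) {
      f <- (fi - 1) %/% (poh * pow) + 1
      r <- amax[fi, b]
      if (A1[[b]][r, f] > 0) dA1[r, f] <- dA1[r, f] + dD[fi, b]
    }
    dWc <- dWc + t(cols[[b]]) %*% dA1
    dbc <- dbc + colSums(dA1)
  }
  list(loss = loss, yhat = yhat,
       grads = list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2, W3 = dW3, b3 = db3))
}

random_rna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_hairpin_target <- function(max_stem = 10L) {
  stem <- sample(3:max_stem, 1)
  loop <- sample(3:8, 1)
  paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
}
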