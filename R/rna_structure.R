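#' Parse dot-bracket notation into a pair set
#'
#' Converts a dot-bracket string over `(`, `)`, `.` into the set of nested
#' base pairs it encodes. Indices are 0-based, consistent with all coordinate
#' handling in the package.
#'
#' @param db dot-bracket string.
#' @return integer matrix with columns `i`, `j` (0-based, `i < j`), one row
#'   per pair, ordered by `i`, with attribute `L` giving the sequence length.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0)
    stop("dot-bracket string contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  stack <- integer(0)
  res_i <- integer(0); res_j <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k - 1L)
    } else if (chars[k] == ")") {
      if (length(stack) == 0)
        stop("unbalanced dot-bracket string: unmatched ')' at position ",
             k - 1L, call. = FALSE)
      res_i <- c(res_i, stack[length(stack)])
      res_j <- c(res_j, k - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop("unbalanced dot-bracket string: ", length(stack),
         " unmatched '('", call. = FALSE)
  ps <- cbind(i = res_i, j = res_j)
  ps <- ps[order(ps[, 1]), , drop = FALSE]
  pair_set(ps, length(chars))
}

pair_set <- function(mat, L) {
  mat <- matrix(as.integer(mat), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  attr(mat, "L") <- as.integer(L)
  mat
}

#' Render a pair set as a dot-bracket string
#'
#' @param ps pair set as returned by [parse_dotbracket()] or [fold_nussinov()].
#' @param L sequence length; defaults to the pair set's `L` attribute.
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(ps, L = attr(ps, "L")) {
  out <- rep(".", L)
  if (nrow(ps) > 0) {
    out[ps[, 1] + 1L] <- "("
    out[ps[, 2] + 1L] <- ")"
  }
  paste(out, collapse = "")
}

#' Fold a sequence by weighted maximum pairing
#'
#' A Nussinov-style dynamic programme maximising total pair weight (G-C 3,
#' A-U 2, G-U 1) over all nested structures with a minimum hairpin loop.
#' The traceback is deterministic: at equal score, pairing the 5' base with
#' its leftmost optimal partner is preferred over leaving it unpaired.
#'
#' @param seq RNA string over A, C, G, U.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3, the standard steric constraint).
#' @return pair set (0-based index matrix with attribute `L`).
#' @examples
#' fold_nussinov("GGGAAACCC")
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  assert_rna(seq)
  codes <- seq_codes(seq)
  ps <- nussinov_fold_cpp(codes, as.integer(min_loop))
  ps <- ps[order(ps[, 1]), , drop = FALSE]
  pair_set(ps, length(codes))
}

# total pair weight of a pair set on a sequence (internal scoring helper)
pairset_weight <- function(ps, seq) {
  if (nrow(ps) == 0) return(0L)
  w <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  w["G", "C"] <- w["C", "G"] <- 3L
  w["A", "U"] <- w["U", "A"] <- 2L
  w["G", "U"] <- w["U", "G"] <- 1L
  chars <- strsplit(seq, "")[[1]]
  sum(w[cbind(chars[ps[, 1] + 1L], chars[ps[, 2] + 1L])])
}

#' Base-pair distance between two structures
#'
#' Number of base pairs present in exactly one of the two structures
#' (the symmetric difference).
#'
#' @param a,b pair sets over sequences of the same length.
#' @return non-negative integer count.
#' @export
basepair_distance <- function(a, b) {
  La <- attr(a, "L"); Lb <- attr(b, "L")
  if (!is.null(La) && !is.null(Lb) && La != Lb)
    stop("pair sets refer to sequences of different lengths", call. = FALSE)
  ka <- if (nrow(a)) paste(a[, 1], a[, 2]) else character(0)
  kb <- if (nrow(b)) paste(b[, 1], b[, 2]) else character(0)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# seeded sequence compatible with a target pair set; paired positions get a
# complementary pair (GC-biased so strong stems out-compete spurious pairs)
init_compatible_sequence <- function(ps, L,
                                     pair_prob = c(0.3, 0.3, 0.15, 0.15,
                                                   0.05, 0.05),
                                     unpaired_base = NULL) {
  chars <- character(L)
  unpaired <- setdiff(seq_len(L) - 1L, c(ps[, 1], ps[, 2]))
  if (length(unpaired) > 0)
    chars[unpaired + 1L] <- if (is.null(unpaired_base))
      sample(RNA_BASES, length(unpaired), replace = TRUE)
    else unpaired_base
  if (nrow(ps) > 0) {
    types <- sample(PAIRING_DINUCS, nrow(ps), replace = TRUE, prob = pair_prob)
    chars[ps[, 1] + 1L] <- substr(types, 1, 1)
    chars[ps[, 2] + 1L] <- substr(types, 2, 2)
  }
  paste(chars, collapse = "")
}

#' Inverse folding: find a sequence folding into a target structure
#'
#' Searches sequence space for a sequence whose predicted structure matches
#' the dot-bracket target. The internal backend runs an adaptive stochastic
#' local search against the package's maximum-pairing folder: starting from a
#' pairing-compatible random sequence, it proposes single-base mutations at
#' unpaired positions and compensatory dinucleotide changes at paired
#' positions, accepting any move that does not increase the base-pair
#' distance between the refolded candidate and the target. The external
#' backend shells out to `RNAinverse` (ViennaRNA), which optimises under the
#' thermodynamic nearest-neighbour model instead.
#'
#' @param target dot-bracket string.
#' @param seed integer seed for the internal search (also used to draw the
#'   start sequence handed to the external backend).
#' @param max_iter iteration cap for the internal search (default 20000).
#' @param backend `"internal"` (default) or `"external"`.
#' @param min_loop minimum hairpin loop passed to the internal folder.
#' @return an object of class `inverse_fold_result`: list with `sequence`,
#'   `target`, `achieved_distance`, `iterations`, `backend`. A search that
#'   does not reach distance 0 returns its best sequence with the distance
#'   reported honestly rather than raising an error.
#' @export
inverse_fold <- function(target, seed = 1L, max_iter = 20000L,
                         backend = c("internal", "external"),
                         min_loop = 3L) {
  backend <- match.arg(backend)
  ps <- parse_dotbracket(target)
  L <- attr(ps, "L")
  if (backend == "external") return(inverse_fold_external(target, ps, seed))

  with_seed(seed, {
    res <- inverse_fold_search_cpp(ps, L, as.integer(min_loop),
                                   as.integer(max_iter), 1500L)
    structure(list(sequence = codes_to_seq(res$codes), target = target,
                   achieved_distance = res$distance,
                   iterations = res$iterations,
                   backend = "internal"),
              class = "inverse_fold_result")
  })
}

inverse_fold_external <- function(target, ps, seed) {
  exe <- Sys.which("RNAinverse")
  if (!nzchar(exe))
    stop("external inverse-folding backend requested but 'RNAinverse' was ",
         "not found on PATH", call. = FALSE)
  start <- with_seed(seed, init_compatible_sequence(ps, attr(ps, "L")))
  out <- system2(exe, stdout = TRUE,
                 input = paste(target, start, sep = "\n"))
  line <- out[nzchar(trimws(out))][1]
  if (is.na(line))
    stop("RNAinverse produced no output for target ", target, call. = FALSE)
  fields <- strsplit(trimws(line), "\\s+")[[1]]
  seq <- chartr("T", "U", toupper(fields[1]))
  dist <- if (length(fields) > 1) {
    suppressWarnings(as.integer(gsub("[^0-9]", "", fields[2])))
  } else 0L
  if (is.na(dist)) dist <- 0L
  structure(list(sequence = seq, target = target,
                 achieved_distance = dist, iterations = NA_integer_,
                 backend = "external"),
            class = "inverse_fold_result")
}

#' @export
print.inverse_fold_result <- function(x, ...) {
  cat("inverse fold (", x$backend, "): distance ", x$achieved_distance,
      if (!is.na(x$iterations)) paste0(" after ", x$iterations, " iterations"),
      "\n  ", x$sequence, "\n  ", x$target, "\n", sep = "")
  invisible(x)
}

#' Build an inverse-folding pre-training dataset
#'
#' Draws `n_positive` structure-equivalent sequences by inverse folding,
#' cycling round-robin over the supplied target structures, and pairs them
#' with an equal number of uniform-random negative sequences with matched
#' lengths. The result is partitioned into a pre-training part and a held-out
#' part used to determine the early-stopping point of pre-training
#' (85% / 15% by default).
#'
#' @param structures character vector of dot-bracket targets.
#' @param n_positive number of positive (inverse-folded) sequences.
#' @param seed integer seed.
#' @param split named fractions for the two partitions
#'   (default `c(pretrain = 0.85, earlystop = 0.15)`).
#' @param backend,max_iter,min_loop passed to [inverse_fold()].
#' @return list with data frames `pretrain` and `earlystop` (columns `id`,
#'   `sequence`, `label`, `target`, `achieved_distance`) and the full
#'   `records` table.
#' @export
generate_pretraining_set <- function(structures, n_positive, seed = 1L,
                                     split = c(pretrain = 0.85,
                                               earlystop = 0.15),
                                     backend = "internal",
                                     max_iter = 20000L, min_loop = 3L) {
  if (!is_count(n_positive, 1L))
    stop("n_positive must be a positive count", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  targets <- vapply(structures, function(s) {
    parse_dotbracket(s)  # errors on malformed input
    s
  }, character(1))
  nS <- length(targets)

  pos <- lapply(seq_len(n_positive), function(i) {
    tgt <- targets[[((i - 1L) %% nS) + 1L]]
    res <- inverse_fold(tgt, seed = subseed(seed, i), max_iter = max_iter,
                        backend = backend, min_loop = min_loop)
    data.frame(id = sprintf("invfold_%04d", i), sequence = res$sequence,
               label = 1L, target = tgt,
               achieved_distance = res$achieved_distance,
               stringsAsFactors = FALSE)
  })
  pos <- do.call(rbind, pos)

  neg <- with_seed(subseed(seed, 0L), {
    data.frame(id = sprintf("random_%04d", seq_len(n_positive)),
               sequence = vapply(nchar(pos$sequence), random_rna,
                                 character(1)),
               label = 0L, target = NA_character_,
               achieved_distance = NA_integer_, stringsAsFactors = FALSE)
  })

  records <- rbind(pos, neg)
  n_pre <- round(split[[1]] * n_positive)
  idx <- with_seed(subseed(seed, -1L), list(
    pos = sample.int(n_positive), neg = sample.int(n_positive)))
  pre <- rbind(pos[idx$pos[seq_len(n_pre)], ],
               neg[idx$neg[seq_len(n_pre)], ])
  early <- rbind(pos[idx$pos[-seq_len(n_pre)], ],
                 neg[idx$neg[-seq_len(n_pre)], ])
  rownames(pre) <- rownames(early) <- NULL
  list(pretrain = pre, earlystop = early, records = records)
}

#' Per-class GC content of a labelled dataset
#'
#' @param dataset data frame with columns `sequence` and `label`.
#' @return list with `summary` (per-label n and mean GC fraction) and
#'   `per_sequence` (label and GC fraction per record).
#' @export
gc_content <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0)
    stop("dataset must be a non-empty data frame", call. = FALSE)
  gc <- vapply(dataset$sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  label <- if ("label" %in% names(dataset)) dataset$label else 1L
  per_seq <- data.frame(label = label, gc = gc)
  summ <- do.call(rbind, lapply(split(per_seq, per_seq$label), function(d) {
    data.frame(label = d$label[1], n = nrow(d), mean_gc = mean(d$gc))
  }))
  rownames(summ) <- NULL
  list(summary = summ, per_sequence = per_seq)
}
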