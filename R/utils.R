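#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the Mersenne-Twister stream seeded to `seed`, then
#' restores the caller's RNG state, so seeded operations never perturb
#' surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-stream seeds, kept inside 32-bit integer range
subseed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_rna <- function(seq, allow_n = FALSE, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  ok <- chars %in% if (allow_n) c(RNA_BASES, "N") else RNA_BASES
  if (!all(ok)) {
    stop(sprintf("%s contains characters outside the RNA alphabet: %s",
                 what, paste(unique(chars[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seq)
}

seq_codes <- function(seq) {
  # A=0 C=1 G=2 U=3, NA for anything else
  match(strsplit(seq, "")[[1]], RNA_BASES) - 1L
}

codes_to_seq <- function(codes) paste(RNA_BASES[codes + 1L], collapse = "")

random_rna <- function(n, bases = RNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

#' Reverse complement of an RNA sequence
#'
#' @param seq character string over A, C, G, U (and N).
#' @return the reverse complement string.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGUN", "UGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}
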