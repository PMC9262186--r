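#' Read sequences from a FASTA file
#'
#' Thymine is transliterated to uracil on read, so genomic DNA and RNA
#' inputs share one alphabet downstream.
#'
#' @param path FASTA file.
#' @return data frame with columns `id` (full header) and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("failed to parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  data.frame(id = names(set),
             sequence = chartr("Tt", "Uu", toupper(as.character(set))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read/write BED-like interval tables
#'
#' Six tab-separated columns (chrom, start, end, name, score, strand), no
#' header. Coordinates are 0-based, half-open throughout the package.
#'
#' @param path file path.
#' @return data frame with the six columns.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED-like table needs at least 3 columns",
                         call. = FALSE)
  names(df)[1:min(6, ncol(df))] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(6, ncol(df))]
  df
}

#' @rdname read_bed
#' @param df data frame with columns chrom, start, end, name, score, strand
#'   (0-based half-open coordinates).
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  missing <- setdiff(cols, names(df))
  for (m in missing) df[[m]] <- if (m == "strand") "+" else if (m == "name")
    "." else 0L
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pad a genomic record to a target length with true flanking context
#'
#' Adds the flanking genome bases so the padded record has `target_length`
#' nucleotides, split symmetrically with the extra base on the 3' side.
#' Minus-strand records are padded in genome space and returned as the
#' reverse complement (sense strand of the element). Records longer than the
#' target are discarded (returns `NULL`), mirroring the curation rule that
#' over-long terminators are dropped rather than truncated.
#'
#' @param record list or one-row data frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open genome coordinates).
#' @param genome named character vector of contig sequences.
#' @param target_length padded length (default 75).
#' @return the record with updated `start`, `end` and a `sequence` field, or
#'   `NULL` (discard signal) if the record exceeds `target_length`.
#' @export
pad_with_context <- function(record, genome, target_length = 75L) {
  record <- as.list(record)
  len <- record$end - record$start
  if (len > target_length) return(NULL)
  contig <- genome[[record$chrom]]
  if (is.null(contig))
    stop("contig '", record$chrom, "' not found in genome", call. = FALSE)
  add <- target_length - len
  n5 <- add %/% 2L
  n3 <- add - n5
  if (identical(record$strand, "-")) {
    new_start <- record$start - n3
    new_end <- record$end + n5
  } else {
    new_start <- record$start - n5
    new_end <- record$end + n3
  }
  if (new_start < 0 || new_end > nchar(contig))
    stop("padding for record '", record$name %||% record$chrom,
         "' runs off the contig end", call. = FALSE)
  seq <- substr(contig, new_start + 1L, new_end)
  if (identical(record$strand, "-")) seq <- reverse_complement(seq)
  record$start <- new_start
  record$end <- new_end
  record$sequence <- chartr("T", "U", toupper(seq))
  record
}

#' Sample negative windows matched to a positive set
#'
#' Draws `ratio` times as many negative windows as there are positives,
#' matching the per-genome and per-strand proportions of the positive set
#' within rounding. Negative windows never overlap positive intervals (they
#' may overlap each other).
#'
#' @param genomes named character vector of contig sequences.
#' @param positives data frame with columns `chrom`, `start`, `end`,
#'   `strand` describing positive intervals.
#' @param ratio negatives per positive (default 3).
#' @param target_length window length in nt (default 75).
#' @param seed integer seed.
#' @param max_tries rejection cap per window.
#' @return data frame: id, sequence, label (0), chrom, start, end, strand.
#' @export
sample_negatives <- function(genomes, positives, ratio = 3, seed = 1L,
                             target_length = 75L, max_tries = 1000L) {
  stopifnot(nrow(positives) > 0)
  groups <- split(positives, paste(positives$chrom, positives$strand))
  n_total <- round(ratio * nrow(positives))
  # largest-remainder apportionment of the negative count over groups
  quota <- vapply(groups, nrow, integer(1)) / nrow(positives) * n_total
  counts <- floor(quota)
  rem <- n_total - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  with_seed(seed, {
    out <- lapply(seq_along(groups), function(g) {
      grp <- groups[[g]]
      chrom <- grp$chrom[1]
      strand <- grp$strand[1]
      contig <- genomes[[chrom]]
      if (is.null(contig))
        stop("positives reference contig '", chrom,
             "' absent from genomes", call. = FALSE)
      clen <- nchar(contig)
      if (clen < target_length)
        stop("contig '", chrom, "' shorter than the window length",
             call. = FALSE)
      pos_iv <- positives[positives$chrom == chrom, c("start", "end")]
      starts <- integer(0)
      for (k in seq_len(counts[g])) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          s <- sample.int(clen - target_length + 1L, 1L) - 1L
          e <- s + target_length
          if (!any(s < pos_iv$end & e > pos_iv$start)) {
            starts <- c(starts, s)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not sample a negative window on '", chrom,
                      "' that avoids all positive intervals", call. = FALSE)
      }
      if (length(starts) == 0) return(NULL)
      seqs <- substring(contig, starts + 1L, starts + target_length)
      seqs <- chartr("T", "U", toupper(seqs))
      if (strand == "-") seqs <- vapply(seqs, reverse_complement,
                                        character(1), USE.NAMES = FALSE)
      data.frame(id = sprintf("neg_%s_%s_%d", chrom, strand, starts),
                 sequence = seqs, label = 0L, chrom = chrom,
                 start = starts, end = starts + target_length,
                 strand = strand, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Monte Carlo cross-validation splits
#'
#' Repeats an independent random shuffle of the records `n_replicates`
#' times (default 10) and cuts each shuffle into train/test/validation
#' parts (default fractions 0.70/0.15/0.15).
#'
#' @param n number of records, or a data frame whose rows are split.
#' @param fractions three fractions summing to 1.
#' @param n_replicates number of independent shuffles.
#' @param seed integer seed; replicate r uses a sub-seed derived from
#'   `seed` and `r`, so individual replicates are reproducible.
#' @param stratify optional vector of class labels; when given, the split is
#'   stratified so each part preserves class proportions.
#' @return list of `split_set` objects: `replicate`, and integer index
#'   vectors `train`, `test`, `validation` (disjoint, exhaustive).
#' @export
monte_carlo_split <- function(n, fractions = c(0.70, 0.15, 0.15),
                              n_replicates = 10L, seed = 1L,
                              stratify = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1", call. = FALSE)
  if (length(fractions) != 3)
    stop("expected three fractions (train/test/validation)", call. = FALSE)

  cut_parts <- function(idx) {
    m <- length(idx)
    sizes <- floor(fractions * m)
    rem <- m - sum(sizes)
    if (rem > 0) {
      extra <- order(fractions * m - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    split(idx, rep.int(c("train", "test", "validation"), sizes))
  }

  lapply(seq_len(n_replicates), function(r) {
    with_seed(subseed(seed, r), {
      if (is.null(stratify)) {
        parts <- cut_parts(sample.int(n))
      } else {
        parts <- list(train = integer(0), test = integer(0),
                      validation = integer(0))
        for (cls in unique(stratify)) {
          idx <- which(stratify == cls)
          p <- cut_parts(sample(idx))
          parts <- Map(c, parts, p[c("train", "test", "validation")])
        }
      }
      structure(list(replicate = r, train = sort(parts$train),
                     test = sort(parts$test),
                     validation = sort(parts$validation)),
                class = "split_set")
    })
  })
}
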