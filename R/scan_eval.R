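#' Extract elongated transcript regions from a genome
#'
#' Each transcript interval is extended by `elongation` nt on both ends
#' (clamped at contig boundaries) so terminators at transcript edges are
#' fully contained in the scan, and the sense-strand sequence is extracted
#' (reverse complement for minus-strand transcripts).
#'
#' @param transcripts BED-like data frame (chrom, start, end, name, score,
#'   strand; 0-based half-open).
#' @param genome named character vector of contig sequences.
#' @param elongation extension in nt (default 150).
#' @return data frame: name, chrom, start, end, strand, sequence (region
#'   coordinates after elongation).
#' @export
prepare_regions <- function(transcripts, genome, elongation = 150L) {
  missing <- setdiff(unique(transcripts$chrom), names(genome))
  if (length(missing) > 0)
    stop("transcripts reference contigs absent from the genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts[i, ]
    contig <- genome[[tr$chrom]]
    start <- max(0L, tr$start - elongation)
    end <- min(nchar(contig), tr$end + elongation)
    seq <- chartr("T", "U", toupper(substr(contig, start + 1L, end)))
    if (tr$strand == "-") seq <- reverse_complement(seq)
    data.frame(name = tr$name, chrom = tr$chrom, start = start, end = end,
               strand = tr$strand, sequence = seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Slide a model over a region sequence
#'
#' Scores windows of `window` nt at starts 0, step, 2*step, ... (region
#' coordinates, 0-based).
#'
#' @param model trained `termscan_model` (or a scoring function).
#' @param region_seq sequence to scan.
#' @param window window length (default 75, the model input length).
#' @param step step size in nt (default 3).
#' @param batch_size scoring batch size.
#' @return data frame with columns `start` and `score`, with attributes
#'   `window` and `step`. A region shorter than the window yields zero rows
#'   with a warning.
#' @export
scan_windows <- function(model, region_seq, window = 75L, step = 3L,
                         batch_size = 512L) {
  L <- nchar(region_seq)
  if (L < window) {
    warning("region shorter than the scan window; no windows scored")
    out <- data.frame(start = integer(0), score = numeric(0))
    attr(out, "window") <- window
    attr(out, "step") <- step
    return(out)
  }
  score <- as_scorer(model)
  starts <- seq(0L, L - window, by = step)
  seqs <- substring(region_seq, starts + 1L, starts + window)
  scores <- numeric(length(starts))
  for (lo in seq(1L, length(starts), by = batch_size)) {
    hi <- min(lo + batch_size - 1L, length(starts))
    scores[lo:hi] <- score(seqs[lo:hi])
  }
  out <- data.frame(start = starts, score = scores)
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Fuse above-threshold windows into hits
#'
#' Maximal runs of windows at consecutive step positions whose score exceeds
#' the threshold are fused into one hit spanning the union of their windows;
#' the hit carries the maximum score of the run and the central nucleotide
#' of the span. A single sub-threshold window breaks a run.
#'
#' @param windows result of [scan_windows()] (or data frame with `start`,
#'   `score` plus `window`/`step` attributes or arguments).
#' @param threshold fusion threshold on the model output (default 0.5,
#'   strictly exceeded).
#' @param window,step window geometry; default from attributes.
#' @return data frame of hits: `start`, `end` (0-based half-open span),
#'   `center`, `score`.
#' @export
call_hits <- function(windows, threshold = 0.5,
                      window = attr(windows, "window"),
                      step = attr(windows, "step")) {
  stopifnot(!is.null(window), !is.null(step))
  empty <- data.frame(start = integer(0), end = integer(0),
                      center = integer(0), score = numeric(0))
  hot <- which(windows$score > threshold)
  if (length(hot) == 0) return(empty)
  starts <- windows$start[hot]
  run_id <- cumsum(c(1L, diff(starts) != step))
  out <- lapply(split(seq_along(hot), run_id), function(ii) {
    s <- starts[ii[1]]
    e <- starts[ii[length(ii)]] + window
    data.frame(start = s, end = e,
               center = (s + e - 1L) %/% 2L,
               score = max(windows$score[hot[ii]]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan all transcripts of a genome and report hits in genome coordinates
#'
#' Convenience wrapper: [prepare_regions()], [scan_windows()] and
#' [call_hits()] per transcript, with hit centers mapped back from region to
#' genome coordinates (strand-aware).
#'
#' @inheritParams prepare_regions
#' @inheritParams scan_windows
#' @param threshold hit-fusion threshold.
#' @return BED-like data frame of hits: chrom, start, end, name, score,
#'   strand, plus `center` (genome coordinates).
#' @export
scan_transcriptome <- function(model, genome, transcripts,
                               elongation = 150L, window = 75L, step = 3L,
                               threshold = 0.5, batch_size = 512L) {
  regions <- prepare_regions(transcripts, genome, elongation)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    win <- scan_windows(model, rg$sequence, window = window, step = step,
                        batch_size = batch_size)
    hits <- call_hits(win, threshold = threshold)
    if (nrow(hits) == 0) return(NULL)
    if (rg$strand == "-") {
      g_start <- rg$end - hits$end
      g_end <- rg$end - hits$start
      center <- rg$end - 1L - hits$center
    } else {
      g_start <- rg$start + hits$start
      g_end <- rg$start + hits$end
      center <- rg$start + hits$center
    }
    data.frame(chrom = rg$chrom, start = g_start, end = g_end,
               name = paste0(rg$name, "_hit"), score = hits$score,
               strand = rg$strand, center = center,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      center = integer(0))
  rownames(out) <- NULL
  out
}

#' Precision-recall evaluation of scan hits against termination sites
#'
#' A hit is a true positive when its central nucleotide lies within the
#' distance threshold of the nearest site, a false positive otherwise; a
#' site with no hit within the threshold is a false negative. Recall counts
#' distinct detected sites (hit-to-site matching is not one-to-one). The PR
#' curve sweeps a secondary cutoff over the fused-hit scores and the AUPRC
#' is its average precision.
#'
#' @param hits data frame with `center` and `score` (e.g. from
#'   [scan_transcriptome()]).
#' @param sites integer vector of termination-site positions (same
#'   coordinate system as the hit centers), or a BED-like data frame whose
#'   `start` column holds the site positions.
#' @param thresholds distance thresholds in nt
#'   (default `c(10, 15, 35, 50, 100, 150, 250)`).
#' @return data frame with one row per threshold: distance_threshold, tp,
#'   fp, fn, precision, recall, auprc; PR curves attached as the
#'   `pr_curves` attribute (list of data frames).
#' @export
evaluate_scan <- function(hits, sites,
                          thresholds = c(10, 15, 35, 50, 100, 150, 250)) {
  if (is.data.frame(sites)) sites <- sites$start
  if (length(sites) == 0)
    stop("site list is empty; evaluation undefined", call. = FALSE)
  centers <- hits$center
  scores <- hits$score

  eval_at <- function(thr, keep) {
    cc <- centers[keep]; n_hits <- length(cc)
    if (n_hits == 0)
      return(c(tp = 0, fp = 0, fn = length(sites), precision = NA,
               recall = 0))
    dmin <- vapply(cc, function(x) min(abs(x - sites)), numeric(1))
    tp <- sum(dmin <= thr)
    fp <- n_hits - tp
    detected <- sum(vapply(sites, function(s)
      any(abs(cc - s) <= thr), logical(1)))
    c(tp = tp, fp = fp, fn = length(sites) - detected,
      precision = tp / n_hits, recall = detected / length(sites))
  }

  curves <- list()
  rows <- lapply(thresholds, function(thr) {
    base <- eval_at(thr, rep(TRUE, length(centers)))
    cuts <- sort(unique(scores), decreasing = TRUE)
    curve <- do.call(rbind, lapply(cuts, function(ct) {
      v <- eval_at(thr, scores >= ct)
      data.frame(cutoff = ct, precision = unname(v["precision"]),
                 recall = unname(v["recall"]))
    }))
    auprc <- if (is.null(curve) || nrow(curve) == 0) 0 else {
      prec <- ifelse(is.na(curve$precision), 0, curve$precision)
      sum(diff(c(0, curve$recall)) * prec)
    }
    curves[[as.character(thr)]] <<- curve
    data.frame(distance_threshold = thr, tp = unname(base["tp"]),
               fp = unname(base["fp"]), fn = unname(base["fn"]),
               precision = unname(base["precision"]),
               recall = unname(base["recall"]), auprc = auprc)
  })
  out <- do.call(rbind, rows)
  attr(out, "pr_curves") <- curves
  out
}

#' Mean model output as a function of distance to termination sites
#'
#' Averages window scores by the offset of the window center from the
#' nearest termination site, over all scanned regions.
#'
#' @param model trained model or scoring function.
#' @param regions result of [prepare_regions()].
#' @param sites integer site positions (genome coordinates) or BED-like
#'   data frame.
#' @param flank offset range; the profile spans `[-flank, +flank]`.
#' @param window,step scan geometry.
#' @return data frame: offset, mean_score, n (number of windows averaged).
#' @export
positional_profile <- function(model, regions, sites, flank = 150L,
                               window = 75L, step = 3L) {
  if (is.data.frame(sites)) sites <- sites$start
  acc <- new.env()
  acc$sum <- setNames(numeric(2 * flank + 1), -flank:flank)
  acc$n <- setNames(integer(2 * flank + 1), -flank:flank)
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    win <- scan_windows(model, rg$sequence, window = window, step = step)
    if (nrow(win) == 0) next
    center_local <- win$start + (window - 1L) %/% 2L
    center <- if (rg$strand == "-") rg$end - 1L - center_local
              else rg$start + center_local
    for (k in seq_along(center)) {
      d <- center[k] - sites
      d <- d[abs(d) <= flank]
      if (rg$strand == "-") d <- -d  # offsets in transcript orientation
      for (dd in d) {
        key <- as.character(dd)
        acc$sum[key] <- acc$sum[key] + win$score[k]
        acc$n[key] <- acc$n[key] + 1L
      }
    }
  }
  data.frame(offset = -flank:flank,
             mean_score = ifelse(acc$n > 0, acc$sum / acc$n, NA_real_),
             n = as.integer(acc$n), row.names = NULL)
}
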