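const_scorer <- function(value) function(seqs) rep(value, length(seqs))

test_that("region preparation elongates, clamps and respects strand", {
  set.seed(2)
  genome <- c(g = random_rna_seq(3000))
  tx <- data.frame(chrom = "g", start = c(1000, 50), end = c(2000, 400),
                   name = c("t1", "t2"), score = 0, strand = c("+", "-"))
  reg <- prepare_regions(tx, genome, elongation = 150)
  expect_equal(c(reg$start[1], reg$end[1]), c(850, 2150))
  expect_equal(reg$start[2], 0)  # clamped at the contig start
  expect_equal(nchar(reg$sequence[1]), 1300)
  expect_equal(reg$sequence[2],
               reverse_complement(substr(genome[["g"]], 1, 550)))
  expect_error(prepare_regions(data.frame(chrom = "missing", start = 1,
                                          end = 10, name = "x", score = 0,
                                          strand = "+"), genome),
               "absent")
})

test_that("window scans tile the region at the declared step", {
  set.seed(3)
  region <- random_rna_seq(84)
  win <- scan_windows(const_scorer(0.7), region, window = 75, step = 3)
  expect_equal(win$start, c(0, 3, 6, 9))
  expect_equal(win$score, rep(0.7, 4))

  one <- scan_windows(const_scorer(0.2), random_rna_seq(75))
  expect_equal(nrow(one), 1)

  expect_warning(short <- scan_windows(const_scorer(1), random_rna_seq(50)),
                 "shorter")
  expect_equal(nrow(short), 0)
})

test_that("hit fusion merges adjacent runs and breaks on gaps", {
  win <- data.frame(start = c(0, 3, 6, 9, 12, 15),
                    score = c(0.9, 0.8, 0.2, 0.6, 0.7, 0.3))
  hits <- call_hits(win, threshold = 0.5, window = 75, step = 3)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(0, 9))
  expect_equal(hits$end, c(3 + 75, 12 + 75))
  expect_equal(hits$score, c(0.9, 0.7))
  expect_equal(hits$center, c((0 + 78 - 1) %/% 2, (9 + 87 - 1) %/% 2))

  none <- call_hits(data.frame(start = 0, score = 0.4), threshold = 0.5,
                    window = 75, step = 3)
  expect_equal(nrow(none), 0)

  single <- call_hits(data.frame(start = 30, score = 0.8), threshold = 0.5,
                      window = 75, step = 3)
  expect_equal(c(single$start, single$end), c(30, 105))
})

test_that("hit fusion equals the brute-force reference grouping", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    starts <- seq(0, by = 3, length.out = n)
    scores <- round(runif(n), 3)
    win <- data.frame(start = starts, score = scores)
    ours <- call_hits(win, threshold = 0.5, window = 75, step = 3)
    ref <- oracle_call_hits(starts, scores, window = 75, step = 3)
    if (is.null(ref)) {
      expect_equal(nrow(ours), 0)
    } else {
      expect_equal(ours, ref, ignore_attr = TRUE)
    }
  }
})

test_that("scan evaluation classifies hits and sites by distance", {
  sites <- c(1000, 2000)
  hits <- data.frame(center = c(1005, 1960, 3000), score = c(0.9, 0.8, 0.7))
  ev <- evaluate_scan(hits, sites, thresholds = c(10, 50))
  r10 <- ev[ev$distance_threshold == 10, ]
  expect_equal(c(r10$tp, r10$fp, r10$fn), c(1, 2, 1))
  expect_equal(r10$precision, 1 / 3)
  expect_equal(r10$recall, 1 / 2)
  r50 <- ev[ev$distance_threshold == 50, ]
  expect_equal(c(r50$tp, r50$fp, r50$fn), c(2, 1, 0))
  expect_equal(r50$recall, 1)

  # single hit 40 nt from the only site at threshold 35: everything misses
  ev35 <- evaluate_scan(data.frame(center = 140, score = 0.9), 100,
                        thresholds = 35)
  expect_equal(c(ev35$tp, ev35$fp, ev35$fn), c(0, 1, 1))

  # no hits: recall 0, all sites are false negatives
  ev0 <- evaluate_scan(data.frame(center = numeric(0), score = numeric(0)),
                       sites, thresholds = 35)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$fn, 2)

  expect_error(evaluate_scan(hits, integer(0)), "empty")
})

test_that("hits exactly on all sites give perfect precision and recall", {
  sites <- c(500, 1500, 2500)
  hits <- data.frame(center = sites, score = c(0.9, 0.95, 0.99))
  ev <- evaluate_scan(hits, sites)
  expect_equal(ev$precision, rep(1, 7))
  expect_equal(ev$recall, rep(1, 7))
  expect_equal(ev$auprc, rep(1, 7))
})

test_that("recall is non-decreasing in the distance threshold", {
  set.seed(9)
  sites <- sort(sample(1:50000, 20))
  hits <- data.frame(center = sort(sample(1:50000, 40)),
                     score = runif(40, 0.5, 1))
  ev <- evaluate_scan(hits, sites)
  expect_true(all(diff(ev$recall) >= 0))
  expect_true(all(ev$fn == 20 - ev$recall * 20))
})

test_that("transcriptome scan maps hit centers back to genome coordinates", {
  set.seed(4)
  # genome with one strong GC hairpin implanted at a known position
  g <- make_genome(3, 6000, seed = 21)
  tx <- make_transcripts(g, seed = 5)
  # scorer: fraction of G+C in the window center region (proxy signal), max
  # at the implanted stems; used only to exercise coordinates
  scorer <- function(seqs) vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    mean(chars[30:45] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  hits <- scan_transcriptome(scorer, c(synth_genome = g$sequence),
                             tx$transcripts, window = 75, step = 3,
                             threshold = 0.7)
  if (nrow(hits) > 0) {
    expect_true(all(hits$center >= hits$start & hits$center < hits$end))
    expect_true(all(hits$start >= 0))
  }
  # with an always-on scorer every region yields exactly one fused hit
  all_on <- scan_transcriptome(const_scorer(0.9),
                               c(synth_genome = g$sequence),
                               tx$transcripts, window = 75, step = 3)
  expect_equal(nrow(all_on), nrow(tx$transcripts))
})

test_that("positional profile spans the flank and averages per offset", {
  region <- data.frame(name = "r1", chrom = "g", start = 0, end = 300,
                       strand = "+",
                       sequence = strrep("A", 300))
  prof <- positional_profile(const_scorer(0.4), region, sites = 150,
                             flank = 50, window = 75, step = 3)
  expect_equal(range(prof$offset), c(-50, 50))
  covered <- prof$n > 0
  expect_true(any(covered))
  expect_equal(unique(prof$mean_score[covered]), 0.4)
})
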