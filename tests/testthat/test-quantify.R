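test_that("precount index groups duplicate sequences under the lexicographic canonical name", {
  refs <- data.frame(name = c("miR-b", "miR-a", "miR-c"),
                     sequence = c("ACGTACGT", "ACGTACGT", "TTTTACGT"),
                     stringsAsFactors = FALSE)
  idx <- build_precount_index(refs)
  expect_equal(length(idx$sequences), 2L)
  expect_true("miR-a" %in% idx$canonical)
  expect_false("miR-b" %in% idx$canonical)
  expect_equal(idx$aliases[["miR-a"]], "miR-b")

  set.seed(41)
  sq <- vapply(1:18, function(i) random_dna_str(22), character(1))
  refs20 <- data.frame(name = sprintf("hsa-miR-d%02d", 1:20),
                       sequence = c(sq, sq[1:2]), stringsAsFactors = FALSE)
  expect_equal(length(build_precount_index(refs20)$sequences), 18L)
})

test_that("precounting assigns exact full-length matches only and conserves reads", {
  refs <- data.frame(name = c("miR-x", "miR-y"),
                     sequence = c("ACGTACGTACGTACGTACGTAC", "TTGTACGTACGTACGTACGTAC"),
                     stringsAsFactors = FALSE)
  idx <- build_precount_index(refs)
  reads <- data.frame(read_id = c("r1", "r2", "r3"),
                      insert = c("ACGTACGTACGTACGTACGTAC",   # exact
                                 "ACGTACGTACGTACGTACGTAG",   # one mismatch
                                 "ACGTACGTACGTACGTACGTA"),   # truncated
                      umi = "", stringsAsFactors = FALSE)
  pc <- precount(reads, idx)
  expect_equal(unname(pc$precounts["miR-x"]), 1L)
  expect_equal(sum(pc$precounts), 1L)
  expect_equal(pc$unmatched$read_id, c("r2", "r3"))
  expect_equal(sum(pc$precounts) + nrow(pc$unmatched), nrow(reads))
})

test_that("ungapped alignment finds planted hits on both strands in the best stratum", {
  set.seed(42)
  g <- random_dna_str(3000)
  genome <- c(chrT = g)
  read <- substring(g, 1001, 1022)
  h <- align_ungapped(read, genome, 1)
  expect_true(any(h$pos0 == 1000 & h$strand == "+" & h$mismatches == 0))

  hrc <- align_ungapped(revcomp(read), genome, 1)
  expect_true(any(hrc$pos0 == 1000 & hrc$strand == "-" & hrc$mismatches == 0))

  mut <- read
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(mut, 11, 11))[1]
  h1 <- align_ungapped(mut, genome, 1)
  expect_true(all(h1$mismatches == min(h1$mismatches)))
  expect_true(any(h1$pos0 == 1000 & h1$strand == "+" & h1$mismatches == 1))

  expect_equal(nrow(align_ungapped(substring(read, 1, 8), genome, 1)), 0L)  # shorter than seed
})

test_that("ungapped alignment equals the all-offsets scan on random toy genomes", {
  set.seed(43)
  genome <- c(chrA = random_dna_str(1500), chrB = random_dna_str(800))
  for (i in 1:25) {
    chrom <- sample(names(genome), 1)
    L <- sample(20:24, 1)
    st <- sample(nchar(genome[[chrom]]) - L, 1)
    read <- substring(genome[[chrom]], st, st + L - 1)
    if (runif(1) < 0.5) read <- revcomp(read)
    if (runif(1) < 0.6) {
      p <- sample(L, 1)
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    mm <- sample(0:2, 1)
    expect_equal(align_ungapped(read, genome, mm), oracle_align(read, genome, mm))
  }
})

test_that("feature counting is strand-specific, overlap-permitting, and drops multi-mappers", {
  features <- data.frame(chrom = "chr1", start = c(100L, 105L, 300L),
                         end = c(130L, 140L, 330L),
                         name = c("fA", "fB", "fC"), score = 0,
                         strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  hit <- function(pos, strand) data.frame(chrom = "chr1", pos0 = pos, strand = strand,
                                          mismatches = 0L, stringsAsFactors = FALSE)
  hits <- list(r1 = hit(106, "+"),                    # overlaps fA and fB (nested)
               r2 = hit(106, "-"),                    # wrong strand
               r3 = rbind(hit(100, "+"), hit(300, "+")),  # multi-placement
               r4 = hit(305, "-"),                    # fC
               r5 = hit(2000, "+"))                   # no feature
  lens <- setNames(rep(22L, 5), names(hits))
  cf <- count_features(hits, lens, features)
  expect_equal(unname(cf$feature_counts[c("fA", "fB", "fC")]), c(1L, 1L, 1L))
  expect_equal(cf$ambiguous, 1L)
  expect_equal(cf$no_feature, 2L)  # r2 (strand) and r5 (outside)
  expect_equal(cf$assigned, 2L)

  cf_un <- count_features(hits, lens, features, stranded = FALSE)
  expect_equal(unname(cf_un$feature_counts[c("fA", "fB")]), c(2L, 2L))
})

test_that("count merging is additive over precounts and feature counts", {
  total <- merge_counts(c("miR-x" = 5, "miR-y" = 0), c("miR-x" = 3, "miR-z" = 7))
  expect_equal(unname(total[c("miR-x", "miR-y", "miR-z")]), c(8, 0, 7))
})

test_that("matrix assembly unions features, keeps sample order, retains provenance", {
  q <- function(pre, fc) structure(list(precounts = pre, feature_counts = fc,
                                        total = merge_counts(pre, fc)),
                                   class = "sample_quant")
  quants <- list(s1 = q(c(a = 2), c(b = 1)), s2 = q(c(c = 4), setNames(integer(0), character(0))))
  m <- assemble_matrix(quants)
  expect_equal(colnames(m), c("s1", "s2"))
  expect_equal(sort(rownames(m)), c("a", "b", "c"))
  expect_equal(m["a", ], c(s1 = 2, s2 = 0))
  prov <- attr(m, "provenance")
  expect_equal(prov$precount + prov$feature_count, m, ignore_attr = TRUE)

  m2 <- assemble_matrix(quants[c("s2", "s1")])
  expect_equal(m2[, colnames(m)], m, ignore_attr = TRUE)
  expect_error(assemble_matrix(list(q(c(a = 1), c()), q(c(a = 1), c()))), "named")
})

test_that("three-prime variants fall through to feature counting and conservation holds", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_mirnas = 8L, genome_len = 2000L, n_per_condition = 1L,
                    mean_range = c(20, 40), duplication_rate = 0,
                    base_error_rate = 0, three_prime_variation = 0.4, seed = 51)
  ref <- make_reference(cfg)
  sim <- simulate_counts(cfg)
  tr <- synthesize_reads(sim$counts, ref, cfg, d)
  idx <- build_precount_index(ref$mature)
  p <- prep_sample(tr$fastq[[1]])
  qs <- quantify_sample(p$reads, idx, ref$genome, ref$features)
  r <- qs$report
  expect_equal(r$input_reads, r$precounted + r$unmatched)
  expect_gt(r$unmatched, 0L)  # truncated inserts cannot precount
  expect_gt(sum(qs$feature_counts), 0L)  # but they align onto their locus
  expect_equal(r$unmatched, r$assigned + r$no_feature + r$ambiguous + r$unplaced)
  expect_true(all(qs$total[names(qs$precounts)] >= qs$precounts))
})

test_that("external SAM alignments can replace the built-in aligner", {
  features <- data.frame(chrom = "chr1", start = 100L, end = 130L, name = "fA",
                         score = 0, strand = "+", stringsAsFactors = FALSE)
  refs <- data.frame(name = "miR-q", sequence = strrep("ACGT", 6), stringsAsFactors = FALSE)
  idx <- build_precount_index(refs)
  reads <- data.frame(read_id = "r1", insert = strrep("TGCA", 6), umi = "",
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(paste("r1", 0, "chr1", 106, 255, "24M", "*", 0, 0,
                   strrep("TGCA", 6), strrep("I", 24), sep = "\t"), f)
  qs <- quantify_sample(reads, idx, features = features, sam = read_sam_minimal(f))
  expect_equal(unname(qs$total["fA"]), 1)
})
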