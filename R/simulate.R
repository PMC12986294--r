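# Synthetic-data generator: random references (genome + mature miRNAs +
# BED features), two-condition NB count tables with known log2FC, and
# UMI-tagged QIAseq-style FASTQ libraries with PCR duplicates and base
# errors — everything the other modules need, with ground truth attached.
# All generators are pure functions of (config, seed); each operation (and
# each per-sample read synthesis) draws from its own derived RNG stream.

#' Simulator configuration
#'
#' Defaults model a desk-scale two-condition small-RNA experiment with the
#' library structure the package targets: 72 nt reads of insert + 19 nt
#' adapter + 12 nt UMI + filler, log-uniform expression between 10 and 1000
#' expected molecules, NB dispersion 0.2, 10% of miRNAs differentially
#' expressed at |log2FC| = 2, 50% PCR duplication and a 0.1% per-base
#' substitution error rate.
#'
#' @param n_mirnas number of miRNA loci.
#' @param genome_len genome length (nt, single chromosome).
#' @param mirna_len_range inclusive mature length range.
#' @param n_per_condition samples per condition.
#' @param mean_range expected-molecule range (log-uniform).
#' @param dispersion NB dispersion alpha (0 = Poisson).
#' @param de_fraction fraction of miRNAs with a true effect.
#' @param true_lfc |log2FC| of true effects (sign random per miRNA).
#' @param duplication_rate per-molecule probability of one PCR duplicate.
#' @param base_error_rate per-base substitution probability.
#' @param read_len sequenced read length.
#' @param adapter,umi_len library chemistry (match [trim_config()]).
#' @param three_prime_variation fraction of molecules with a 1-2 nt 3'
#'   truncation of the insert (exercises the alignment fallback; default 0).
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 200L, genome_len = 20000L,
                       mirna_len_range = c(20L, 24L), n_per_condition = 6L,
                       mean_range = c(10, 1000), dispersion = 0.2,
                       de_fraction = 0.1, true_lfc = 2,
                       duplication_rate = 0.5, base_error_rate = 0.001,
                       read_len = 72L, adapter = "AACTGTAGGCACCATCAAT",
                       umi_len = 12L, three_prime_variation = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_mirnas = as.integer(n_mirnas), genome_len = as.integer(genome_len),
              mirna_len_range = as.integer(mirna_len_range),
              n_per_condition = as.integer(n_per_condition),
              mean_range = mean_range, dispersion = dispersion,
              de_fraction = de_fraction, true_lfc = true_lfc,
              duplication_rate = duplication_rate,
              base_error_rate = base_error_rate, read_len = as.integer(read_len),
              adapter = adapter, umi_len = as.integer(umi_len),
              three_prime_variation = three_prime_variation, seed = seed)
  for (r in c(de_fraction, duplication_rate, base_error_rate, three_prime_variation))
    .chk_num(r, "rate", 0, 1)
  stopifnot(mirna_len_range[1] <= mirna_len_range[2], mean_range[1] > 0)
  structure(cfg, class = "sim_config")
}

.random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic genome, mature reference and feature annotation
#'
#' A random genome with `n_mirnas` non-overlapping stranded loci; each mature
#' sequence equals its genomic locus (`+`) or the locus' reverse complement
#' (`-`), so every mature sequence is re-locatable at its BED interval.
#' Mature names are `hsa-miR-sim-<i>`. Mature sequences are guaranteed
#' distinct. Byte-identical for identical (config, seed).
#'
#' @param cfg a [sim_config()].
#' @return list: `genome` (named character vector, chromosome `chrS`),
#'   `mature` (data.frame `name`, `sequence`), `features` (BED6 data.frame).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "reference"))
  genome <- .random_dna(cfg$genome_len)
  n <- cfg$n_mirnas
  if (n == 0L)
    return(list(genome = c(chrS = genome),
                mature = data.frame(name = character(), sequence = character(),
                                    stringsAsFactors = FALSE),
                features = data.frame(chrom = character(), start = integer(),
                                      end = integer(), name = character(),
                                      score = numeric(), strand = character(),
                                      stringsAsFactors = FALSE)))
  lens <- sample(seq(cfg$mirna_len_range[1], cfg$mirna_len_range[2]), n, replace = TRUE)
  # lay loci on a fixed grid with >= 2 nt gaps, then shuffle placements
  pitch <- max(lens) + 2L
  n_slots <- cfg$genome_len %/% pitch
  if (n_slots < n) stop("genome too short to place loci without overlap")
  slots <- sort(sample(n_slots, n))
  start <- (slots - 1L) * pitch
  end <- start + lens
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome, start + 1L, end)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  if (anyDuplicated(seqs))
    stop("duplicate mature sequences drawn; use a longer genome or another seed")
  name <- sprintf("hsa-miR-sim-%03d", seq_len(n))
  list(genome = c(chrS = genome),
       mature = data.frame(name = name, sequence = seqs, stringsAsFactors = FALSE),
       features = data.frame(chrom = "chrS", start = start, end = end,
                             name = name, score = 0, strand = strand,
                             stringsAsFactors = FALSE))
}

#' Simulate a two-condition NB count table with known truth
#'
#' Per-miRNA baseline means are log-uniform over `mean_range`; a fixed number
#' `round(de_fraction * n_mirnas)` of miRNAs get a true log2FC of
#' `+/- true_lfc` (random sign) applied to the treatment condition. Counts
#' are NB with dispersion `alpha` (Poisson when `alpha = 0`).
#'
#' @param cfg a [sim_config()].
#' @return list: `counts` (features x samples matrix; samples `ref_*` then
#'   `trt_*`), `condition` (character vector), `truth` (list: `mu`, `lfc`,
#'   `de_flags`, `dispersion`, `seed`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "counts"))
  n <- cfg$n_mirnas
  mu <- exp(stats::runif(n, log(cfg$mean_range[1]), log(cfg$mean_range[2])))
  n_de <- round(cfg$de_fraction * n)
  de <- rep(FALSE, n); de[sample(n, n_de)] <- TRUE
  lfc <- numeric(n)
  lfc[de] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$true_lfc
  ns <- cfg$n_per_condition
  condition <- rep(c("reference", "treatment"), each = ns)
  mu_mat <- outer(mu, ifelse(condition == "treatment", 1, 0),
                  function(m, trt) m) * 2^outer(lfc, ifelse(condition == "treatment", 1, 0))
  draw <- function(m) {
    if (cfg$dispersion <= 0) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), size = 1 / cfg$dispersion, mu = m)
  }
  counts <- matrix(draw(mu_mat), n, 2L * ns)
  names_feat <- if (n) sprintf("hsa-miR-sim-%03d", seq_len(n)) else character()
  dimnames(counts) <- list(names_feat,
                           paste0(rep(c("ref_", "trt_"), each = ns), seq_len(ns)))
  list(counts = counts, condition = condition,
       truth = list(mu = setNames(mu, names_feat), lfc = setNames(lfc, names_feat),
                    de_flags = setNames(de, names_feat),
                    dispersion = cfg$dispersion, seed = cfg$seed))
}

.apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(list(reads = reads, n_errors = 0L))
  chars <- strsplit(reads, "", fixed = TRUE)
  n_err <- 0L
  for (i in seq_along(chars)) {
    hit <- which(stats::runif(length(chars[[i]])) < rate)
    for (p in hit)
      chars[[i]][p] <- sample(setdiff(DNA_BASES, chars[[i]][p]), 1L)
    n_err <- n_err + length(hit)
  }
  list(reads = vapply(chars, paste, character(1), collapse = ""), n_errors = n_err)
}

# filler that never recreates the adapter's first 6 nt (rejected sampling),
# so the leftmost adapter match stays the real one
.safe_filler <- function(n, adapter) {
  if (n <= 0L) return("")
  probe <- substr(adapter, 1L, min(6L, nchar(adapter)))
  repeat {
    f <- .random_dna(n)
    if (!grepl(probe, f, fixed = TRUE)) return(f)
  }
}

#' Synthesise UMI-tagged FASTQ libraries from a true count table
#'
#' Each molecule becomes a read: mature insert (optionally 3'-truncated by
#' 1-2 nt for a `three_prime_variation` fraction), then the adapter, a random
#' UMI, and random filler to `read_len` nt; per-base substitution errors are
#' applied at `base_error_rate`; with probability `duplication_rate` a PCR
#' duplicate (an exact copy, same UMI) is appended. Qualities are constant
#' phred 40. Byte-identical FASTQ for identical (config, seed).
#'
#' @param counts true molecule counts (features x samples), e.g. from
#'   [simulate_counts()].
#' @param ref a [make_reference()] result (feature order must match rows).
#' @param cfg the [sim_config()].
#' @param dir output directory for `<sample>.fastq` files.
#' @return list of class `sim_truth`: `fastq` (named paths), `molecules`
#'   (the true count matrix), `n_reads`, `n_duplicates`, `n_errors`,
#'   `distinct_pairs` (distinct (insert, UMI) keys per sample, the dedup
#'   oracle), per sample.
#' @export
synthesize_reads <- function(counts, ref, cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"), nrow(counts) == nrow(ref$mature))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- character(0); n_reads <- integer(0); n_dup <- integer(0)
  n_err <- integer(0); distinct <- integer(0)
  for (s in colnames(counts)) {
    set.seed(derive_seed(cfg$seed, paste0("reads:", s)))
    src <- rep(seq_len(nrow(counts)), counts[, s])
    insert <- ref$mature$sequence[src]
    if (cfg$three_prime_variation > 0 && length(insert)) {
      vary <- stats::runif(length(insert)) < cfg$three_prime_variation
      cut <- sample(1:2, sum(vary), replace = TRUE)
      insert[vary] <- substr(insert[vary], 1L, nchar(insert[vary]) - cut)
    }
    umi <- vapply(seq_along(insert), function(i) .random_dna(cfg$umi_len), character(1))
    body <- paste0(insert, cfg$adapter, umi)
    fill <- vapply(pmax(cfg$read_len - nchar(body), 0L), .safe_filler,
                   character(1), adapter = cfg$adapter)
    reads <- substr(paste0(body, fill), 1L, cfg$read_len)
    err <- .apply_errors(reads, cfg$base_error_rate)
    reads <- err$reads
    dup <- stats::runif(length(reads)) < cfg$duplication_rate
    ids <- sprintf("%s_m%06d", s, seq_along(reads))
    all_reads <- c(reads, reads[dup])
    all_ids <- c(ids, paste0(ids[dup], "_dup"))
    ord <- order(c(seq_along(reads), which(dup) + 0.5))  # duplicate follows its template
    df <- data.frame(read_id = all_ids[ord], bases = all_reads[ord],
                     qual = strrep("I", nchar(all_reads[ord])),
                     stringsAsFactors = FALSE)
    path <- file.path(dir, paste0(s, ".fastq"))
    write_fastq(df, path)
    # dedup oracle: distinct (errored insert, errored UMI) pairs among molecules
    key <- paste(substr(reads, 1L, nchar(insert)),
                 vapply(seq_along(reads), function(i) {
                   a <- nchar(insert[i]) + nchar(cfg$adapter)
                   substr(reads[i], a + 1L, a + cfg$umi_len)
                 }, character(1)), sep = "\x1f")
    fastq[s] <- path; n_reads[s] <- nrow(df); n_dup[s] <- sum(dup)
    n_err[s] <- err$n_errors; distinct[s] <- length(unique(key))
  }
  structure(list(fastq = fastq, molecules = counts, n_reads = n_reads,
                 n_duplicates = n_dup, n_errors = n_err,
                 distinct_pairs = distinct),
            class = "sim_truth")
}

#' Preset fixture suites
#'
#' Writes a self-contained fixture directory with fixed configuration:
#' * `tiny` — 10 miRNAs, 2 vs 2 samples, ~500 molecules per sample, no PCR
#'   duplicates, no errors; full file set (genome/mature FASTA, BED, FASTQ
#'   per sample, sample sheet, counts, truth JSON). Completes in seconds.
#' * `de_recovery` — 200 miRNAs, 6 vs 6, 20 true effects at |log2FC| = 2,
#'   dispersion 0.2; count-level fixture (reference, counts, sample sheet,
#'   truth JSON; no FASTQ — the differential expression checks it feeds need
#'   only counts).
#' * `null_calibration` — 500 miRNAs, 6 vs 6, no true effects, dispersion
#'   0.2; count-level fixture.
#'
#' @param preset one of `"tiny"`, `"de_recovery"`, `"null_calibration"`.
#' @param dir output directory.
#' @param seed integer seed (default 20770305).
#' @return list: the `sim_config` used, file paths, and the truth objects.
#' @export
make_fixture_suite <- function(preset = c("tiny", "de_recovery", "null_calibration"),
                               dir, seed = 20770305) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = sim_config(n_mirnas = 10L, genome_len = 2000L, n_per_condition = 2L,
                      mean_range = c(30, 80), dispersion = 0.2,
                      de_fraction = 0.2, true_lfc = 2, duplication_rate = 0,
                      base_error_rate = 0, seed = seed),
    de_recovery = sim_config(n_mirnas = 200L, genome_len = 20000L,
                             n_per_condition = 6L, mean_range = c(50, 1000),
                             dispersion = 0.2, de_fraction = 0.1, true_lfc = 2,
                             seed = seed),
    null_calibration = sim_config(n_mirnas = 500L, genome_len = 40000L,
                                  n_per_condition = 6L, mean_range = c(50, 500),
                                  dispersion = 0.2, de_fraction = 0,
                                  seed = seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(cfg)
  sim <- simulate_counts(cfg)
  paths <- list(genome = file.path(dir, "genome.fa"),
                mature = file.path(dir, "mature.fa"),
                features = file.path(dir, "mirna.bed"),
                counts = file.path(dir, "true_counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.json"))
  write_fasta(ref$genome, paths$genome)
  write_fasta(ref$mature, paths$mature)
  write_bed6(ref$features, paths$features)
  write_counts_tsv(sim$counts, paths$counts)
  truth <- list(preset = preset, seed = seed,
                lfc = as.list(sim$truth$lfc), de_flags = as.list(sim$truth$de_flags),
                dispersion = cfg$dispersion)
  reads_truth <- NULL
  sheet <- data.frame(sample_id = colnames(sim$counts),
                      fastq_path = NA_character_,
                      condition = sim$condition, stringsAsFactors = FALSE)
  if (preset == "tiny") {
    reads_truth <- synthesize_reads(sim$counts, ref, cfg, dir)
    # relative paths keep regenerated fixture directories byte-identical
    sheet$fastq_path <- basename(unname(reads_truth$fastq[sheet$sample_id]))
    truth$n_reads <- as.list(reads_truth$n_reads)
    truth$distinct_pairs <- as.list(reads_truth$distinct_pairs)
  }
  utils::write.table(sheet, paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  list(config = cfg, paths = paths, reference = ref, counts = sim$counts,
       condition = sim$condition, truth = sim$truth, reads_truth = reads_truth)
}
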