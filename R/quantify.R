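# Two-step quantification: exact-sequence "precounting" against mature miRNA
# references, then a fallback ungapped genomic alignment of unmatched reads
# with strand-aware feature-overlap counting, merged into one matrix.

#' Filter mature references to one species
#'
#' Mirrors the usual miRBase filter "for the species and biotype of interest"
#' as a name-prefix filter (default human, `hsa-`).
#'
#' @param refs data.frame from [read_fasta()].
#' @param prefix species name prefix.
#' @return the filtered data.frame.
#' @export
filter_species <- function(refs, prefix = "hsa-") {
  refs[startsWith(refs$name, prefix), , drop = FALSE]
}

#' Build an exact-sequence precount index
#'
#' Identical mature sequences are grouped under one canonical name (the
#' lexicographically smallest, C-locale) with the remaining names recorded as
#' aliases, so identical sequences are never counted twice.
#'
#' @param refs data.frame with `name` and `sequence` (U already transliterated
#'   to T, as [read_fasta()] does).
#' @return list of class `precount_index`: `sequences` (unique sequences),
#'   `canonical` (parallel canonical names), `aliases` (named list), `names`
#'   (all canonical names).
#' @export
build_precount_index <- function(refs) {
  stopifnot(all(c("name", "sequence") %in% names(refs)))
  if (anyDuplicated(refs$name)) stop("duplicate reference names")
  if (any(grepl("U", refs$sequence, fixed = TRUE)))
    stop("reference sequences contain U; load with read_fasta()")
  grp <- split(refs$name, refs$sequence)
  seqs <- names(grp)
  canon <- vapply(grp, function(nm) sort(nm, method = "radix")[1L], character(1),
                  USE.NAMES = FALSE)
  aliases <- lapply(grp, function(nm) setdiff(sort(nm, method = "radix"), sort(nm, method = "radix")[1L]))
  names(aliases) <- canon
  structure(list(sequences = seqs, canonical = canon, aliases = aliases,
                 names = sort(canon, method = "radix")),
            class = "precount_index")
}

#' Exact-sequence read assignment (precounting)
#'
#' A read increments exactly one canonical miRNA count iff its insert equals a
#' reference sequence exactly and at full length; all other reads are returned
#' unmatched. Counts plus unmatched reads conserve the input.
#'
#' @param processed data.frame of deduplicated reads (needs an `insert`
#'   column).
#' @param index a [build_precount_index()] result.
#' @return list: `precounts` (named integer vector over all canonical names),
#'   `unmatched` (the unmatched rows of `processed`).
#' @export
precount <- function(processed, index) {
  stopifnot(inherits(index, "precount_index"))
  m <- match(processed$insert, index$sequences)
  hit <- !is.na(m)
  counts <- integer(length(index$names))
  names(counts) <- index$names
  if (any(hit)) {
    tab <- table(index$canonical[m[hit]])
    counts[names(tab)] <- as.integer(tab)
  }
  list(precounts = counts, unmatched = processed[!hit, , drop = FALSE])
}

# mismatch counts of `pattern` against every offset of `chrom_raw`
# (raw-byte column comparison; one vector op per pattern position)
.mm_profile <- function(chrom_raw, pattern) {
  L <- nchar(pattern); G <- length(chrom_raw)
  n_off <- G - L + 1L
  if (n_off < 1L) return(integer(0))
  p <- charToRaw(pattern)
  mm <- integer(n_off)
  for (d in seq_len(L)) mm <- mm + (chrom_raw[d:(d + n_off - 1L)] != p[d])
  mm
}

# candidate 0-based offsets where `pattern` could align with <= max_mm
# substitutions: exact hits of the (max_mm+1) pigeonhole seeds when the read
# is long enough to guarantee one error-free seed, otherwise every offset
.candidate_offsets <- function(chrom_seq, pattern, max_mm, seed_k) {
  L <- nchar(pattern); G <- nchar(chrom_seq)
  if (G < L) return(integer(0))
  if (L >= (max_mm + 1L) * seed_k) {
    cand <- integer(0)
    for (i in 0:max_mm) {
      seed <- substr(pattern, i * seed_k + 1L, i * seed_k + seed_k)
      m <- gregexpr(seed, chrom_seq, fixed = TRUE)[[1]]
      if (m[1] > 0) cand <- c(cand, (m - 1L) - i * seed_k)
    }
    cand <- sort(unique(cand))
    cand[cand >= 0L & cand <= G - L]
  } else 0:(G - L)
}

#' Ungapped alignment of a read against a genome
#'
#' Seed-and-extend with substitutions only: candidate placements (from exact
#' seed hits when the pigeonhole bound guarantees an error-free seed, from an
#' exhaustive vectorised scan otherwise) are verified on both strands and the
#' best stratum (minimum mismatch count, `<= max_mismatches`) is returned in
#' deterministic (chrom, pos, strand) order. A `-`-strand hit means the
#' genomic interval matches the read's reverse complement. Reads shorter than
#' `seed_k` are not aligned.
#'
#' @param read read sequence (single string).
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatches maximum substitutions allowed.
#' @param seed_k seed length.
#' @return data.frame: `chrom`, `pos0` (0-based start), `strand`,
#'   `mismatches`. Zero rows when unaligned.
#' @export
align_ungapped <- function(read, genome, max_mismatches = 1L, seed_k = 12L) {
  empty <- data.frame(chrom = character(), pos0 = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  L <- nchar(read)
  if (L < seed_k) return(empty)
  pats <- c("+" = read, "-" = revcomp(read))
  hits <- empty
  for (chrom in names(genome)) {
    craw <- charToRaw(genome[[chrom]])
    for (strand in c("+", "-")) {
      cand <- .candidate_offsets(genome[[chrom]], pats[[strand]], max_mismatches, seed_k)
      if (!length(cand)) next
      if (length(cand) == nchar(genome[[chrom]]) - L + 1L) {
        mm <- .mm_profile(craw, pats[[strand]])
        ok <- which(mm <= max_mismatches)
        if (length(ok))
          hits <- rbind(hits, data.frame(chrom = chrom, pos0 = ok - 1L,
                                         strand = strand, mismatches = mm[ok],
                                         stringsAsFactors = FALSE))
      } else {
        p <- charToRaw(pats[[strand]])
        for (off in cand) {
          mm <- sum(craw[(off + 1L):(off + L)] != p)
          if (mm <= max_mismatches)
            hits <- rbind(hits, data.frame(chrom = chrom, pos0 = off,
                                           strand = strand, mismatches = mm,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (!nrow(hits)) return(empty)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$pos0, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Strand-aware feature-overlap counting
#'
#' A read is assigned iff it has exactly one genomic placement; it then
#' increments every feature it overlaps by at least 1 bp on the same strand
#' (overlap-permitting mode: a read spanning several same-strand features
#' counts each of them). Multi-placement reads are discarded as ambiguous.
#'
#' @param hits_by_read named list of [align_ungapped()] results (one entry per
#'   read; the read's insert length is inferred from `read_len`).
#' @param read_len named integer vector of read lengths (same names).
#' @param features data.frame from [read_bed6()].
#' @param stranded require read and feature strand to agree.
#' @return list: `feature_counts` (named integer vector over all feature
#'   names), `assigned`, `ambiguous`, `unplaced`, `no_feature` counters.
#' @export
count_features <- function(hits_by_read, read_len, features, stranded = TRUE) {
  counts <- integer(nrow(features))
  names(counts) <- features$name
  n_hits <- vapply(hits_by_read, nrow, integer(1))
  ambiguous <- sum(n_hits > 1L)
  unplaced <- sum(n_hits == 0L)
  uniq <- names(hits_by_read)[n_hits == 1L]
  no_feature <- 0L
  if (length(uniq) && nrow(features)) {
    h <- do.call(rbind, hits_by_read[uniq])
    len <- read_len[uniq]
    reads_gr <- GenomicRanges::GRanges(
      h$chrom, IRanges::IRanges(start = h$pos0 + 1L, width = len),
      strand = h$strand)
    feat_gr <- GenomicRanges::GRanges(
      features$chrom, IRanges::IRanges(start = features$start + 1L, end = features$end),
      strand = features$strand)
    ov <- GenomicRanges::findOverlaps(reads_gr, feat_gr, minoverlap = 1L,
                                      ignore.strand = !stranded)
    if (length(ov)) {
      tab <- table(features$name[S4Vectors::subjectHits(ov)])
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    no_feature <- sum(!seq_along(uniq) %in% S4Vectors::queryHits(ov))
  } else no_feature <- length(uniq)
  list(feature_counts = counts, assigned = length(uniq) - no_feature,
       ambiguous = ambiguous, unplaced = unplaced, no_feature = no_feature)
}

#' Merge precounts and feature counts into a per-sample total
#'
#' Feature names identical to canonical reference names are reconciled by
#' exact string match; other feature names remain as additional rows. The
#' total for each miRNA is the sum of its precount and feature count.
#'
#' @param precounts named integer vector (canonical reference names).
#' @param feature_counts named integer vector (feature names).
#' @return named numeric vector of total abundances.
#' @export
merge_counts <- function(precounts, feature_counts) {
  all_names <- union(names(precounts), names(feature_counts))
  total <- setNames(numeric(length(all_names)), all_names)
  total[names(precounts)] <- total[names(precounts)] + precounts
  if (length(feature_counts))
    total[names(feature_counts)] <- total[names(feature_counts)] + feature_counts
  total
}

#' Quantify one prepared sample
#'
#' Runs precounting, aligns the unmatched reads, counts strand-aware feature
#' overlaps of uniquely placed reads and merges the two count sets.
#'
#' @param processed deduplicated reads from [prep_sample()], or a FASTQ path
#'   (then [prep_sample()] is run with `cfg`).
#' @param index a [build_precount_index()].
#' @param genome named character vector of chromosome sequences (optional:
#'   without it the fallback stage is skipped).
#' @param features data.frame from [read_bed6()] (optional with `genome`).
#' @param sam optional [read_sam_minimal()] result providing external
#'   alignments for the unmatched reads instead of the built-in aligner.
#' @param max_mismatches,seed_k aligner parameters.
#' @param stranded strand-specific feature counting.
#' @param cfg [trim_config()] used when `processed` is a path.
#' @return list of class `sample_quant`: `precounts`, `feature_counts`,
#'   `total` (merged), and a `report` with conservation counters.
#' @export
quantify_sample <- function(processed, index, genome = NULL, features = NULL,
                            sam = NULL, max_mismatches = 1L, seed_k = 12L,
                            stranded = TRUE, cfg = trim_config()) {
  if (is.character(processed)) processed <- prep_sample(processed, cfg)$reads
  if (is.list(processed) && !is.data.frame(processed) && !is.null(processed$reads))
    processed <- processed$reads
  pc <- precount(processed, index)
  un <- pc$unmatched
  fc <- setNames(integer(0), character(0))
  counters <- list(assigned = 0L, ambiguous = 0L, unplaced = nrow(un), no_feature = 0L)
  if (nrow(un) && !is.null(features)) {
    if (!is.null(sam)) {
      al <- sam$alignments
      hits_by_read <- lapply(un$read_id, function(id) {
        h <- al[al$read_id == id, c("chrom", "pos0", "strand"), drop = FALSE]
        h$mismatches <- 0L
        h
      })
    } else {
      stopifnot(!is.null(genome))
      hits_by_read <- lapply(un$insert, align_ungapped, genome = genome,
                             max_mismatches = max_mismatches, seed_k = seed_k)
    }
    names(hits_by_read) <- un$read_id
    lens <- setNames(nchar(un$insert), un$read_id)
    cf <- count_features(hits_by_read, lens, features, stranded = stranded)
    fc <- cf$feature_counts
    counters <- cf[c("assigned", "ambiguous", "unplaced", "no_feature")]
  }
  total <- merge_counts(pc$precounts, fc)
  structure(list(precounts = pc$precounts, feature_counts = fc, total = total,
                 report = c(list(input_reads = nrow(processed),
                                 precounted = sum(pc$precounts),
                                 unmatched = nrow(un)), counters)),
            class = "sample_quant")
}

#' Assemble the final quantification matrix
#'
#' Rows are the union of miRNA names across samples (absent entries are 0),
#' columns follow the given sample order. The per-cell precount /
#' feature-count split is retained in the `"provenance"` attribute.
#'
#' @param quants named list of `sample_quant` objects (names = sample ids, in
#'   sample-sheet order).
#' @return numeric matrix (features x samples) with a `provenance` attribute
#'   (list of two matrices, `precount` and `feature_count`).
#' @export
assemble_matrix <- function(quants) {
  stopifnot(length(quants) >= 1L)
  ids <- names(quants)
  if (is.null(ids) || any(!nzchar(ids))) stop("quants must be a named list of samples")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  feat <- sort(unique(unlist(lapply(quants, function(q) names(q$total)))), method = "radix")
  fill <- function(get) {
    m <- matrix(0, length(feat), length(ids), dimnames = list(feat, ids))
    for (s in ids) {
      v <- get(quants[[s]])
      if (length(v)) m[names(v), s] <- v
    }
    m
  }
  total <- fill(function(q) q$total)
  prov <- list(precount = fill(function(q) q$precounts),
               feature_count = fill(function(q) q$feature_counts))
  stopifnot(all(prov$precount + prov$feature_count == total))
  attr(total, "provenance") <- prov
  total
}
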