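# Read preparation for a QIAseq-style library layout:
#   insert -- 3' adapter -- 12 nt UMI -- filler (to the sequenced length).
# Stages: adapter location + UMI extraction -> BWA-style 3' quality trim ->
# length filter -> UMI deduplication.

#' Trimming configuration for QIAseq-style reads
#'
#' The kit's adapter sequence and UMI length are not dictated by the data; the
#' defaults follow the QIAseq miRNA kit (19 nt adapter, 12 nt UMI). Thresholds
#' default to the small-RNA settings used throughout the package: phred 10,
#' insert length 10-40 nt.
#'
#' @param adapter 3' adapter DNA sequence.
#' @param umi_len UMI length in nt (>= 0).
#' @param max_adapter_error_rate maximum fraction of substitutions allowed in
#'   the aligned part of the adapter (in `[0, 0.5)`).
#' @param phred_threshold 3' quality-trim threshold.
#' @param min_len,max_len inclusive insert length bounds after trimming.
#' @param keep_no_adapter keep (flagged) reads in which no adapter was found,
#'   deduplicating them on insert alone.
#' @return list of class `trim_config`.
#' @export
trim_config <- function(adapter = "AACTGTAGGCACCATCAAT", umi_len = 12L,
                        max_adapter_error_rate = 0.1, phred_threshold = 10L,
                        min_len = 10L, max_len = 40L, keep_no_adapter = TRUE) {
  stopifnot(nzchar(adapter), !grepl("[^ACGT]", adapter))
  .chk_num(umi_len, "umi_len", 0)
  .chk_num(max_adapter_error_rate, "max_adapter_error_rate", 0, 0.5 - 1e-12)
  .chk_num(phred_threshold, "phred_threshold", 0)
  .chk_num(min_len, "min_len", 1)
  .chk_num(max_len, "max_len", min_len)
  .chk_flag(keep_no_adapter, "keep_no_adapter")
  structure(list(adapter = adapter, umi_len = as.integer(umi_len),
                 max_adapter_error_rate = max_adapter_error_rate,
                 phred_threshold = as.integer(phred_threshold),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 keep_no_adapter = keep_no_adapter),
            class = "trim_config")
}

#' Locate the 3' adapter in a read
#'
#' Returns the leftmost 0-based start index `i` such that the adapter, aligned
#' at `i` with substitutions only and truncation at the read's 3' end, has at
#' most `floor(max_error_rate * aligned_length)` mismatches with an aligned
#' length of at least `min_overlap` nt. `NA` when no such position exists.
#'
#' @param bases read sequence (single string).
#' @param adapter adapter sequence.
#' @param max_error_rate allowed substitution fraction.
#' @param min_overlap minimum aligned adapter length at the 3' end.
#' @return 0-based adapter start position, or `NA_integer_`.
#' @export
#' @examples
#' locate_adapter(paste0("ACGTACGTACGT", "AACTGTAGGCACCATCAAT"), "AACTGTAGGCACCATCAAT")
locate_adapter <- function(bases, adapter, max_error_rate = 0.1, min_overlap = 6L) {
  stopifnot(nzchar(adapter))
  L <- nchar(bases); A <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  rc <- strsplit(bases, "", fixed = TRUE)[[1]]
  ac <- strsplit(adapter, "", fixed = TRUE)[[1]]
  # fast path: exact full-length match cannot be preceded by a valid
  # approximate match at lower cost than scanning everything, but leftmost
  # semantics require scanning positions before it, so just bound the scan.
  exact <- regexpr(adapter, bases, fixed = TRUE)[1]
  last <- if (exact > 0L) exact - 1L else L - min_overlap
  for (i in 0:last) {
    al <- min(A, L - i)
    if (al < min_overlap) break
    mm <- sum(rc[(i + 1L):(i + al)] != ac[seq_len(al)])
    if (mm <= floor(max_error_rate * al)) return(i)
  }
  if (exact > 0L) return(exact - 1L)
  NA_integer_
}

#' Split reads into insert, UMI and status
#'
#' Applies [locate_adapter()] to every read. The insert is everything before
#' the adapter; the UMI is the `umi_len` bases immediately after the adapter,
#' recorded only when fully present (an incomplete UMI tail yields an empty
#' UMI). Reads without an adapter get status `no_adapter`, the whole read as
#' insert and an empty UMI.
#'
#' @param reads data.frame from [read_fastq()].
#' @param cfg a [trim_config()].
#' @return data.frame: `read_id`, `insert`, `qual` (insert qualities), `umi`,
#'   `status` (`ok` or `no_adapter`).
#' @export
extract_umi <- function(reads, cfg) {
  stopifnot(inherits(cfg, "trim_config"))
  n <- nrow(reads)
  pos <- vapply(reads$bases, locate_adapter, integer(1), adapter = cfg$adapter,
                max_error_rate = cfg$max_adapter_error_rate, USE.NAMES = FALSE)
  found <- !is.na(pos)
  insert <- ifelse(found, substr(reads$bases, 1L, ifelse(found, pos, 0L)), reads$bases)
  qual <- ifelse(found, substr(reads$qual, 1L, ifelse(found, pos, 0L)), reads$qual)
  A <- nchar(cfg$adapter)
  umi_start <- pos + A + 1L
  umi <- ifelse(found & nchar(reads$bases) >= pos + A + cfg$umi_len & cfg$umi_len > 0L,
                substr(reads$bases, umi_start, umi_start + cfg$umi_len - 1L), "")
  umi[is.na(umi)] <- ""
  data.frame(read_id = reads$read_id, insert = insert, qual = qual, umi = umi,
             status = ifelse(found, "ok", "no_adapter"), stringsAsFactors = FALSE)
}

#' BWA-style 3' quality trimming
#'
#' For phred scores `q[1..L]` and threshold `t`, compute the suffix sums
#' `s_j = sum_{k=j..L} (t - q[k])`; if the maximum suffix sum is positive the
#' read is cut before the smallest `j` attaining it (keeping bases
#' `1..j-1`), otherwise the read is unchanged. All-high-quality reads are
#' never shortened; an all-low-quality read trims to empty.
#'
#' @param bases insert sequence (single string).
#' @param qual phred+33 quality string of the same length.
#' @param threshold phred threshold `t`.
#' @return list with trimmed `bases` and `qual`.
#' @export
quality_trim_3prime <- function(bases, qual, threshold = 10L) {
  L <- nchar(bases)
  if (L == 0L) return(list(bases = bases, qual = qual))
  q <- utf8ToInt(qual) - 33L
  s <- rev(cumsum(rev(threshold - q)))
  j <- which(s == max(s))[1L]
  if (s[j] <= 0) return(list(bases = bases, qual = qual))
  list(bases = substr(bases, 1L, j - 1L), qual = substr(qual, 1L, j - 1L))
}

#' Length filter
#'
#' Keeps reads whose insert length lies in `[min_len, max_len]` (inclusive).
#'
#' @param len integer vector of insert lengths.
#' @param min_len,max_len inclusive bounds.
#' @return character vector: `"keep"`, `"too_short"` or `"too_long"`.
#' @export
length_filter <- function(len, min_len = 10L, max_len = 40L) {
  ifelse(len < min_len, "too_short", ifelse(len > max_len, "too_long", "keep"))
}

#' UMI deduplication
#'
#' Collapses processed reads on the key (insert sequence, UMI); reads with an
#' empty UMI collapse on insert alone. The first-encountered read of each key
#' is retained, so output order is deterministic. Idempotent.
#'
#' @param processed data.frame with `insert` and `umi` columns.
#' @return the deduplicated data.frame.
#' @export
deduplicate <- function(processed) {
  key <- paste(processed$insert, processed$umi, sep = "\x1f")
  processed[!duplicated(key), , drop = FALSE]
}

#' Prepare one sample: adapter/UMI, quality trim, length filter, deduplicate
#'
#' @param fastq_path path to the sample's FASTQ file (or a data.frame of reads
#'   already loaded with [read_fastq()]).
#' @param cfg a [trim_config()].
#' @return list with `reads` (deduplicated processed reads; columns `read_id`,
#'   `insert`, `qual`, `umi`, `status`) and `report`, a list of counters:
#'   `input_reads`, `adapter_found`, `no_adapter`, `dropped_no_adapter`,
#'   `discarded_short`, `discarded_long`, `kept`, `unique_after_dedup`.
#'   Counters satisfy `input_reads == kept + discarded_short + discarded_long
#'   + dropped_no_adapter` with `kept` the ok/no_adapter reads entering
#'   deduplication.
#' @export
prep_sample <- function(fastq_path, cfg = trim_config()) {
  raw <- if (is.data.frame(fastq_path)) fastq_path else read_fastq(fastq_path)
  n_in <- nrow(raw)
  pr <- extract_umi(raw, cfg)
  adapter_found <- sum(pr$status == "ok")
  no_adapter_n <- n_in - adapter_found
  if (!cfg$keep_no_adapter) {
    dropped_na <- sum(pr$status == "no_adapter")
    pr <- pr[pr$status != "no_adapter", , drop = FALSE]
  } else dropped_na <- 0L
  if (nrow(pr)) {
    trimmed <- mapply(quality_trim_3prime, pr$insert, pr$qual,
                      MoreArgs = list(threshold = cfg$phred_threshold),
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
    pr$insert <- vapply(trimmed, `[[`, character(1), "bases")
    pr$qual <- vapply(trimmed, `[[`, character(1), "qual")
  }
  verdict <- length_filter(nchar(pr$insert), cfg$min_len, cfg$max_len)
  short_n <- sum(verdict == "too_short"); long_n <- sum(verdict == "too_long")
  kept <- pr[verdict == "keep", , drop = FALSE]
  uniq <- deduplicate(kept)
  rownames(uniq) <- NULL
  list(reads = uniq,
       report = list(input_reads = n_in, adapter_found = adapter_found,
                     no_adapter = no_adapter_n, dropped_no_adapter = dropped_na,
                     discarded_short = short_n, discarded_long = long_n,
                     kept = nrow(kept), unique_after_dedup = nrow(uniq)))
}
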