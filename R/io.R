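# Readers/writers for the on-disk formats the pipeline touches.
# Conventions enforced throughout: phred+33 quality encoding, 0-based
# half-open genomic coordinates (BED native; SAM shifted by -1 at ingestion),
# U->T transliteration for RNA-space references.

#' Decode a phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors (one per input string), values in 0..93.
#' @export
#' @examples
#' decode_quals("II!")[[1]]  # 40 40 0
decode_quals <- function(qual) {
  lapply(qual, function(q) {
    v <- utf8ToInt(q) - 33L
    if (length(v) && (min(v) < 0L || max(v) > 93L))
      stop("quality string outside phred+33 range")
    v
  })
}

#' Encode integer phred scores as a phred+33 string
#' @param q integer vector of phred scores (0..93).
#' @return single character string.
#' @export
encode_quals <- function(q) {
  stopifnot(all(q >= 0L), all(q <= 93L))
  intToUtf8(as.integer(q) + 33L)
}

#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ with phred+33 qualities. A malformed record
#' aborts with the offending record number; a truncated file (line count not a
#' multiple of four) is an error.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `read_id`, `bases`, `qual` (phred+33
#'   string), one row per record, in file order. Use [decode_quals()] for
#'   integer scores.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ: ", path, " has ", n, " lines (not a multiple of 4)")
  if (n == 0L)
    return(data.frame(read_id = character(), bases = character(),
                      qual = character(), stringsAsFactors = FALSE))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]; seqs <- lines[idx + 1L]; plus <- lines[idx + 2L]; quals <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ record ", bad[1L], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("FASTQ record ", bad[1L], ": separator line does not start with '+'")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) stop("FASTQ record ", bad[1L],
                        ": sequence and quality lengths differ")
  ids <- substring(hdr, 2L)
  if (any(!nzchar(ids))) stop("FASTQ record ", which(!nzchar(ids))[1L], ": empty read id")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("FASTQ record ", which(grepl("[^ACGTN]", seqs))[1L],
         ": bases outside {A,C,G,T,N}")
  invisible(decode_quals(quals))  # validates phred+33 range
  data.frame(read_id = ids, bases = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param reads data.frame with `read_id`, `bases`, `qual` (as from
#'   [read_fastq()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases", "qual") %in% names(reads)))
  if (any(nchar(reads$bases) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  con <- file(path, "wb")  # binary mode keeps round trips byte-identical
  on.exit(close(con))
  if (nrow(reads))
    writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                               "+", reads$qual)), con, sep = "\n")
  invisible(path)
}

#' Read a mature-miRNA FASTA reference
#'
#' miRBase-style: the record name is the first whitespace-delimited token of
#' the header; RNA-space U (and lower case) are transliterated to DNA-space T.
#' Multi-line sequences are concatenated. Duplicate names and empty sequences
#' are errors.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `name`, `sequence`, `species` (the leading
#'   `xxx-` tag of the name, or NA), in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, ">")
  if (!length(lines) || !is_hdr[1L]) {
    if (!length(lines))
      return(data.frame(name = character(), sequence = character(),
                        species = character(), stringsAsFactors = FALSE))
    stop("FASTA must start with a '>' header: ", path)
  }
  grp <- cumsum(is_hdr)
  hdrs <- lines[is_hdr]
  names <- vapply(strsplit(substring(hdrs, 2L), "[ \t]+"), `[`, character(1), 1L)
  if (any(!nzchar(names) | is.na(names))) stop("empty FASTA header name")
  if (anyDuplicated(names))
    stop("duplicate FASTA record name: ", names[duplicated(names)][1L])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste, character(1), collapse = "")
  out <- character(length(hdrs)); names(out) <- as.character(seq_along(hdrs))
  out[names(seqs)] <- seqs
  out <- toupper(out)
  out <- chartr("U", "T", out)
  if (any(!nzchar(out))) stop("empty sequence under header: ", names[!nzchar(out)][1L])
  if (any(grepl("[^ACGTN]", out))) stop("non-nucleotide character in FASTA sequence")
  species <- ifelse(grepl("^[a-z]{3}-", names), sub("^([a-z]{3})-.*$", "\\1", names), NA_character_)
  data.frame(name = names, sequence = unname(out), species = species,
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#' @param x data.frame with `name` and `sequence` columns, or a named
#'   character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- data.frame(name = names(x), sequence = unname(x),
                                       stringsAsFactors = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(x))
    writeLines(as.vector(rbind(paste0(">", x$name), x$sequence)), con, sep = "\n")
  invisible(path)
}

#' Read genomic features from a BED6 file
#'
#' BED coordinates are 0-based half-open and are stored unchanged (the
#' package-wide convention). `start >= end` or a strand outside {+,-} aborts.
#'
#' @param path BED6 file path (6 tab-separated columns).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 6L))
    stop("BED6 line ", which(lengths(parts) != 6L)[1L], ": expected 6 columns")
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) stop("non-integer BED coordinates")
  if (any(start < 0L)) stop("negative BED start coordinate")
  if (any(start >= end))
    stop("BED line ", which(start >= end)[1L], ": start >= end")
  if (any(!m[, 6L] %in% c("+", "-")))
    stop("BED line ", which(!m[, 6L] %in% c("+", "-"))[1L], ": strand not in {+,-}")
  data.frame(chrom = m[, 1L], start = start, end = end, name = m[, 4L],
             score = suppressWarnings(as.numeric(m[, 5L])), strand = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Write genomic features as BED6
#' @param features data.frame as returned by [read_bed6()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(features, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(features)))
  score <- if ("score" %in% names(features)) features$score else 0
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(features))
    writeLines(paste(features$chrom, features$start, features$end,
                     features$name, score, features$strand, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Minimal SAM ingestion
#'
#' Reads plain SAM text, keeping primary mapped alignments only. Header lines
#' (`@`) are skipped; unmapped records (FLAG 0x4) and non-primary records
#' (FLAG 0x100/0x800) are skipped and counted in the report. FLAG 0x10 maps to
#' strand `-`; the 1-based POS is converted to the package's 0-based
#' convention. The aligned reference length is taken from the CIGAR
#' (M/D/N/=/X operations), falling back to the SEQ length.
#'
#' @param path SAM file path.
#' @return list with `alignments` (data.frame: `read_id`, `chrom`, `pos0`,
#'   `strand`, `aln_len`) and a `report` list counting `unmapped` and
#'   `secondary` records.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.frame(read_id = character(), chrom = character(),
                      pos0 = integer(), strand = character(),
                      aln_len = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(list(alignments = empty, report = list(unmapped = 0L, secondary = 0L)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L))
    stop("SAM record ", which(lengths(parts) < 11L)[1L], ": fewer than 11 fields")
  flag <- as.integer(vapply(parts, `[`, character(1), 2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, bitwOr(256L, 2048L)) != 0L
  keep <- !unmapped & !secondary
  cig_len <- function(cigar, seqs) {
    out <- integer(length(cigar))
    for (i in seq_along(cigar)) {
      if (cigar[i] == "*") { out[i] <- nchar(seqs[i]); next }
      ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
      n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
      op <- sub("^[0-9]+", "", ops)
      out[i] <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    }
    out
  }
  al <- if (any(keep)) {
    p <- parts[keep]
    data.frame(
      read_id = vapply(p, `[`, character(1), 1L),
      chrom = vapply(p, `[`, character(1), 3L),
      pos0 = as.integer(vapply(p, `[`, character(1), 4L)) - 1L,
      strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
      aln_len = cig_len(vapply(p, `[`, character(1), 6L),
                        vapply(p, `[`, character(1), 10L)),
      stringsAsFactors = FALSE)
  } else empty
  list(alignments = al,
       report = list(unmapped = sum(unmapped), secondary = sum(secondary)))
}

#' Write / read a count matrix as TSV
#'
#' Layout: header row of sample names, first column (`feature`) of feature
#' names, integer-like non-negative counts. The round trip is lossless.
#' Provenance matrices attached by [assemble_matrix()] are not serialised.
#'
#' @param matrix numeric matrix, features x samples, with dimnames.
#' @param path output path.
#' @return `path` invisibly (writer); a counts matrix (reader).
#' @export
write_counts_tsv <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (anyDuplicated(rownames(matrix))) stop("duplicate feature names")
  if (any(matrix < 0)) stop("negative counts")
  df <- data.frame(feature = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature") stop("first column must be 'feature'")
  if (anyDuplicated(df$feature)) stop("duplicate feature names")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(m < 0)) stop("negative counts")
  rownames(m) <- df$feature
  m
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `fastq_path`, `condition` and optionally
#' `subject_id`. Sample ids must be unique. Relative `fastq_path` entries are
#' resolved against the sheet's own directory.
#'
#' @param path sample sheet path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if ("fastq_path" %in% names(df)) {
    rel <- !is.na(df$fastq_path) & !grepl("^(/|[A-Za-z]:)", df$fastq_path)
    df$fastq_path[rel] <- file.path(dirname(path), df$fastq_path[rel])
  }
  df
}
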