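# Independent brute-force oracles, deliberately written from the definitions
# and kept free of any package internals.

# BH step-up by direct definition: q_(i) = min_{j>=i} p_(j) * m / j, capped
# at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# hypergeometric upper tail by point-mass enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# all-offsets ungapped alignment scan, both strands, best stratum
oracle_align <- function(read, genome, max_mm) {
  out <- NULL
  for (chrom in names(genome)) {
    gc <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else mirquant::revcomp(read)
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      L <- length(pc)
      if (length(gc) < L) next
      for (i in 0:(length(gc) - L)) {
        mm <- sum(gc[(i + 1):(i + L)] != pc)
        if (mm <= max_mm)
          out <- rbind(out, data.frame(chrom = chrom, pos0 = i, strand = strand,
                                       mismatches = mm, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    return(data.frame(chrom = character(), pos0 = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
  out <- out[order(out$chrom, out$pos0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# leftmost approximate adapter start by scanning every position
oracle_locate_adapter <- function(bases, adapter, rate, min_overlap = 6L) {
  L <- nchar(bases); A <- nchar(adapter)
  rc <- strsplit(bases, "", fixed = TRUE)[[1]]
  ac <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (i in 0:max(L - min_overlap, 0)) {
    al <- min(A, L - i)
    if (al < min_overlap) break
    if (sum(rc[(i + 1):(i + al)] != ac[seq_len(al)]) <= floor(rate * al)) return(i)
  }
  NA_integer_
}

# best 3' cut point by trying every suffix: cut before the smallest j whose
# suffix sum of (threshold - q) is maximal and positive
oracle_quality_trim <- function(q, thr) {
  L <- length(q)
  if (L == 0) return(0L)
  s <- vapply(seq_len(L), function(j) sum(thr - q[j:L]), numeric(1))
  j <- which(s == max(s))[1]
  if (s[j] > 0) j - 1L else L
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

two_group_coldata <- function(condition) {
  data.frame(condition = factor(condition, levels = c("reference", "treatment")))
}
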