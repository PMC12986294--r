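# Hypergeometric over-representation analysis (ORA) of pathways for the
# target genes of differentially expressed miRNAs, plus the shared-gene
# overlap structure used for pathway network displays.

#' Load a miRNA -> target-gene annotation table
#'
#' TSV with columns `mirna` and `gene` (one pair per row).
#'
#' @param path TSV path.
#' @return named list: miRNA -> character vector of target genes.
#' @export
read_mirna_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(df)))
    stop("targets table needs columns: mirna, gene")
  lapply(split(df$gene, df$mirna), unique)
}

#' Load a gene -> pathway annotation table
#'
#' TSV with columns `gene`, `pathway_id` and (optionally) `pathway_name`.
#'
#' @param path TSV path.
#' @return list: `pathway_genes` (pathway id -> gene set), `gene_to_pathways`
#'   (gene -> pathway ids), `pathway_names` (id -> label).
#' @export
read_gene_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway_id") %in% names(df)))
    stop("pathways table needs columns: gene, pathway_id")
  nm <- if ("pathway_name" %in% names(df)) {
    u <- !duplicated(df$pathway_id)
    setNames(df$pathway_name[u], df$pathway_id[u])
  } else setNames(unique(df$pathway_id), unique(df$pathway_id))
  list(pathway_genes = lapply(split(df$gene, df$pathway_id), unique),
       gene_to_pathways = lapply(split(df$pathway_id, df$gene), unique),
       pathway_names = nm)
}

#' Map differentially expressed miRNAs to their target-gene set
#'
#' @param mirnas character vector of miRNA names.
#' @param targets named list from [read_mirna_targets()].
#' @return list: `genes` (sorted union of target sets), `unannotated`
#'   (miRNAs absent from the annotation).
#' @export
map_mirnas_to_genes <- function(mirnas, targets) {
  if (!length(mirnas)) stop("empty miRNA input")
  known <- mirnas %in% names(targets)
  list(genes = sort(unique(unlist(targets[mirnas[known]], use.names = FALSE))),
       unannotated = mirnas[!known])
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Over-representation p-value: the probability that a sample of `n` genes
#' from a background of `N` (of which `K` belong to the pathway) contains at
#' least `k` pathway genes. Computed with the stable [stats::phyper()] tail.
#'
#' @param k overlap count; `K` pathway size; `n` query size; `N` background
#'   size. Vectorised.
#' @param K,n,N see above.
#' @return p-value(s).
#' @export
#' @examples
#' hypergeom_upper(4, 5, 4, 10)  # 5/210
hypergeom_upper <- function(k, K, n, N) {
  if (any(K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of pathways
#'
#' One-sided hypergeometric test per pathway with at least one query gene,
#' BH-adjusted across tested pathways, rows flagged significant below
#' `p_cutoff`, sorted by ascending p (ties broken by pathway id).
#'
#' @param query_genes character vector of query genes (e.g. from
#'   [map_mirnas_to_genes()]).
#' @param annotation list from [read_gene_pathways()].
#' @param background background gene universe; default all genes in the
#'   annotation. Must contain every query gene.
#' @param p_cutoff significance flag threshold (default 0.01).
#' @return data.frame: `pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`,
#'   `p_hyper`, `p_adj`, `significant`, `genes` (overlap, ";"-collapsed);
#'   the overlap gene sets are kept in the `"gene_sets"` attribute for
#'   [pathway_overlap()].
#' @export
run_ora <- function(query_genes, annotation, background = NULL, p_cutoff = 0.01) {
  query_genes <- unique(query_genes)
  if (is.null(background)) background <- names(annotation$gene_to_pathways)
  background <- unique(background)
  missing <- setdiff(query_genes, background)
  if (length(missing))
    stop("query gene(s) absent from background: ", paste(utils::head(missing, 3), collapse = ", "))
  N <- length(background); n <- length(query_genes)
  rows <- list(); sets <- list()
  for (pid in sort(names(annotation$pathway_genes), method = "radix")) {
    genes <- intersect(annotation$pathway_genes[[pid]], background)
    hit <- intersect(genes, query_genes)
    if (!length(hit)) next
    rows[[pid]] <- data.frame(
      pathway_id = pid,
      pathway_name = unname(annotation$pathway_names[pid]),
      k = length(hit), K = length(genes), n = n, N = N,
      p_hyper = hypergeom_upper(length(hit), length(genes), n, N),
      stringsAsFactors = FALSE)
    sets[[pid]] <- sort(hit)
  }
  if (!length(rows)) {
    out <- data.frame(pathway_id = character(), pathway_name = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p_hyper = numeric(), p_adj = numeric(),
                      significant = logical(), genes = character(),
                      stringsAsFactors = FALSE)
    attr(out, "gene_sets") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_hyper)
  out$significant <- out$p_hyper < p_cutoff
  out$genes <- vapply(sets[out$pathway_id], paste, character(1), collapse = ";")
  ord <- order(out$p_hyper, out$pathway_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_sets") <- sets[out$pathway_id]
  out
}

#' Pairwise shared-gene counts between enriched pathways
#'
#' @param rows a [run_ora()] result (its `"gene_sets"` attribute is used), or
#'   a named list of gene sets.
#' @return symmetric integer matrix of pairwise intersection sizes; the
#'   diagonal holds each pathway's overlap-set size.
#' @export
pathway_overlap <- function(rows) {
  sets <- if (is.data.frame(rows)) attr(rows, "gene_sets") else rows
  ids <- names(sets)
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  m
}
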