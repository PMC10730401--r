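# GO keyword gene-set construction, Fisher-exact overrepresentation with
# Bonferroni correction, and DEG threshold calls.

#' Build a gene set from GO term-name keyword matching
#'
#' Returns every gene annotated to at least one GO term whose name contains
#' `keyword` as a case-insensitive substring (so "autophag" collects both
#' "autophagy" and "macroautophagy"). This mirrors the common practice of
#' defining e.g. mitochondria-, inflammation- or autophagy-related gene sets
#' by the keywords "mitochondri", "inflamm" and "autophag". No GO-graph
#' propagation is performed: only the terms present in the table are matched.
#'
#' @param annotations Data.frame with columns `gene`, `go_id`, `go_name`,
#'   `ontology` (see [read_annotations()]).
#' @param keyword Non-empty keyword string.
#' @return Character vector of gene ids, named by the keyword via the
#'   `"set_name"` attribute. Empty result gives an empty set with a warning.
#' @export
#' @examples
#' ann <- data.frame(gene = c("Atg5", "Tnf", "Ndufa1"),
#'                   go_id = c("GO:1", "GO:2", "GO:3"),
#'                   go_name = c("autophagosome assembly",
#'                               "inflammatory response",
#'                               "mitochondrion organization"),
#'                   ontology = "BP")
#' filter_genes_by_keyword(ann, "autophag")
filter_genes_by_keyword <- function(annotations, keyword) {
  if (!is.character(keyword) || length(keyword) != 1L || !nzchar(keyword)) {
    stop("`keyword` must be a non-empty string", call. = FALSE)
  }
  need <- c("gene", "go_name")
  if (!all(need %in% names(annotations))) {
    stop("`annotations` must have columns gene and go_name", call. = FALSE)
  }
  # literal case-insensitive substring match (keywords are not regexes)
  hit <- grepl(tolower(keyword), tolower(annotations$go_name), fixed = TRUE)
  genes <- sort(unique(as.character(annotations$gene[hit])))
  if (length(genes) == 0L) {
    warning("keyword '", keyword, "' matched no GO term names", call. = FALSE)
  }
  structure(genes, set_name = keyword)
}

#' One-sided Fisher-exact overrepresentation of a DEG set in term sets
#'
#' For each term the 2x2 table (in-term & DEG, in-term & not DEG, DEG not in
#' term, remainder) is tested for enrichment: the p-value is the upper
#' hypergeometric tail `P[X >= overlap]` with `X ~ Hypergeom(N, K, n)` where
#' `N` is the universe size, `K` the term size and `n` the DEG count.
#' Bonferroni adjustment multiplies by the number of terms tested; a term is
#' significant when the adjusted value is at most 0.05.
#'
#' @param deg_set Character vector of differentially expressed genes. Genes
#'   outside `universe` are dropped with a warning.
#' @param term_sets Named list of character vectors; each is intersected with
#'   the universe.
#' @param universe Character vector of all assayed genes (non-empty).
#' @return Data.frame with columns `term`, `term_size`, `n_deg`, `overlap`,
#'   `p`, `p_bonferroni`, `significant`.
#' @export
fisher_overrepresentation <- function(deg_set, term_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("`universe` must be non-empty", call. = FALSE)
  }
  if (!is.list(term_sets) || length(term_sets) == 0L ||
      is.null(names(term_sets))) {
    stop("`term_sets` must be a non-empty named list", call. = FALSE)
  }
  deg <- unique(as.character(deg_set))
  outside <- setdiff(deg, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " DEG(s) outside the universe were dropped",
            call. = FALSE)
    deg <- intersect(deg, universe)
  }
  n_univ <- length(universe)
  n_deg <- length(deg)
  m <- length(term_sets)
  rows <- lapply(names(term_sets), function(nm) {
    term <- intersect(unique(as.character(term_sets[[nm]])), universe)
    k_term <- length(term)
    overlap <- length(intersect(term, deg))
    # upper tail P[X >= overlap]; overlap = 0 gives p = 1 exactly
    p <- stats::phyper(overlap - 1, k_term, n_univ - k_term, n_deg,
                       lower.tail = FALSE)
    data.frame(term = nm, term_size = k_term, n_deg = n_deg,
               overlap = overlap, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p * m)
  res$significant <- res$p_bonferroni <= 0.05
  rownames(res) <- NULL
  res
}

#' Flag differentially expressed genes by adjusted p-value
#'
#' A gene is a DEG when its BH-adjusted p-value is below `threshold`
#' (default 0.1, the conventional FDR cut for DESeq2-style tables). Missing
#' `padj` (DESeq2's independent-filtering NA) means not a DEG. Direction is
#' the sign of the log2 fold change.
#'
#' @param de_table Data.frame with columns `gene`, `log2fc`, `padj`.
#' @param threshold FDR threshold (default 0.1).
#' @return Data.frame with columns `gene`, `padj`, `is_deg`, `direction`.
#' @export
identify_degs <- function(de_table, threshold = 0.1) {
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(de_table))) {
    stop("`de_table` must have columns gene, log2fc, padj", call. = FALSE)
  }
  stop_unless_scalar_number(threshold, "threshold", nonnegative = TRUE)
  padj <- as.numeric(de_table$padj)
  lfc <- as.numeric(de_table$log2fc)
  is_deg <- !is.na(padj) & padj < threshold
  direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  data.frame(gene = as.character(de_table$gene), padj = padj,
             is_deg = is_deg, direction = direction,
             stringsAsFactors = FALSE)
}
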