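# Running-sum gene-set enrichment: the Maximum Estimate Score (MES).
#
# Genes are ranked by decreasing log2 fold change. Each rank contributes a
# step X_i to a running sum, with one step value for pathway members and
# another for non-members, scaled by the set size G and the universe size N.
# The MES is an extremum of the running sum; its significance comes from a
# permutation null over membership positions; per-contrast families are
# corrected by Benjamini-Hochberg; p-values are converted to signed Z scores
# for heatmap display.
#
# Two increment conventions are supported:
#   * "as_printed": members get -sqrt(G/(N-G)), non-members +sqrt((N-G)/G).
#   * "balanced" (default): the signs swapped, so members get
#     +sqrt((N-G)/G) and non-members -sqrt(G/(N-G)); the increments then sum
#     to zero and a positive MES corresponds to up-enrichment, matching the
#     stated direction semantics. Only the balanced signed-extremum form can
#     produce the negative scores that encode down-regulated pathways.

#' Rank genes by decreasing log2 fold change
#'
#' Ties are broken by gene id in C-locale lexicographic order so the ranking
#' is deterministic across runs and platforms.
#'
#' @param de_table Data.frame with columns `gene` and `log2fc` (extra columns
#'   are ignored). Gene ids must be unique and log2fc finite.
#' @return An object of class `ranked_genes`: a list with `gene`, `log2fc`
#'   (both ordered) and `n`.
#' @export
#' @examples
#' rank_genes(data.frame(gene = c("a", "b", "c"), log2fc = c(1, -1, 2)))
rank_genes <- function(de_table) {
  if (!is.data.frame(de_table) || nrow(de_table) == 0L) {
    stop("`de_table` must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("gene", "log2fc") %in% names(de_table))) {
    stop("`de_table` must have columns gene and log2fc", call. = FALSE)
  }
  gene <- as.character(de_table$gene)
  lfc <- as.numeric(de_table$log2fc)
  if (anyDuplicated(gene)) {
    stop("duplicate gene ids in DE table", call. = FALSE)
  }
  if (any(!is.finite(lfc))) {
    stop("log2fc contains non-finite values (NA/NaN/Inf)", call. = FALSE)
  }
  if (length(gene) < 2L) {
    stop("need at least 2 genes to rank", call. = FALSE)
  }
  o <- order(-lfc, gene, method = "radix")
  structure(list(gene = gene[o], log2fc = lfc[o], n = length(gene)),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat("ranked gene list:", x$n, "genes; log2fc range [",
      format(min(x$log2fc)), ",", format(max(x$log2fc)), "]\n")
  invisible(x)
}

# Member / non-member step values for a given (N, G) and convention.
increment_values <- function(n, g, convention = c("balanced", "as_printed")) {
  convention <- match.arg(convention)
  if (g <= 0L || g >= n) {
    stop("degenerate gene set: need 0 < G < N after universe intersection ",
         "(G = ", g, ", N = ", n, ")", call. = FALSE)
  }
  printed_member <- -sqrt(g / (n - g))
  printed_nonmember <- sqrt((n - g) / g)
  if (convention == "as_printed") {
    list(member = printed_member, nonmember = printed_nonmember)
  } else {
    list(member = printed_nonmember, nonmember = printed_member)
  }
}

#' Per-rank increment vector for a gene set
#'
#' @param ranked A `ranked_genes` object from [rank_genes()].
#' @param gene_set Character vector of member gene ids; intersected with the
#'   ranked universe before use.
#' @param convention `"balanced"` (default; increments sum to zero, members
#'   positive) or `"as_printed"` (members negative).
#' @return Numeric vector of length N with attributes `member_positions`,
#'   `G`, `N` and `convention`.
#' @export
mes_increments <- function(ranked, gene_set,
                           convention = c("balanced", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ranked, "ranked_genes"))
  member <- ranked$gene %in% gene_set
  g <- sum(member)
  vals <- increment_values(ranked$n, g, convention)
  x <- ifelse(member, vals$member, vals$nonmember)
  structure(x,
            member_positions = which(member), G = g, N = ranked$n,
            convention = convention)
}

#' Running-sum extremum (MES) of an increment vector
#'
#' @param increments Numeric increment vector (e.g. from [mes_increments()]).
#' @param mode `"signed_extremum"` (default): the partial sum of largest
#'   absolute value, ties between +v and -v resolved toward +v. This is what
#'   lets a pathway whose members sit at the bottom of the ranking score
#'   negatively. `"literal_max"`: the plain maximum partial sum.
#' @return A single MES value.
#' @export
#' @examples
#' ranked <- rank_genes(data.frame(gene = sprintf("g%02d", 1:10),
#'                                 log2fc = 10:1))
#' inc <- mes_increments(ranked, c("g01", "g02"))
#' mes_score(inc) # members at the top: +4
mes_score <- function(increments, mode = c("signed_extremum", "literal_max")) {
  mode <- match.arg(mode)
  if (length(increments) == 0L || any(!is.finite(increments))) {
    stop("`increments` must be non-empty and finite", call. = FALSE)
  }
  s <- cumsum(increments)
  smax <- max(s)
  if (mode == "literal_max") {
    return(smax)
  }
  smin <- min(s)
  pick_signed_extremum(smax, smin)
}

# Positive value wins exact-magnitude ties; the comparison carries a small
# relative tolerance so float rounding cannot flip the tie-break between
# algebraically equivalent computation routes.
pick_signed_extremum <- function(smax, smin) {
  tol <- 1e-9 * (abs(smax) + abs(smin) + 1)
  ifelse(abs(smax) >= abs(smin) - tol, smax, smin)
}

# MES from sorted member positions only (O(G) instead of O(N)).
#
# Between member positions the running sum is linear with slope x_nonmember,
# so its extrema over all N prefixes occur at member positions, just before
# member positions, at rank 1, or at rank N. Spurious candidates evaluate to
# 0 (= S_0) which can never dominate a nonzero extremum in absolute value.
mes_from_positions <- function(pos, n, xm, xn,
                               mode = c("signed_extremum", "literal_max")) {
  mode <- match.arg(mode)
  g <- length(pos)
  i <- seq_len(g)
  s_at <- i * xm + (pos - i) * xn               # prefix ending at pos[i]
  s_before <- (i - 1) * xm + (pos - i) * xn     # prefix ending at pos[i]-1
  s_first <- xn                                 # prefix ending at rank 1
  if (pos[1L] == 1L) {
    # no prefix ends before the first member; drop the degenerate candidates
    s_before[1L] <- s_at[1L]
    s_first <- s_at[1L]
  }
  s_last <- g * xm + (n - g) * xn               # prefix ending at rank N
  cand <- c(s_at, s_before, s_first, s_last)
  smax <- max(cand)
  if (mode == "literal_max") {
    return(smax)
  }
  smin <- min(cand)
  pick_signed_extremum(smax, smin)
}

# Vectorised MES for a G x B matrix of sorted member-position columns.
mes_from_position_matrix <- function(pos, n, xm, xn,
                                     mode = c("signed_extremum",
                                              "literal_max")) {
  mode <- match.arg(mode)
  g <- nrow(pos)
  i <- seq_len(g)
  s_at <- i * xm + (pos - i) * xn
  s_before <- (i - 1) * xm + (pos - i) * xn
  first_is_one <- pos[1L, ] == 1L
  s_before[1L, first_is_one] <- s_at[1L, first_is_one]
  s_first <- ifelse(first_is_one, s_at[1L, ], xn)
  s_last <- rep(g * xm + (n - g) * xn, ncol(pos))
  m <- rbind(s_at, s_before, s_first, s_last)
  smax <- Reduce(pmax, asplit(m, 1L))
  if (mode == "literal_max") {
    return(smax)
  }
  smin <- Reduce(pmin, asplit(m, 1L))
  pick_signed_extremum(smax, smin)
}

# Draw B null |membership patterns| and return their MES values. Sampling a
# uniform set of G positions out of N is equivalent to permuting the ranking.
sample_null_mes <- function(n, g, xm, xn, n_perm,
                            mode = c("signed_extremum", "literal_max")) {
  mode <- match.arg(mode)
  pos <- matrix(0L, nrow = g, ncol = n_perm)
  for (b in seq_len(n_perm)) {
    pos[, b] <- sort.int(sample.int(n, g))
  }
  mes_from_position_matrix(pos, n, xm, xn, mode)
}

# Exhaustive null: MES of every C(N, G) membership pattern.
exhaustive_null_mes <- function(n, g, xm, xn,
                                mode = c("signed_extremum", "literal_max")) {
  mode <- match.arg(mode)
  pos <- utils::combn(n, g)
  mes_from_position_matrix(pos, n, xm, xn, mode)
}

#' Permutation test for an MES value
#'
#' The null hypothesis is that the pathway is not enriched in the ranking:
#' member positions are uniformly random. When the number of membership
#' patterns `choose(N, G)` is at most `exhaustive_threshold` the null is
#' enumerated exactly and the p-value is the exact proportion of patterns
#' with `|MES| >=` the observed `|MES|`; otherwise `n_perm` patterns are
#' sampled and the add-one estimator `p = (1 + hits) / (n_perm + 1)` is used
#' (so sampled p-values are floored at `1/(n_perm + 1)` and never zero).
#'
#' @param ranked A `ranked_genes` object.
#' @param gene_set Character vector of member gene ids.
#' @param n_perm Number of sampled permutations (default 1000, the number
#'   used in the source study).
#' @param seed Optional integer seed; `NULL` draws from the current stream.
#' @param convention,mode Passed to [mes_increments()] and [mes_score()].
#' @param exhaustive_threshold Enumerate exactly when `choose(N, G)` is at
#'   most this value (default 10000).
#' @return A list of class `mes_test`: `mes`, `p`, `direction` (`"up"`,
#'   `"down"` or `"none"`), `G`, `N`, `exact` (logical), `n_perm`, and
#'   `null_abs_q` (quantiles of the null |MES| distribution).
#' @export
mes_perm_test <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                          convention = c("balanced", "as_printed"),
                          mode = c("signed_extremum", "literal_max"),
                          exhaustive_threshold = 10000) {
  convention <- match.arg(convention)
  mode <- match.arg(mode)
  stopifnot(inherits(ranked, "ranked_genes"))
  stop_unless_scalar_number(n_perm, "n_perm", positive = TRUE)
  n <- ranked$n
  member <- ranked$gene %in% gene_set
  g <- sum(member)
  vals <- increment_values(n, g, convention) # errors on degenerate sets
  obs <- mes_from_positions(which(member), n, vals$member, vals$nonmember,
                            mode)
  tol <- 1e-12
  exact <- choose(n, g) <= exhaustive_threshold
  null_mes <- with_seed(seed, {
    if (exact) {
      exhaustive_null_mes(n, g, vals$member, vals$nonmember, mode)
    } else {
      sample_null_mes(n, g, vals$member, vals$nonmember, n_perm, mode)
    }
  })
  hits <- sum(abs(null_mes) >= abs(obs) - tol)
  p <- if (exact) hits / length(null_mes) else (1 + hits) / (n_perm + 1)
  direction <- if (obs > 0) "up" else if (obs < 0) "down" else "none"
  structure(list(
    mes = obs, p = p, direction = direction, G = g, N = n,
    exact = exact, n_perm = if (exact) length(null_mes) else n_perm,
    null_abs_q = stats::quantile(abs(null_mes), c(0.5, 0.95, 0.99))
  ), class = "mes_test")
}

#' @export
print.mes_test <- function(x, ...) {
  cat(sprintf("MES = %.4f (%s), p = %.4g [%s null, %d patterns], G = %d/%d\n",
              x$mes, x$direction, x$p,
              if (x$exact) "exhaustive" else "sampled", x$n_perm, x$G, x$N))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; order-preserving.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Significance call combining nominal and adjusted thresholds
#'
#' A pathway is called significant when its nominal permutation p-value is
#' below `alpha_nominal` *and* its BH-adjusted value is below `fdr_cut`
#' (defaults 0.05 and 0.1).
#'
#' @param p,q Numeric vectors of nominal and BH-adjusted p-values.
#' @param alpha_nominal,fdr_cut Thresholds.
#' @return Logical vector.
#' @export
call_significance <- function(p, q, alpha_nominal = 0.05, fdr_cut = 0.1) {
  stopifnot(length(p) == length(q))
  p < alpha_nominal & q < fdr_cut
}

#' Convert a two-sided p-value and direction to a signed Z score
#'
#' `Z = sign(direction) * qnorm(1 - p/2)`; `p = 1` maps to `Z = 0`, and
#' `p = 0.05` maps to `|Z| = 1.96`, the conventional two-sided 5% critical
#' value used to threshold enrichment heatmaps.
#'
#' @param p P-values in (0, 1].
#' @param direction `"up"`/`"down"`/`"none"`, or numeric signs.
#' @return Signed Z scores.
#' @export
pvalue_to_z <- function(p, direction) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.character(direction)) {
    sgn <- ifelse(direction == "up", 1,
                  ifelse(direction == "down", -1, 0))
  } else {
    sgn <- sign(as.numeric(direction))
  }
  if (length(sgn) == 1L) sgn <- rep(sgn, length(p))
  stopifnot(length(sgn) == length(p))
  sgn * stats::qnorm(1 - p / 2)
}

#' Run the full enrichment procedure for one contrast
#'
#' rank -> increments -> MES -> permutation p -> BH over the tested
#' collection -> significance call -> signed Z. Sets are intersected with the
#' ranked universe first; sets with fewer than `min_size` members (or more
#' than `N - min_size`) are skipped with a message since their increments are
#' degenerate or near-degenerate.
#'
#' @param de_table Data.frame with columns `gene`, `log2fc`.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm,seed,convention,mode,exhaustive_threshold Passed to
#'   [mes_perm_test()]; all sets draw from one seeded stream.
#' @param min_size Minimum (and `N -` maximum) post-intersection set size.
#' @param alpha_nominal,fdr_cut Significance thresholds (defaults 0.05, 0.1).
#' @return A data.frame of class `enrichment_results` with one row per tested
#'   pathway: `pathway`, `G`, `mes`, `p`, `q`, `z`, `direction`,
#'   `significant`. Skipped sets are recorded in the `"skipped"` attribute.
#' @export
run_enrichment <- function(de_table, gene_sets, n_perm = 1000, seed = NULL,
                           convention = c("balanced", "as_printed"),
                           mode = c("signed_extremum", "literal_max"),
                           min_size = 5, alpha_nominal = 0.05, fdr_cut = 0.1,
                           exhaustive_threshold = 10000) {
  convention <- match.arg(convention)
  mode <- match.arg(mode)
  if (!is.list(gene_sets) || length(gene_sets) == 0L ||
      is.null(names(gene_sets))) {
    stop("`gene_sets` must be a non-empty named list", call. = FALSE)
  }
  ranked <- rank_genes(de_table)
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene %in% s), 1L)
  keep <- sizes >= min_size & sizes <= ranked$n - min_size
  if (any(!keep)) {
    message("skipping ", sum(!keep), " gene set(s) with G < ", min_size,
            " or G > N - ", min_size, ": ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  }
  if (!any(keep)) {
    stop("no gene sets left after size filtering", call. = FALSE)
  }
  tested <- gene_sets[keep]
  tests <- with_seed(seed, lapply(tested, function(s) {
    mes_perm_test(ranked, s, n_perm = n_perm, seed = NULL,
                  convention = convention, mode = mode,
                  exhaustive_threshold = exhaustive_threshold)
  }))
  res <- data.frame(
    pathway = names(tested),
    G = vapply(tests, `[[`, 1L, "G"),
    mes = vapply(tests, `[[`, 1, "mes"),
    p = vapply(tests, `[[`, 1, "p"),
    direction = vapply(tests, `[[`, "", "direction"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$q <- bh_fdr(res$p)
  res$significant <- call_significance(res$p, res$q, alpha_nominal, fdr_cut)
  res$z <- pvalue_to_z(res$p, res$direction)
  res <- res[c("pathway", "G", "mes", "p", "q", "z", "direction",
               "significant")]
  attr(res, "skipped") <- names(gene_sets)[!keep]
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Run enrichment across several contrasts
#'
#' Each contrast is a separate BH family (FDR is controlled per contrast, not
#' pooled). Per-contrast seeds are derived from `seed` by fixed offsets so
#' results are reproducible yet contrasts are independent.
#'
#' @param de_tables Named list of DE data.frames, one per contrast.
#' @param gene_sets Named list of gene sets.
#' @param seed Base seed; contrast k uses `seed + k - 1`.
#' @param ... Passed to [run_enrichment()].
#' @return A data.frame with a `contrast` column prepended, rows from all
#'   contrasts stacked.
#' @export
enrich_contrasts <- function(de_tables, gene_sets, seed = NULL, ...) {
  if (!is.list(de_tables) || length(de_tables) == 0L ||
      is.null(names(de_tables))) {
    stop("`de_tables` must be a non-empty named list", call. = FALSE)
  }
  out <- lapply(seq_along(de_tables), function(k) {
    res <- run_enrichment(de_tables[[k]], gene_sets,
                          seed = if (is.null(seed)) NULL else seed + k - 1,
                          ...)
    cbind(contrast = names(de_tables)[k], as.data.frame(res),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pathways-by-contrasts Z matrix with significance mask
#'
#' Cells hold the signed Z score (0 where a pathway was not tested in a
#' contrast); the mask marks cells with `|Z| >= z_threshold` *and* a positive
#' significance call. Non-significant cells keep their Z value — the
#' threshold describes display gating, not censoring.
#'
#' @param results Stacked results from [enrich_contrasts()] (needs columns
#'   `contrast`, `pathway`, `z`, `significant`).
#' @param z_threshold Display threshold (default 1.96, the two-sided 5%
#'   normal critical value).
#' @return List with numeric matrix `z` and logical matrix `mask`.
#' @export
z_matrix <- function(results, z_threshold = 1.96) {
  need <- c("contrast", "pathway", "z", "significant")
  if (!all(need %in% names(results))) {
    stop("`results` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pathways <- unique(results$pathway)
  contrasts <- unique(results$contrast)
  z <- matrix(0, nrow = length(pathways), ncol = length(contrasts),
              dimnames = list(pathways, contrasts))
  mask <- matrix(FALSE, nrow = length(pathways), ncol = length(contrasts),
                 dimnames = list(pathways, contrasts))
  idx <- cbind(match(results$pathway, pathways),
               match(results$contrast, contrasts))
  z[idx] <- results$z
  mask[idx] <- abs(results$z) >= z_threshold & results$significant
  list(z = z, mask = mask)
}
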