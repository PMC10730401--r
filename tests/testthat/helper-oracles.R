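# Independent oracles used to freeze expected values. Each is written the
# dumbest possible way (explicit loops / enumeration) so it shares no code
# path with the implementation it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# MES oracle: explicit prefix sums from the full increment vector.
oracle_mes <- function(increments, mode = "signed_extremum") {
  s <- 0
  best_max <- -Inf
  best_min <- Inf
  for (x in increments) {
    s <- s + x
    if (s > best_max) best_max <- s
    if (s < best_min) best_min <- s
  }
  if (mode == "literal_max") {
    return(best_max)
  }
  # positive wins ties, with the same relative tolerance the package
  # documents for its tie-break
  tol <- 1e-9 * (abs(best_max) + abs(best_min) + 1)
  if (abs(best_max) >= abs(best_min) - tol) best_max else best_min
}

# Increment vector oracle from first principles.
oracle_increments <- function(n, g, member_positions,
                              convention = "balanced") {
  xm_printed <- -sqrt(g / (n - g))
  xn_printed <- sqrt((n - g) / g)
  if (convention == "as_printed") {
    xm <- xm_printed
    xn <- xn_printed
  } else {
    xm <- xn_printed
    xn <- xm_printed
  }
  x <- rep(xn, n)
  x[member_positions] <- xm
  x
}

# BH oracle: literal "min over the tail" definition, double loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) ps[j] * m / j, 1)
    q[i] <- min(1, min(tail_vals))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper-tail oracle: explicit sum of choose() products.
oracle_hyper_tail <- function(n_univ, k_term, n_deg, overlap) {
  ks <- overlap:min(k_term, n_deg)
  sum(choose(k_term, ks) * choose(n_univ - k_term, n_deg - ks)) /
    choose(n_univ, n_deg)
}

# Mann-Whitney oracle: enumerate every labeling, recompute U by pair counts.
oracle_mwu <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  u_of <- function(idx) {
    xa <- pooled[idx]
    xb <- pooled[-idx]
    u <- 0
    for (x in xa) {
      for (y in xb) {
        u <- u + (x > y) + 0.5 * (x == y)
      }
    }
    u
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * (n - na) / 2
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2, u_of)
  list(u = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Tiny DE table builder for enrichment tests.
make_de <- function(lfc, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_along(lfc))
  data.frame(gene = genes, log2fc = lfc,
             pvalue = rep(0.5, length(lfc)), padj = rep(0.5, length(lfc)),
             stringsAsFactors = FALSE)
}

# Ranked list whose order is simply gene 1..n (log2fc strictly decreasing).
make_ranked <- function(n) {
  rank_genes(make_de(seq(n, 1)))
}
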