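test_that("rank_genes sorts decreasingly with deterministic tie-breaks", {
  r <- rank_genes(make_de(c(1, -1, 2), genes = c("a", "b", "c")))
  expect_equal(r$gene, c("c", "a", "b"))
  expect_equal(r$log2fc, c(2, 1, -1))
  expect_equal(r$n, 3L)

  # equal log2fc -> lexicographic gene order, stable across reruns
  tied <- make_de(c(1, 1, 0), genes = c("zeta", "alpha", "mid"))
  r1 <- rank_genes(tied)
  r2 <- rank_genes(tied[c(2, 1, 3), ])
  expect_equal(r1$gene, c("alpha", "zeta", "mid"))
  expect_identical(r1, r2)

  expect_error(rank_genes(make_de(c(1, NaN))), "non-finite")
  expect_error(rank_genes(make_de(c(1, NA))), "non-finite")
  expect_error(rank_genes(make_de(c(1, 2), genes = c("a", "a"))),
               "duplicate")
  expect_error(rank_genes(data.frame()), "non-empty")
})

test_that("increment values match the printed formulas and conventions", {
  ranked <- make_ranked(10)
  members <- ranked$gene[1:2]

  printed <- mes_increments(ranked, members, convention = "as_printed")
  expect_equal(unique(printed[1:2]), -0.5)
  expect_equal(unique(printed[3:10]), 2.0)

  balanced <- mes_increments(ranked, members, convention = "balanced")
  expect_equal(unique(balanced[1:2]), 2.0)
  expect_equal(unique(balanced[3:10]), -0.5)
  expect_equal(sum(balanced), 0)

  # N=4, G=2 balanced: +/- 1, zero total
  r4 <- make_ranked(4)
  inc4 <- mes_increments(r4, r4$gene[1:2], convention = "balanced")
  expect_equal(as.numeric(inc4), c(1, 1, -1, -1),
               ignore_attr = TRUE)
  expect_equal(sum(inc4), 0)

  # degenerate sets error
  expect_error(mes_increments(ranked, character(0)), "degenerate")
  expect_error(mes_increments(ranked, ranked$gene), "degenerate")
})

test_that("increment sums obey both conventions for random (N, G)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:400, 1)
    g <- sample(seq_len(n - 1), 1)
    ranked <- make_ranked(n)
    members <- sample(ranked$gene, g)
    bal <- mes_increments(ranked, members, convention = "balanced")
    expect_lt(abs(sum(bal)), 1e-9 * n)
    pr <- mes_increments(ranked, members, convention = "as_printed")
    expect_equal(sum(pr),
                 (n - g)^1.5 / sqrt(g) - g^1.5 / sqrt(n - g),
                 tolerance = 1e-9)
  }
})

test_that("mes_score returns the signed running-sum extremum", {
  ranked <- make_ranked(10)
  top <- mes_increments(ranked, ranked$gene[1:2])
  expect_equal(mes_score(top), 4.0)
  bottom <- mes_increments(ranked, ranked$gene[9:10])
  expect_equal(mes_score(bottom), -4.0)
  # literal max of the bottom pattern is 0 (the final prefix)
  expect_equal(mes_score(bottom, mode = "literal_max"), 0)

  # reversing the ranking negates the MES (no |max| == |min| tie here)
  expect_equal(mes_score(rev(as.numeric(top))), -4.0)

  expect_error(mes_score(numeric(0)), "non-empty")
  expect_error(mes_score(c(1, NA)), "finite")
})

test_that("position-based MES agrees with the full-vector oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    g <- sample(seq_len(n - 1), 1)
    pos <- sort(sample.int(n, g))
    for (conv in c("balanced", "as_printed")) {
      vals <- mespath:::increment_values(n, g, conv)
      inc <- oracle_increments(n, g, pos, conv)
      for (mode in c("signed_extremum", "literal_max")) {
        expect_equal(
          mespath:::mes_from_positions(pos, n, vals$member, vals$nonmember,
                                       mode),
          oracle_mes(inc, mode),
          tolerance = 1e-12,
          label = sprintf("n=%d g=%d conv=%s mode=%s", n, g, conv, mode))
      }
    }
  }
})

test_that("MES depends only on ranks, not log2fc magnitudes", {
  set.seed(11)
  lfc <- rnorm(60)
  de1 <- make_de(lfc)
  de2 <- make_de(2 * lfc + 3) # strictly increasing transform
  de3 <- make_de(sign(lfc) * abs(lfc)^3 + exp(lfc) * 1e-3)
  sets <- list(s1 = de1$gene[seq(1, 60, by = 4)],
               s2 = de1$gene[31:45])
  r1 <- run_enrichment(de1, sets, n_perm = 200, seed = 99)
  r2 <- run_enrichment(de2, sets, n_perm = 200, seed = 99)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_enrichment(de3, sets, n_perm = 200, seed = 99)
  expect_equal(r1$mes, r3$mes)
})

test_that("exhaustive permutation p matches hand enumeration (N=4, G=2)", {
  r4 <- make_ranked(4)
  t_top <- mes_perm_test(r4, r4$gene[1:2], seed = 1)
  expect_true(t_top$exact)
  expect_equal(t_top$p, 2 / 6)
  expect_equal(t_top$mes, 2)
  expect_equal(t_top$direction, "up")

  t_bottom <- mes_perm_test(r4, r4$gene[3:4], seed = 1)
  expect_equal(t_bottom$p, 2 / 6)
  expect_equal(t_bottom$direction, "down")
})

test_that("sampled permutation p is floored at 1/(n_perm+1)", {
  ranked <- make_ranked(60)
  t <- mes_perm_test(ranked, ranked$gene[1:10], n_perm = 1000, seed = 3,
                     exhaustive_threshold = 1)
  expect_false(t$exact)
  expect_gte(t$p, 1 / 1001)
  expect_equal(t$p, 1 / 1001) # members solidly on top -> never beaten
})

test_that("sampled p converges to the exhaustive p", {
  # moderate case where p is not at the floor
  ranked <- make_ranked(8)
  members <- ranked$gene[c(2, 5, 6)]
  exact <- mes_perm_test(ranked, members, seed = 1)
  expect_true(exact$exact)
  sampled <- mes_perm_test(ranked, members, n_perm = 50000, seed = 2,
                           exhaustive_threshold = 1)
  se <- sqrt(exact$p * (1 - exact$p) / 50000)
  expect_lt(abs(sampled$p - exact$p), 3 * se + 1e-4)
})

test_that("bh_fdr matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("significance needs both nominal p < 0.05 and q < 0.1", {
  expect_true(call_significance(0.01, 0.05))
  expect_false(call_significance(0.01, 0.2))
  expect_false(call_significance(0.06, 0.05))
  expect_equal(call_significance(c(0.01, 0.01, 0.06), c(0.05, 0.2, 0.05)),
               c(TRUE, FALSE, FALSE))
})

test_that("pvalue_to_z is the signed two-sided normal quantile", {
  expect_equal(round(pvalue_to_z(0.05, "up"), 2), 1.96)
  expect_equal(pvalue_to_z(1, "down"), 0)
  expect_equal(round(pvalue_to_z(0.01, "down"), 4), -2.5758)
  expect_error(pvalue_to_z(0, "up"), "\\(0, 1\\]")

  # round trip: two-sided p of Z maps back to Z
  z <- seq(0.1, 5, by = 0.3)
  p <- 2 * pnorm(-z)
  expect_equal(pvalue_to_z(p, "up"), z, tolerance = 1e-9)
  expect_equal(pvalue_to_z(p, "down"), -z, tolerance = 1e-9)
})

test_that("run_enrichment recovers a planted set with the right sign", {
  cfg_up <- de_sim_config(2000, null_sd = 0.5, planted_sets = list(
    list(name = "planted_up", size = 40, delta = 1, direction = "up")),
    seed = 21)
  sim <- simulate_de_table(cfg_up)
  sets <- list(planted_up = sim$truth$sets$planted_up$members,
               decoy = sim$table$gene[1001:1040])
  res <- run_enrichment(sim$table, sets, n_perm = 499, seed = 4)
  row <- res[res$pathway == "planted_up", ]
  expect_true(row$significant)
  expect_gt(row$mes, 0)
  expect_gt(row$z, 0)
  expect_equal(row$direction, "up")

  cfg_down <- de_sim_config(2000, null_sd = 0.5, planted_sets = list(
    list(name = "planted_down", size = 40, delta = 1, direction = "down")),
    seed = 22)
  sim2 <- simulate_de_table(cfg_down)
  res2 <- run_enrichment(
    sim2$table,
    list(planted_down = sim2$truth$sets$planted_down$members),
    n_perm = 499, seed = 4)
  expect_lt(res2$mes[1], 0)
  expect_lt(res2$z[1], 0)
})

test_that("run_enrichment filters degenerate sets and errors when all go", {
  de <- make_de(seq(50, 1))
  small <- list(tiny = de$gene[1:2])
  expect_error(suppressMessages(run_enrichment(de, small)), "no gene sets")
  mixed <- list(tiny = de$gene[1:2], ok = de$gene[1:10])
  expect_message(res <- run_enrichment(de, mixed, n_perm = 99, seed = 1),
                 "skipping")
  expect_equal(res$pathway, "ok")
  expect_equal(attr(res, "skipped"), "tiny")
})

test_that("enrich_contrasts keeps per-contrast BH families and seeds", {
  de_a <- make_de(seq(30, 1))
  de_b <- make_de(seq(-1, -30))
  sets <- list(s1 = de_a$gene[1:8], s2 = de_a$gene[15:24])
  res <- enrich_contrasts(list(A = de_a, B = de_b), sets,
                          seed = 10, n_perm = 99)
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$contrast), c("A", "B"))
  # q within each contrast is BH of that contrast's p only
  for (ct in c("A", "B")) {
    sub <- res[res$contrast == ct, ]
    expect_equal(sub$q, bh_fdr(sub$p))
  }
  # deterministic rerun
  res2 <- enrich_contrasts(list(A = de_a, B = de_b), sets,
                           seed = 10, n_perm = 99)
  expect_identical(res, res2)
})

test_that("z_matrix lays out pathways x contrasts with a gated mask", {
  res <- data.frame(contrast = "c1", pathway = "p1", z = 2.5,
                    significant = TRUE)
  zm <- z_matrix(res)
  expect_equal(dim(zm$z), c(1L, 1L))
  expect_equal(zm$z[1, 1], 2.5)
  expect_true(zm$mask[1, 1])

  # |z| below threshold -> masked out but value kept
  res2 <- data.frame(contrast = c("c1", "c1"), pathway = c("p1", "p2"),
                     z = c(0.67, -3), significant = c(TRUE, FALSE))
  zm2 <- z_matrix(res2)
  expect_false(zm2$mask["p1", "c1"]) # small |z|
  expect_false(zm2$mask["p2", "c1"]) # not significant
  expect_equal(zm2$z["p2", "c1"], -3) # not censored
})
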