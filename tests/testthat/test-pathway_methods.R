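test_that("enrichment score reproduces the 4-gene worked examples", {
  sc <- scores_with_r(c("g1", "g2", "g3", "g4"), c(4, 3, 2, 1))
  # single member at the top: running sum (1, 2/3, 1/3, 0)
  expect_equal(enrichment_score(sc, "g1"), 1, tolerance = 1e-12)
  # single member at the bottom: running sum (-1/3, -2/3, -1, 0)
  expect_equal(enrichment_score(sc, "g4"), 0, tolerance = 1e-12)
  # middle member, weighted walk: hit adds 1 at position 2
  expect_equal(enrichment_score(sc, "g2"),
               naive_es(c(4, 3, 2, 1), c(FALSE, TRUE, FALSE, FALSE)),
               tolerance = 1e-12)
  expect_error(enrichment_score(sc, c("g1", "g2", "g3", "g4")), "some but not all")
  expect_error(enrichment_score(sc, "absent"), "some but not all")
})

test_that("vectorized enrichment score equals the naive walk on 500 random instances", {
  set.seed(44)
  for (i in 1:500) {
    N <- sample(5:60, 1)
    r <- sort(rchisq(N, 1), decreasing = TRUE)
    NH <- sample(seq_len(N - 1), 1)
    member <- seq_len(N) %in% sample(N, NH)
    w <- sample(c(0, 1), 1)
    sc <- scores_with_r(sprintf("g%02d", seq_len(N)), r)
    es <- enrichment_score(sc, sc$gene[member], weight_exponent = w)
    expect_equal(es, naive_es(r, member, w), tolerance = 1e-12)
    expect_gte(es, 0); expect_lte(es, 1)
  }
})

test_that("enrichment score is 1 exactly when all members precede all non-members", {
  sc <- scores_with_r(sprintf("g%02d", 1:12), seq(12, 1))
  expect_equal(enrichment_score(sc, sc$gene[1:4]), 1, tolerance = 1e-12)
  expect_lt(enrichment_score(sc, sc$gene[c(1:3, 5)]), 1)
})

test_that("unweighted scores are invariant to monotone re-transforms of the ranking statistic", {
  set.seed(9)
  N <- 30
  r <- sort(rchisq(N, 1), decreasing = TRUE)
  member <- seq_len(N) %in% sample(N, 8)
  sc1 <- scores_with_r(sprintf("g%02d", 1:N), r)
  sc2 <- scores_with_r(sprintf("g%02d", 1:N), 5 * log1p(r))  # same order
  expect_equal(enrichment_score(sc1, sc1$gene[member], weight_exponent = 0),
               enrichment_score(sc2, sc2$gene[member], weight_exponent = 0),
               tolerance = 1e-12)
})

test_that("enrichment score agrees with fgsea on random instances", {
  set.seed(77)
  for (i in 1:50) {
    N <- sample(10:80, 1)
    r <- sort(rchisq(N, 1) + 0.01, decreasing = TRUE)
    member_idx <- sort(sample(N, sample(2:(N %/% 2), 1)))
    sc <- scores_with_r(sprintf("g%02d", seq_len(N)), r)
    es <- enrichment_score(sc, sc$gene[member_idx])
    ref <- fgsea::calcGseaStat(stats = r, selectedStats = member_idx,
                               gseaParam = 1, scoreType = "pos")
    expect_equal(es, ref, tolerance = 1e-10)
  }
})

test_that("NES centering, scaling and empirical-p bounds follow the permutation null", {
  mk_null <- function(obs, null_mat, B) {
    structure(list(sets = rownames(null_mat),
                   set_sizes = rep(5L, nrow(null_mat)),
                   observed_es = obs, observed_prop = obs,
                   null_es = null_mat, null_prop = null_mat,
                   B = B, seed = 1, n_genes = 50,
                   scores = NULL), class = "permutation_null")
  }
  # null {1,2,3}, observed 3: nes = (3-2)/1, p = (1+1)/4
  nn <- mk_null(c(S = 3), matrix(c(1, 2, 3), 1, dimnames = list("S", NULL)), 3)
  g <- normalize_and_test(nn)
  expect_equal(g$nes, 1.0, tolerance = 1e-12)
  expect_equal(g$empirical_p, 0.5, tolerance = 1e-12)
  # observed equal to the null mean: nes = 0
  nn0 <- mk_null(c(S = 2), matrix(c(1, 2, 3), 1, dimnames = list("S", NULL)), 3)
  expect_equal(normalize_and_test(nn0)$nes, 0, tolerance = 1e-12)
  # observed above every null value at B = 999: p at its lower bound 1/1000
  set.seed(1)
  nb <- mk_null(c(S = 9), matrix(rnorm(999), 1, dimnames = list("S", NULL)), 999)
  expect_equal(normalize_and_test(nb)$empirical_p, 1 / 1000, tolerance = 1e-15)
  # zero-SD null: flagged untestable
  nz <- mk_null(c(S = 1), matrix(1, 1, 5, dimnames = list("S", NULL)), 5)
  expect_true(is.na(normalize_and_test(nz)$nes))
  # empirical-enrichment conventions: observed proportion 0 gives p = 1
  nzp <- mk_null(c(S = 0), matrix(c(0, 0.1, 0, 0.2), 1,
                                  dimnames = list("S", NULL)), 4)
  expect_equal(empirical_enrichment(nzp)$empirical_p, 1, tolerance = 1e-12)
})

test_that("permutation engine is deterministic and honors forced permutations", {
  cfg <- small_cfg()
  sim <- simulate_genotypes(cfg, 41)
  gsc <- simulate_gene_sets(cfg, sim$genemap, 41)
  ph <- simulate_traits(sim$genotypes, sim$genemap, cfg, 1, 41,
                        sim$causal_variants)
  vars <- build_variables(sim$genotypes, sim$genemap)
  X <- as.matrix(ph[, c("Age", "Sex", "Smoking")])
  a <- permute_and_rescore(ph$q1, vars$V, vars$meta, X, gsc, B = 2, seed = 5,
                           size_bounds = cfg$set_size_bounds)
  b <- permute_and_rescore(ph$q1, vars$V, vars$meta, X, gsc, B = 2, seed = 5,
                           size_bounds = cfg$set_size_bounds)
  expect_identical(a$null_es, b$null_es)
  expect_identical(a$null_prop, b$null_prop)
  # identity permutation reproduces the observed statistics exactly
  n <- length(ph$q1)
  idp <- permute_and_rescore(ph$q1, vars$V, vars$meta, X, gsc, B = 1,
                             size_bounds = cfg$set_size_bounds,
                             permutations = matrix(seq_len(n), n, 1))
  expect_equal(idp$null_es[, 1], idp$observed_es, tolerance = 1e-12)
  expect_equal(idp$null_prop[, 1], idp$observed_prop, tolerance = 1e-12)
  expect_error(permute_and_rescore(ph$q1, vars$V, vars$meta, X, gsc, B = 0),
               "B must be")
})

test_that("empirical-p of a permutation draw is discretely uniform under exchangeability", {
  # the observed trait is itself a null draw, so the causal set's GSEA
  # empirical p must be uniform on {1/(B+1), ..., 1}
  cfg <- small_cfg(q4_pop_shift = rep(0, 4), fst = rep(0.02, 4))
  sim <- simulate_genotypes(cfg, 55)
  gsc <- simulate_gene_sets(cfg, sim$genemap, 55)
  vars <- build_variables(sim$genotypes, sim$genemap)
  B <- 19
  ps <- vapply(1:120, function(r) {
    ph <- simulate_traits(sim$genotypes, sim$genemap, cfg, r, 55,
                          sim$causal_variants)
    X <- as.matrix(ph[, c("Age", "Sex", "Smoking")])
    nn <- permute_and_rescore(ph$q4, vars$V, vars$meta, X, gsc, B = B,
                              seed = 1e6 + r, size_bounds = cfg$set_size_bounds)
    normalize_and_test(nn)$empirical_p[nn$sets == cfg$causal_set_name]
  }, numeric(1))
  counts <- table(factor(round(ps * (B + 1)), levels = 1:(B + 1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("Fisher overrepresentation matches hypergeometric enumeration", {
  # worked example: universe 10, set 5, focus 4, overlap 4 -> 5/210
  sc <- scores_with_r(sprintf("g%02d", 1:10), seq(20, 2, length.out = 10))
  sc$min_p <- rep(0.5, 10)
  sc$min_p[1:4] <- 1e-4   # focus genes = exactly the top 4
  gsc <- gene_set_collection(list(S = sprintf("g%02d", 1:5)))
  res <- fisher_overrepresentation(sc, gsc, focus_alpha = 0.01,
                                   size_bounds = c(1, 100))
  expect_equal(res$overlap, 4L, ignore_attr = TRUE)
  expect_equal(res$ratio, 4 / 5)
  expect_equal(res$fisher_p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$fisher_p, enum_fisher_p(10, 5, 4, 4), tolerance = 1e-12)

  # zero overlap: upper-tail p = P(X >= 0) = 1
  gsc0 <- gene_set_collection(list(S = sprintf("g%02d", 6:10)))
  sc0 <- sc; sc0$min_p <- 1; sc0$min_p[1:4] <- 1e-4
  res0 <- fisher_overrepresentation(sc0, gsc0, size_bounds = c(1, 100))
  expect_equal(res0$fisher_p, 1)

  # enumeration oracle on 200 random instances
  set.seed(66)
  for (i in 1:200) {
    N <- sample(8:40, 1)
    K <- sample(2:(N - 2), 1)
    nf <- sample(0:N, 1)
    genes <- sprintf("x%03d", seq_len(N))
    sci <- scores_with_r(genes, sort(rchisq(N, 1), decreasing = TRUE))
    sci$min_p <- rep(1, N)
    if (nf > 0) sci$min_p[sample(N, nf)] <- 1e-5
    gi <- gene_set_collection(list(S = sample(genes, K)))
    resi <- suppressMessages(
      fisher_overrepresentation(sci, gi, size_bounds = c(1, N)))
    ov <- sum(gi[["S"]] %in% sci$gene[sci$min_p < 0.01])
    want <- if (nf == 0) 1 else enum_fisher_p(N, K, nf, ov)
    expect_equal(resi$fisher_p, want, tolerance = 1e-10)
    expect_identical(resi$overlap, as.integer(ov))
  }
})
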