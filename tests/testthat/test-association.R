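test_that("single-variable OLS matches the closed-form normal equations", {
  # fixed 8-observation toy, no covariates
  g <- c(0, 0, 1, 1, 1, 2, 2, 2)
  y <- c(1.0, 1.2, 1.9, 2.1, 2.0, 3.1, 2.9, 3.0)
  want <- closed_form_ols(y, g)
  got <- fit_linear_association(y, g)
  expect_equal(got$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_equal(got$df_residual, want$df)

  # 100 random small designs with covariates, and the vectorized scan
  # agreeing with both routes
  set.seed(99)
  for (i in 1:100) {
    n <- sample(12:40, 1)
    X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    g <- rbinom(n, 2, 0.3)
    if (var(g) == 0) next
    y <- rnorm(n) + 0.3 * g + X %*% c(0.5, -0.2)
    want <- closed_form_ols(y, g, X)
    got <- fit_linear_association(y, g, X)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
    sc <- association_scan(as.numeric(y), cbind(g = g), X)
    expect_equal(sc$beta, want$beta, tolerance = 1e-8)
    expect_equal(sc$se, want$se, tolerance = 1e-8)
    expect_equal(sc$p_value, want$p, tolerance = 1e-8)
  }
})

test_that("perfect fit and degenerate variables are handled explicitly", {
  g <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  # lm warns about the exact fit; the record itself is what matters here
  got <- suppressWarnings(fit_linear_association(2 * g, g))
  expect_equal(got$beta, 2, tolerance = 1e-8)
  expect_lt(got$p_value, 1e-100)

  # constant variable: flagged untestable, not given an arbitrary p
  const <- fit_linear_association(rnorm(10), rep(1, 10))
  expect_false(const$testable)
  sc <- association_scan(rnorm(10), cbind(a = rep(2, 10), b = c(0, 1, 0, 1,
                                                                0, 1, 0, 1, 0, 1)))
  expect_false(sc$testable[1])
  expect_true(sc$testable[2])
})

test_that("null p-values are uniform over many simulated fits", {
  set.seed(7)
  n <- 150
  V <- matrix(rbinom(n * 2000, 2, 0.25), n)
  colnames(V) <- paste0("v", 1:2000)
  sc <- association_scan(rnorm(n), V, cbind(rnorm(n)))
  expect_gt(suppressWarnings(
    stats::ks.test(sc$p_value[sc$testable], "punif"))$p.value, 0.001)
})

test_that("rare-allele burden counts use a strict MAF threshold and sum dosages", {
  # 10 samples, 3 variants in one gene with MAFs 0.005-ish, 0.02-ish
  dos <- matrix(0L, 100, 3, dimnames = list(NULL, c("v1", "v2", "v3")))
  dos[1, 1] <- 1L            # maf 0.005  -> rare
  dos[1:4, 2] <- 1L          # maf 0.02   -> common, excluded
  dos[1, 3] <- 2L; dos[2, 3] <- 1L   # maf 0.015 -> common at threshold 0.01
  g <- genotype_matrix(dos)
  gm <- data.frame(variant_id = c("v1", "v2", "v3"), gene = "GENE1")
  b <- rare_burden_counts(g, gm, maf_threshold = 0.01)
  expect_identical(colnames(b), "GENE1")
  expect_identical(as.integer(b[1, ]), 1L)   # only v1 contributes

  # additivity: dosages (1, 2) at two rare variants give count 3
  dos2 <- matrix(0L, 200, 2, dimnames = list(NULL, c("a", "b")))
  dos2[1, 1] <- 1L; dos2[1, 2] <- 2L
  g2 <- genotype_matrix(dos2)
  b2 <- rare_burden_counts(g2, data.frame(variant_id = c("a", "b"),
                                          gene = "G"), 0.01)
  expect_identical(as.integer(b2[1, ]), 3L)

  # brute-force recount oracle and upper bound on a random fixture
  set.seed(3)
  cfg <- small_cfg()
  sim <- simulate_genotypes(cfg, 17)
  B <- rare_burden_counts(sim$genotypes, sim$genemap)
  maf <- sim$genotypes$maf
  for (gs in sample(colnames(B), 5)) {
    ids <- sim$genemap$variant_id[sim$genemap$gene == gs]
    rare <- ids[maf[match(ids, sim$genotypes$variant_ids)] < 0.01]
    manual <- rowSums(sim$genotypes$dosages[, rare, drop = FALSE])
    expect_identical(as.integer(B[, gs]), as.integer(manual))
    expect_true(all(B[, gs] <= 2 * length(rare)))
  }
})

test_that("burden regression for a single-rare-variant gene equals the variant's own test", {
  set.seed(5)
  n <- 300
  dos <- matrix(0L, n, 2, dimnames = list(NULL, c("rare1", "comm1")))
  dos[sample(n, 4), 1] <- 1L                    # maf ~0.007
  dos[, 2] <- rbinom(n, 2, 0.3)
  g <- genotype_matrix(dos)
  gm <- data.frame(variant_id = c("rare1", "comm1"), gene = "GENE")
  vars <- build_variables(g, gm)
  # the burden variable is numerically identical to the lone rare variant's
  # dosage column, so its test statistic is identical too
  expect_identical(as.integer(vars$V[, "burden:GENE"]),
                   as.integer(dos[, 1]))
  y <- rnorm(n) + 0.5 * dos[, 1]
  both <- association_scan(y, cbind(rare1 = as.numeric(dos[, 1]),
                                    `burden:GENE` = as.numeric(
                                      vars$V[, "burden:GENE"])))
  expect_identical(both$p_value[1], both$p_value[2])
  # and through the full variable-building route, equal to 1e-12
  sc <- association_scan(y, vars$V)
  p_burden <- sc$p_value[sc$variable_id == "burden:GENE"]
  p_direct <- association_scan(y, dos[, 1, drop = FALSE])$p_value
  expect_equal(p_burden, p_direct, tolerance = 1e-12)
})

test_that("principal components recover structure with deterministic orientation", {
  cfg <- sim_config(n_samples = 200, pop_sizes = c(100, 100),
                    fst = c(0.15, 0.15), q4_pop_shift = c(-0.5, 0.5),
                    n_genes = 200, n_gene_sets = 20)
  sim <- simulate_genotypes(cfg, 23)
  pcs <- compute_pcs(sim$genotypes, K = 5)
  # decomposition contract
  expect_equal(crossprod(pcs$pcs) / diag(crossprod(pcs$pcs)),
               diag(5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
  # PC1 separates the two populations
  pop01 <- as.integer(sim$genotypes$population) - 1
  expect_gt(abs(cor(pcs$pcs[, 1], pop01)), 0.9)

  # duplicated dataset rows get identical coordinates
  dup <- rbind(sim$genotypes$dosages, sim$genotypes$dosages[1:5, ])
  rownames(dup) <- c(sim$genotypes$sample_ids, paste0("dup", 1:5))
  gdup <- genotype_matrix(dup)
  pd <- compute_pcs(gdup, K = 3)
  expect_equal(pd$pcs[201:205, ], pd$pcs[1:5, ], ignore_attr = TRUE,
               tolerance = 1e-8)

  # K beyond rank is reduced with a warning
  tiny <- genotype_matrix(matrix(rbinom(40, 2, 0.4), nrow = 5))
  expect_warning(pk <- compute_pcs(tiny, K = 10), "rank")
  expect_lte(ncol(pk$pcs), 4)
})

test_that("PC selection finds planted associations at the configured level", {
  set.seed(31)
  cfg <- small_cfg(fst = c(0.05, 0.08, 0.12, 0.15))
  sim <- simulate_genotypes(cfg, 29)
  pcs <- compute_pcs(sim$genotypes, K = 6)
  # trait equal to PC3 plus tiny noise selects exactly {3}
  trait <- pcs$pcs[, 3] + rnorm(120, 0, 0.02 * sd(pcs$pcs[, 3]))
  expect_identical(select_pcs(pcs, trait), 3L)
  # strong two-PC signal is always recovered
  hits <- vapply(1:20, function(i) {
    tr <- 2 * scale(pcs$pcs[, 1]) + 2 * scale(pcs$pcs[, 4]) + rnorm(120)
    all(c(1L, 4L) %in% select_pcs(pcs, as.numeric(tr)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # pure-noise traits select about alpha * K components
  n_sel <- vapply(1:60, function(i) length(select_pcs(pcs, rnorm(120))),
                  numeric(1))
  expect_lt(mean(n_sel), 3 * 0.05 * 6 + 0.2)
})

test_that("genomic lambda matches its chi-square quantile definition", {
  expect_equal(genomic_lambda(rep(0.5, 7)), 1.0, tolerance = 1e-12)
  # all p = 0.0455: lambda = qchisq inversion oracle
  want <- qchisq(0.0455, 1, lower.tail = FALSE) / qchisq(0.5, 1)
  expect_equal(genomic_lambda(rep(0.0455, 3)), want, tolerance = 1e-12)
  expect_equal(want, 8.79, tolerance = 0.01)
  set.seed(2)
  expect_equal(genomic_lambda(runif(10000)), 1, tolerance = 0.03)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
})

test_that("gene scoring takes the minimum p, breaks ties lexicographically, and ranks by r", {
  rec <- data.frame(
    gene = c("GB", "GB", "GA", "GC", "GC", "GD"),
    p_value = c(0.04, 0.002, 0.02, 0.02, 0.5, NA),
    variable_id = c("s1", "burden:GB", "s2", "s3", "s4", "s5"),
    testable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  tab <- gene_scores(rec)
  expect_identical(tab$gene[tab$rank == 1], "GB")
  expect_identical(tab$best_variable_id[tab$gene == "GB"], "burden:GB")
  # GA and GC tie at 0.02: lexicographic order decides
  expect_lt(tab$rank[tab$gene == "GA"], tab$rank[tab$gene == "GC"])
  # untestable-only gene excluded and counted
  expect_false("GD" %in% tab$gene)
  expect_identical(attr(tab, "n_untestable_genes"), 1L)
  # ranking by r equals ranking by ascending min_p on a random fixture
  set.seed(8)
  rec2 <- data.frame(gene = paste0("G", 1:50), p_value = runif(50),
                     variable_id = paste0("v", 1:50), testable = TRUE)
  tab2 <- gene_scores(rec2)
  expect_identical(order(tab2$min_p), order(-tab2$r))
  expect_identical(tab2$rank, seq_len(50))
})
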