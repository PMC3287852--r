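# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately avoid the package's vectorized code paths.

# literal walk of the weighted KS running sum; returns the maximum over all
# N step values (the final value is always 0)
naive_es <- function(r_desc, member, weight_exponent = 1) {
  N <- length(r_desc)
  NH <- sum(member)
  w <- abs(r_desc)^weight_exponent
  NR <- sum(w[member])
  running <- 0
  best <- -Inf
  for (i in seq_len(N)) {
    if (member[i]) running <- running + w[i] / NR
    else running <- running - 1 / (N - NH)
    best <- max(best, running)
  }
  best
}

# one-sided upper-tail hypergeometric p by explicit table enumeration with
# choose() arithmetic (independent of phyper)
enum_fisher_p <- function(N, set_size, n_focus, overlap) {
  xs <- overlap:min(set_size, n_focus)
  sum(choose(n_focus, xs) * choose(N - n_focus, set_size - xs)) /
    choose(N, set_size)
}

# closed-form OLS of y on cbind(1, X, g) via the normal equations
closed_form_ols <- function(y, g, X = NULL) {
  A <- if (is.null(X)) cbind(1, g) else cbind(1, X, g)
  XtX <- t(A) %*% A
  bh <- solve(XtX, t(A) %*% y)
  res <- y - A %*% bh
  df <- length(y) - ncol(A)
  s2 <- sum(res^2) / df
  covb <- s2 * solve(XtX)
  j <- ncol(A)
  beta <- bh[j]
  se <- sqrt(covb[j, j])
  t <- beta / se
  list(beta = beta, se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# small, fast simulation profile for unit tests
small_cfg <- function(...) {
  args <- list(n_samples = 120, pop_sizes = rep(30, 4),
               n_genes = 60, variants_per_gene_mean = 6,
               n_gene_sets = 12, causal_set_size = 12,
               set_size_bounds = c(5, 50))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# build a valid gene_scores table with prescribed r values (descending) by
# inverting the chi-square transform
scores_with_r <- function(genes, r_values) {
  p <- pchisq(r_values, df = 1, lower.tail = FALSE)
  gene_scores(data.frame(gene = genes, p_value = p,
                         variable_id = paste0("v_", genes), testable = TRUE,
                         stringsAsFactors = FALSE))
}

# hand-built 5-sample x 4-variant dosage fixture used by the VCF tests
fixture_genotypes <- function() {
  dos <- matrix(c(0L, 1L, 2L, 0L, 1L,
                  0L, 0L, 0L, 0L, 0L,
                  2L, 2L, 1L, 1L, 0L,
                  1L, 0L, 0L, 0L, 0L), nrow = 5,
                dimnames = list(paste0("S", 1:5), paste0("var", 1:4)))
  genotype_matrix(dos, chrom = c("1", "1", "2", "2"),
                  pos = c(100L, 200L, 50L, 75L),
                  ref = rep("A", 4), alt = rep("C", 4))
}
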