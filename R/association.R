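#' Additive linear association test for a single genetic variable
#'
#' Ordinary least squares of the trait on `[1, X, g]`, where `g` is a
#' genetic variable (a common SNP's allele dosage or a gene's aggregate
#' rare-allele count), with a two-sided t-test on the `g` coefficient. A
#' variable that is constant, or collinear with the covariates, is flagged
#' untestable rather than given an arbitrary p-value.
#'
#' @param y numeric trait vector (no missing values).
#' @param g numeric genetic-variable vector.
#' @param X optional covariate matrix/data.frame (no intercept column; one
#'   is always added).
#' @return one-row data.frame: `beta`, `se`, `t_statistic`, `p_value`,
#'   `n_used`, `df_residual`, `testable`.
#' @export
fit_linear_association <- function(y, g, X = NULL) {
  if (anyNA(y) || anyNA(g) || (!is.null(X) && anyNA(X)))
    stop("missing values are not supported")
  n <- length(y)
  dat <- if (is.null(X)) data.frame(y = y, g = g)
         else data.frame(y = y, as.data.frame(X), g = g)
  fit <- stats::lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  if (!"g" %in% rownames(cf) || is.na(stats::coef(fit)["g"])) {
    return(data.frame(beta = NA_real_, se = NA_real_, t_statistic = NA_real_,
                      p_value = NA_real_, n_used = n,
                      df_residual = fit$df.residual, testable = FALSE))
  }
  data.frame(beta = cf["g", 1], se = cf["g", 2], t_statistic = cf["g", 3],
             p_value = cf["g", 4], n_used = n,
             df_residual = fit$df.residual, testable = TRUE)
}

#' Per-gene aggregate rare-allele counts
#'
#' For every gene with at least one rare variant (folded MAF strictly below
#' `maf_threshold`), the per-sample sum of minor-allele dosages over those
#' variants — the "aggregate rare variant" used as a single regressor.
#' Genes without rare variants yield no burden variable.
#'
#' @param genotypes a [genotype_matrix()].
#' @param genemap variant-to-gene map data.frame.
#' @param maf_threshold rare-variant MAF cutoff (strict `<`; default 0.01).
#' @return integer matrix, samples x genes-with-rare-variants.
#' @export
rare_burden_counts <- function(genotypes, genemap, maf_threshold = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_genemap(genemap, genotypes)
  maf <- genotypes$maf[match(genemap$variant_id, genotypes$variant_ids)]
  rare <- genemap[maf < maf_threshold, , drop = FALSE]
  if (nrow(rare) == 0L)
    return(matrix(integer(0), nrow = nrow(genotypes$dosages), ncol = 0))
  genes <- unique(rare$gene)
  out <- vapply(genes, function(gs) {
    idx <- match(rare$variant_id[rare$gene == gs], genotypes$variant_ids)
    as.integer(rowSums(genotypes$dosages[, idx, drop = FALSE]))
  }, integer(nrow(genotypes$dosages)))
  out <- matrix(out, nrow = nrow(genotypes$dosages),
                dimnames = list(genotypes$sample_ids, genes))
  out
}

#' Assemble the genetic-variable matrix for an association scan
#'
#' Columns are (a) allele dosages of every common variant (folded MAF at
#' least `maf_threshold`) and (b) one aggregate rare-allele burden count
#' per gene that has rare variants. This is the full set of genetic
#' variables feeding gene-level scoring.
#'
#' @inheritParams rare_burden_counts
#' @return list: `V` (numeric matrix samples x variables), `meta`
#'   (data.frame `variable_id`, `gene`, `kind` in `common_snp`/`rare_burden`).
#' @export
build_variables <- function(genotypes, genemap, maf_threshold = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_genemap(genemap, genotypes)
  maf <- genotypes$maf[match(genemap$variant_id, genotypes$variant_ids)]
  common <- genemap[maf >= maf_threshold, , drop = FALSE]
  Vc <- genotypes$dosages[, match(common$variant_id, genotypes$variant_ids),
                          drop = FALSE]
  B <- rare_burden_counts(genotypes, genemap, maf_threshold)
  V <- cbind(Vc, B)
  meta <- data.frame(
    variable_id = c(common$variant_id, paste0("burden:", colnames(B))),
    gene = c(common$gene, colnames(B)),
    kind = c(rep("common_snp", nrow(common)),
             rep("rare_burden", ncol(B))),
    stringsAsFactors = FALSE)
  colnames(V) <- meta$variable_id
  list(V = V, meta = meta)
}

# Precompute the covariate projection for repeated scans: thin Q of
# qr(cbind(1, X)) plus the residual degrees of freedom for one extra
# regressor.
.covariate_basis <- function(n, X = NULL) {
  X1 <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  qrd <- qr(X1)
  list(Q = qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE],
       df = n - qrd$rank - 1L)
}

.residualize <- function(M, Q) M - Q %*% crossprod(Q, M)

#' Vectorized association scan over many genetic variables
#'
#' Exact OLS t-tests of the trait on each column of `V` adjusting for
#' covariates, computed by residualizing trait and variables on the
#' covariate space (equivalent to fitting `y ~ X + v` per column, see
#' [fit_linear_association()], but linear-algebra vectorized). Variables
#' with (near) zero residual variance are flagged untestable and excluded
#' from gene scoring by downstream code.
#'
#' @param y numeric trait vector.
#' @param V numeric matrix of genetic variables (samples x variables).
#' @param X optional covariate matrix.
#' @param basis optionally a precomputed `.covariate_basis`-style list and
#'   pre-residualized variables, as used by the permutation engine
#'   (internal fast path): `list(Q, df, Vres, vss)`.
#' @return data.frame: `variable_id`, `beta`, `se`, `t_statistic`,
#'   `p_value`, `n_used`, `testable`.
#' @export
association_scan <- function(y, V, X = NULL, basis = NULL) {
  n <- length(y)
  if (is.null(basis)) {
    cb <- .covariate_basis(n, X)
    Vres <- .residualize(V, cb$Q)
    vss <- colSums(Vres^2)
    basis <- list(Q = cb$Q, df = cb$df, Vres = Vres, vss = vss)
  }
  yres <- as.numeric(y - basis$Q %*% crossprod(basis$Q, y))
  yss <- sum(yres^2)
  xy <- as.numeric(crossprod(basis$Vres, yres))
  vss <- basis$vss
  testable <- vss > 1e-10 * n
  beta <- ifelse(testable, xy / vss, NA_real_)
  rss <- pmax(yss - beta^2 * vss, 0)
  se <- ifelse(testable, sqrt(rss / basis$df / vss), NA_real_)
  tstat <- beta / se
  # guard exact fits (rss == 0): t is infinite, p underflows to 0 and is
  # floored later by the gene-score transform
  p <- ifelse(testable, 2 * stats::pt(-abs(tstat), basis$df), NA_real_)
  data.frame(variable_id = colnames(V), beta = beta, se = se,
             t_statistic = tstat, p_value = p, n_used = n,
             testable = testable, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Principal components of the common-variant genotypes
#'
#' PCA of the column-standardized dosage matrix of common variants (folded
#' MAF at least `maf_threshold`; variants monomorphic after filtering are
#' dropped). The sign of each component is fixed deterministically so that
#' the largest-magnitude variant loading is positive.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_threshold common-variant MAF cutoff (default 0.01).
#' @param K number of components to keep (reduced with a warning if it
#'   exceeds the matrix rank).
#' @return list of class `structure_adjustment`: `pcs` (samples x K score
#'   matrix), `eigenvalues` (length K, descending), `n_common_variants`.
#' @export
compute_pcs <- function(genotypes, maf_threshold = 0.01, K = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  common <- genotypes$dosages[, genotypes$maf >= maf_threshold, drop = FALSE]
  sds <- apply(common, 2, stats::sd)
  common <- common[, sds > 0, drop = FALSE]
  if (ncol(common) < 1L) stop("no polymorphic common variants for PCA")
  Z <- scale(common)
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > 1e-8 * pr$sdev[1])
  if (K > rank) {
    warning(sprintf("K = %d exceeds rank %d; reduced", K, rank))
    K <- rank
  }
  scores <- pr$x[, seq_len(K), drop = FALSE]
  load <- pr$rotation[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    if (load[which.max(abs(load[, k])), k] < 0) {
      scores[, k] <- -scores[, k]
      load[, k] <- -load[, k]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(pcs = scores, eigenvalues = pr$sdev[seq_len(K)]^2,
                 loadings = load, n_common_variants = ncol(common)),
            class = "structure_adjustment")
}

#' Select the principal components associated with a trait
#'
#' Each PC is tested separately in a marginal linear regression of the
#' trait on that PC; components with p below `alpha` are selected for
#' inclusion as covariates in the association models.
#'
#' @param pcs a `structure_adjustment` from [compute_pcs()] (or a plain
#'   score matrix).
#' @param trait numeric trait vector.
#' @param alpha selection level (default 0.05).
#' @return integer vector of selected PC indices (possibly empty).
#' @export
select_pcs <- function(pcs, trait, alpha = 0.05) {
  S <- if (inherits(pcs, "structure_adjustment")) pcs$pcs else as.matrix(pcs)
  p <- vapply(seq_len(ncol(S)), function(k) {
    fit <- stats::lm(trait ~ S[, k])
    stats::summary.lm(fit)$coefficients[2, 4]
  }, numeric(1))
  which(p < alpha)
}

#' Genomic-control inflation factor
#'
#' `lambda` = median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null 1-df chi-square median (~0.4549). Values
#' well above 1 signal confounding such as population stratification.
#'
#' @param p_values numeric vector of two-sided association p-values.
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Gene-level scores from association records
#'
#' Assigns each gene the p-value of its most significant genetic variable
#' (common SNP or rare-allele burden), transforms it into the ranking
#' statistic `r` = 1-df chi-square quantile at `1 - min_p` (p floored at
#' 1e-300 first), and ranks genes from highest to lowest `r`. Ties are
#' broken by ascending gene symbol, deterministically. Genes with no
#' testable variable are excluded from the universe; the number excluded is
#' reported as an attribute.
#'
#' @param records data.frame with at least `gene`, `p_value`, `variable_id`,
#'   `testable` columns (e.g. from [association_scan()] joined with the
#'   variable metadata).
#' @return data.frame of class `gene_scores`: `gene`, `min_p`,
#'   `best_variable_id`, `r`, `rank`, ordered by rank; attribute
#'   `n_untestable_genes`.
#' @export
gene_scores <- function(records) {
  stopifnot(all(c("gene", "p_value", "variable_id", "testable") %in%
                  names(records)))
  all_genes <- unique(records$gene)
  rec <- records[records$testable & !is.na(records$p_value), , drop = FALSE]
  n_dropped <- length(setdiff(all_genes, unique(rec$gene)))
  # deterministic within-gene winner: smallest p, then variable_id
  o <- order(rec$gene, rec$p_value, rec$variable_id)
  rec <- rec[o, , drop = FALSE]
  first <- !duplicated(rec$gene)
  tab <- data.frame(gene = rec$gene[first],
                    min_p = rec$p_value[first],
                    best_variable_id = rec$variable_id[first],
                    stringsAsFactors = FALSE)
  tab$r <- stats::qchisq(pmax(tab$min_p, 1e-300), df = 1, lower.tail = FALSE)
  o <- order(-tab$r, tab$gene)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "n_untestable_genes") <- n_dropped
  class(tab) <- c("gene_scores", "data.frame")
  tab
}
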