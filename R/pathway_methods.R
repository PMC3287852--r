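# Core of the weighted Kolmogorov-Smirnov running-sum statistic.
# Arguments: sorted (ascending) ranks of the member genes, the full
# descending-ordered |r| vector, N, and the weight exponent. The running
# sum gains |r_i|^w / N_R at each member and loses 1/(N - N_H) at each
# non-member; because the sum always returns to 0 at the end of the list,
# its maximum over steps is >= 0 and is attained immediately after a
# member hit (or at the final 0).
.es_core <- function(member_pos, r_abs, weight_exponent) {
  N <- length(r_abs)
  NH <- length(member_pos)
  w <- r_abs[member_pos]^weight_exponent
  NR <- sum(w)
  if (NR <= 0) {
    # degenerate all-zero weights: equal weighting over members
    w <- rep(1, NH)
    NR <- NH
  }
  hits <- cumsum(w) / NR
  misses <- (member_pos - seq_len(NH)) / (N - NH)
  max(0, max(hits - misses))
}

#' Gene-set enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like running-sum statistic over a ranked
#' gene list: walking the list from the most to the least significant gene,
#' the sum increases by `|r_i|^weight_exponent / N_R` at genes in the set
#' (`N_R` = the sum of those weights over the set) and decreases by
#' `1/(N - N_H)` at genes outside it. The enrichment score is the maximum
#' of the running sum — high when the set's genes cluster at the top of the
#' ranking. The running sum ends at exactly 0, so the score is always in
#' `[0, 1]`, and equals 1 iff every member precedes every non-member.
#'
#' @param scores a `gene_scores` table from [gene_scores()] (ordered by
#'   rank).
#' @param gene_set character vector of gene symbols; must intersect the
#'   scored universe in `0 < N_H < N` genes or an error is raised.
#' @param weight_exponent exponent on `|r|` in the member weights
#'   (default 1; 0 gives the unweighted KS statistic).
#' @return the enrichment score (scalar).
#' @export
enrichment_score <- function(scores, gene_set, weight_exponent = 1) {
  stopifnot(inherits(scores, "gene_scores"))
  member <- scores$gene %in% gene_set
  NH <- sum(member)
  if (NH == 0L || NH == length(member))
    stop("gene set must contain some but not all ranked genes")
  .es_core(which(member), abs(scores$r), weight_exponent)
}

# fast gene-level min-p: idx_list maps each gene (in sorted-symbol order)
# to its variable indices
.fast_gene_minp <- function(p, idx_list) {
  vapply(idx_list, function(i) min(p[i]), numeric(1))
}

# per-permutation set statistics given gene-level min-p values.
# gene_rank_pos[i] = position of gene i in the descending-r ranking.
.set_stats_once <- function(minp, set_idx, weight_exponent, alpha_gene) {
  r <- stats::qchisq(pmax(minp, 1e-300), df = 1, lower.tail = FALSE)
  ord <- order(-r, seq_along(r))       # ties: ascending gene-symbol order
  pos_of <- integer(length(r))
  pos_of[ord] <- seq_along(r)
  r_sorted <- r[ord]
  es <- vapply(set_idx, function(idx) {
    .es_core(sort(pos_of[idx]), r_sorted, weight_exponent)
  }, numeric(1))
  prop <- vapply(set_idx, function(idx) mean(minp[idx] < alpha_gene),
                 numeric(1))
  list(es = es, prop = prop)
}

#' Phenotype-permutation null distributions for the enrichment statistics
#'
#' The shared permutation engine of the GSEA and empirical-enrichment
#' tests. The trait vector is permuted against the genotype/covariate rows
#' `B` times (covariates stay attached to the genotypes, so the
#' genotype-covariate structure, including any PCs, is preserved under the
#' null); for each permutation the full association scan, gene-level
#' min-p scoring and both per-set statistics (enrichment score and
#' proportion of genes with min-p below `alpha_gene`) are recomputed. One
#' permutation stream serves all sets, preserving between-set correlation.
#'
#' @param y numeric trait vector.
#' @param V genetic-variable matrix from [build_variables()].
#' @param meta its variable metadata (`variable_id`, `gene`, `kind`).
#' @param X covariate matrix (covariates plus any selected PCs).
#' @param gene_sets a [gene_set_collection()]; restricted internally to the
#'   scored-gene universe with `size_bounds`, identically for the observed
#'   and permuted analyses.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param weight_exponent ES weight exponent (default 1).
#' @param alpha_gene gene-level significance threshold of the proportion
#'   statistic (default 0.01).
#' @param size_bounds inclusive set-size bounds after restriction.
#' @param permutations optional integer matrix (`length(y)` x `B`) of
#'   explicit permutation indices, overriding the seeded draw (used to
#'   force, e.g., the identity permutation in tests).
#' @return list of class `permutation_null`: `sets` (names), `set_sizes`,
#'   `observed_es`, `observed_prop`, `null_es` and `null_prop` (sets x `B`
#'   matrices), `scores` (observed `gene_scores`), `B`, `seed`,
#'   `n_genes`.
#' @export
permute_and_rescore <- function(y, V, meta, X, gene_sets, B = 1000, seed = 1,
                                weight_exponent = 1, alpha_gene = 0.01,
                                size_bounds = c(10, 409),
                                permutations = NULL) {
  if (B < 1) stop("B must be >= 1")
  n <- length(y)
  cb <- .covariate_basis(n, X)
  Vres <- .residualize(V, cb$Q)
  basis <- list(Q = cb$Q, df = cb$df, Vres = Vres, vss = colSums(Vres^2))

  obs <- association_scan(y, V, X, basis = basis)
  obs$gene <- meta$gene[match(obs$variable_id, meta$variable_id)]
  scores <- gene_scores(obs)

  universe <- sort(scores$gene)
  gsc <- restrict_sets(gene_sets, universe, size_bounds[1], size_bounds[2])
  if (length(gsc) == 0L) stop("no gene set survives restriction to the universe")
  # variable-to-gene index list in sorted gene-symbol order
  testable <- obs$testable & !is.na(obs$p_value)
  idx_list <- split(which(testable), obs$gene[testable])
  idx_list <- idx_list[universe]
  set_idx <- lapply(gsc, function(s) match(sort(s), universe))

  minp_obs <- .fast_gene_minp(obs$p_value, idx_list)
  st_obs <- .set_stats_once(minp_obs, set_idx, weight_exponent, alpha_gene)

  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  } else {
    storage.mode(permutations) <- "integer"
    if (nrow(permutations) != n || ncol(permutations) != B)
      stop("permutations must be a length(y) x B index matrix")
  }

  null_es <- matrix(NA_real_, length(gsc), B,
                    dimnames = list(names(gsc), NULL))
  null_prop <- null_es
  for (b in seq_len(B)) {
    sc <- association_scan(y[permutations[, b]], V, basis = basis)
    minp <- .fast_gene_minp(sc$p_value, idx_list)
    st <- .set_stats_once(minp, set_idx, weight_exponent, alpha_gene)
    null_es[, b] <- st$es
    null_prop[, b] <- st$prop
  }
  structure(list(sets = names(gsc), set_sizes = lengths(set_idx),
                 observed_es = st_obs$es, observed_prop = st_obs$prop,
                 null_es = null_es, null_prop = null_prop,
                 scores = scores, B = B, seed = seed,
                 n_genes = length(universe)),
            class = "permutation_null")
}

#' Normalize enrichment scores and compute empirical p-values
#'
#' For each set, the normalized enrichment score
#' `NES = (ES - mean(null ES)) / sd(null ES)` using that set's own
#' permutation distribution; the empirical p-value compares the observed
#' NES to the set's normalized null values with the add-one estimator
#' `(1 + #\{null >= observed\}) / (B + 1)`, one-sided for enrichment, so it
#' is bounded below by `1/(B+1)`. Sets with a zero-SD null are flagged
#' untestable (`NA` NES and p).
#'
#' @param null a `permutation_null` from [permute_and_rescore()].
#' @return data.frame of class `gsea_result`: `set`, `n_genes`, `es`,
#'   `nes`, `empirical_p`.
#' @export
normalize_and_test <- function(null) {
  stopifnot(inherits(null, "permutation_null"))
  mu <- rowMeans(null$null_es)
  sdev <- apply(null$null_es, 1, stats::sd)
  nes <- ifelse(sdev > 0, (null$observed_es - mu) / sdev, NA_real_)
  p <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    znull <- (null$null_es[i, ] - mu[i]) / sdev[i]
    (1 + sum(znull >= nes[i])) / (null$B + 1)
  }, numeric(1))
  out <- data.frame(set = null$sets, n_genes = null$set_sizes,
                    es = null$observed_es, nes = nes, empirical_p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Empirical enrichment test
#'
#' For each set, the observed proportion of member genes whose gene-level
#' min-p is below `alpha_gene` (0.01), compared to the permutation null
#' distribution of the same proportion: empirical p =
#' `(1 + #\{null proportions >= observed\}) / (B + 1)`.
#'
#' @param null a `permutation_null` from [permute_and_rescore()].
#' @return data.frame of class `empirical_enrichment_result`: `set`,
#'   `n_genes`, `proportion`, `empirical_p`.
#' @export
empirical_enrichment <- function(null) {
  stopifnot(inherits(null, "permutation_null"))
  p <- vapply(seq_along(null$observed_prop), function(i) {
    (1 + sum(null$null_prop[i, ] >= null$observed_prop[i])) / (null$B + 1)
  }, numeric(1))
  out <- data.frame(set = null$sets, n_genes = null$set_sizes,
                    proportion = null$observed_prop, empirical_p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("empirical_enrichment_result", "data.frame")
  out
}

#' Fisher's-exact overrepresentation of focus genes
#'
#' Focus genes are the scored genes with min-p below `focus_alpha` (0.01).
#' Each set is tested for overrepresentation of focus genes against the
#' scored universe with the one-sided hypergeometric upper tail (Fisher's
#' exact test on the 2x2 in-set x in-focus table); the ratio is
#' overlap / set size. If no gene reaches the focus threshold, every set
#' gets p = 1 (with a message).
#'
#' @param scores a `gene_scores` table.
#' @param gene_sets a [gene_set_collection()]; restricted to the scored
#'   universe with `size_bounds` first.
#' @param focus_alpha focus-gene threshold on min-p (default 0.01).
#' @param size_bounds inclusive set-size bounds after restriction.
#' @return data.frame of class `fisher_result`: `set`, `n_genes`,
#'   `overlap`, `ratio`, `fisher_p`.
#' @export
fisher_overrepresentation <- function(scores, gene_sets, focus_alpha = 0.01,
                                      size_bounds = c(10, 409)) {
  stopifnot(inherits(scores, "gene_scores"))
  universe <- scores$gene
  gsc <- restrict_sets(gene_sets, universe, size_bounds[1], size_bounds[2])
  focus <- scores$gene[scores$min_p < focus_alpha]
  N <- length(universe)
  nf <- length(focus)
  if (nf == 0L) message("no focus genes at alpha = ", focus_alpha,
                        "; all overrepresentation p-values are 1")
  res <- lapply(seq_along(gsc), function(i) {
    K <- length(gsc[[i]])
    ov <- sum(gsc[[i]] %in% focus)
    p <- if (nf == 0L) 1 else
      stats::phyper(ov - 1L, nf, N - nf, K, lower.tail = FALSE)
    data.frame(set = names(gsc)[i], n_genes = K, overlap = ov,
               ratio = ov / K, fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("fisher_result", "data.frame")
  out
}
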