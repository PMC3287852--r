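#' Construct a genotype matrix
#'
#' The central genotype container: an integer allele-dosage matrix
#' (samples x variants, values 0/1/2 counting copies of the alternate
#' allele) with per-variant metadata. The folded minor allele frequency
#' (MAF, always in \[0, 0.5\]) is computed from the dosages at
#' construction and can be recomputed at any time with [recompute_maf()].
#' Missing genotypes are not modelled: any `NA` dosage is an error, never
#' silently imputed, because imputation would corrupt downstream rare-allele
#' burden counts.
#'
#' @param dosages integer matrix, samples in rows, variants in columns;
#'   every entry must be 0, 1 or 2. Row and column names are used as sample
#'   and variant identifiers when `sample_ids`/`variant_ids` are missing.
#' @param sample_ids,variant_ids character vectors of unique identifiers.
#' @param population optional per-sample population (subpopulation /
#'   ethnicity) labels, coerced to factor.
#' @param chrom,pos,ref,alt optional per-variant VCF-style metadata; carried
#'   through file round-trips but never used by the statistics.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variant_ids`, `maf`, `population`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            variant_ids = colnames(dosages),
                            population = NULL,
                            chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages)) {
    stop("missing dosages are not supported (no imputation is performed)")
  }
  if (!all(dosages %in% c(0L, 1L, 2L))) {
    stop("dosages must all be 0, 1 or 2")
  }
  storage.mode(dosages) <- "integer"
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(dosages)), recycle0 = TRUE)
  if (is.null(variant_ids))
    variant_ids <- paste0("V", seq_len(ncol(dosages)), recycle0 = TRUE)
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (length(sample_ids) != nrow(dosages)) stop("sample_ids length mismatch")
  if (length(variant_ids) != ncol(dosages)) stop("variant_ids length mismatch")
  dimnames(dosages) <- list(sample_ids, variant_ids)
  if (!is.null(population)) {
    if (length(population) != nrow(dosages)) stop("population length mismatch")
    population <- as.factor(population)
  }
  g <- structure(
    list(dosages = dosages, sample_ids = sample_ids, variant_ids = variant_ids,
         maf = numeric(ncol(dosages)), population = population,
         chrom = chrom, pos = pos, ref = ref, alt = alt),
    class = "genotype_matrix"
  )
  g$maf <- recompute_maf(g)
  g
}

#' Folded minor allele frequency from dosages
#'
#' Computes the alternate-allele frequency per variant in the combined
#' sample and folds it to the minor allele: `min(f, 1 - f)`, so the result
#' is always in \[0, 0.5\]. Monomorphic variants have MAF 0.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, one folded MAF per variant.
#' @export
recompute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- unname(colMeans(g$dosages)) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF < 0.01: %.1f%%; MAF > 0.05: %.1f%%\n",
              100 * mean(x$maf < 0.01), 100 * mean(x$maf > 0.05)))
  if (!is.null(x$population)) {
    cat("  populations:", paste(sprintf("%s (%d)", levels(x$population),
                                        table(x$population)), collapse = ", "), "\n")
  }
  invisible(x)
}

# parse one GT field ("0/0", "0|1", ...) into an alt-allele count; the
# dialect is strictly diploid and biallelic, and missing calls are an error
.gt_to_dosage <- function(gt, line_no) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]", fixed = FALSE)
  vapply(alleles, function(a) {
    if (length(a) != 2L || anyNA(a) || any(a == ".") || any(a == ""))
      stop(sprintf("VCF line %d: missing or non-diploid genotype '%s'",
                   line_no, paste(a, collapse = "/")), call. = FALSE)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai < 0L) || any(ai > 1L))
      stop(sprintf("VCF line %d: allele index outside {0,1} in genotype",
                   line_no), call. = FALSE)
    sum(ai)
  }, integer(1))
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file containing biallelic records with GT fields into a
#' [genotype_matrix()]. Dosage is the count of ALT alleles. Variant order is
#' file order. Multiallelic records (a comma in ALT) and missing genotypes
#' are rejected with an error naming the offending line.
#'
#' @param path path to an uncompressed VCF file.
#' @return a [genotype_matrix()]; variant ids come from the ID column (or
#'   `chrom:pos` when ID is `.`).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty VCF file: ", path)
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1L)
    stop("malformed VCF: expected exactly one #CHROM header line in ", path)
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L)
    stop(sprintf("VCF line %d: header has no sample columns", hdr_idx))
  sample_ids <- hdr[-(1:9)]
  body_idx <- setdiff(seq_along(lines), seq_len(hdr_idx))
  body_idx <- body_idx[nzchar(lines[body_idx])]

  n <- length(sample_ids)
  m <- length(body_idx)
  dos <- matrix(0L, nrow = n, ncol = m)
  variant_ids <- character(m)
  chrom <- character(m); pos <- integer(m); ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    ln <- body_idx[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("VCF line %d: expected %d fields, found %d",
                   ln, length(hdr), length(f)))
    if (grepl(",", f[5], fixed = TRUE))
      stop(sprintf("VCF line %d: multiallelic record (ALT = '%s') rejected",
                   ln, f[5]))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_pos <- match("GT", fmt)
    if (is.na(gt_pos))
      stop(sprintf("VCF line %d: FORMAT lacks GT", ln))
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1), gt_pos)
    dos[, j] <- .gt_to_dosage(gt, ln)
    variant_ids[j] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    chrom[j] <- f[1]
    pos[j] <- suppressWarnings(as.integer(f[2]))
    ref[j] <- f[4]; alt[j] <- f[5]
  }
  genotype_matrix(dos, sample_ids = sample_ids, variant_ids = variant_ids,
                  chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Write genotypes to a VCF file
#'
#' Emits an uncompressed VCF 4.2 file with GT-only genotypes such that
#' `read_vcf(write_vcf(g, path))` reproduces the dosages, sample ids and
#' variant ids exactly. Heterozygotes are written `0/1`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- length(g$variant_ids)
  chrom <- if (is.null(g$chrom)) rep("1", m) else g$chrom
  pos <- if (is.null(g$pos)) seq_len(m) else g$pos
  ref <- if (is.null(g$ref)) rep("A", m) else g$ref
  alt <- if (is.null(g$alt)) rep("G", m) else g$alt
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pathenrich",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")), con)
  if (m > 0L) {
    gt <- matrix(gt_code[g$dosages + 1L], nrow = nrow(g$dosages))
    body <- vapply(seq_len(m), function(j) {
      paste(c(chrom[j], pos[j], g$variant_ids[j], ref[j], alt[j], ".", "PASS",
              ".", "GT", gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols; duplicate
#'   symbols within one set are removed. Symbols are case-sensitive exact
#'   strings; no alias resolution is attempted.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty when missing).
#' @return object of class `gene_set_collection`: the named list with a
#'   `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x)
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d (median %d)\n",
              length(x), min(sz), max(sz), as.integer(stats::median(sz))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols. Empty lines are skipped; duplicate
#' symbols within a line are removed with a warning; a line with fewer than
#' three fields is a parse error naming the line number.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()] preserving file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- vector("list", length(keep))
  nms <- character(length(keep))
  desc <- character(length(keep))
  for (i in seq_along(keep)) {
    f <- strsplit(lines[keep[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d: expected at least 3 tab-separated fields, found %d",
                   keep[i], length(f)))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d (%s): %d duplicate gene symbol(s) removed",
                      keep[i], f[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    nms[i] <- f[1]; desc[i] <- f[2]; sets[[i]] <- genes
  }
  names(sets) <- nms
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  desc <- attr(gsc, "descriptions")
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(gsc), function(i) {
    paste(c(names(gsc)[i], desc[i], gsc[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene-set collection to a gene universe
#'
#' Intersects each set with `universe` (preserving within-set order) and
#' drops sets whose restricted size falls outside `[min_size, max_size]`.
#' Restriction is idempotent: restricting twice to the same universe gives
#' the same collection.
#'
#' @param gsc a [gene_set_collection()].
#' @param universe character vector of gene symbols (typically the scored
#'   genes of an analysis).
#' @param min_size,max_size inclusive size bounds applied after restriction
#'   (defaults 10 and 409).
#' @return a restricted [gene_set_collection()].
#' @export
restrict_sets <- function(gsc, universe, min_size = 10, max_size = 409) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  res <- lapply(gsc, function(s) s[s %in% universe])
  keep <- lengths(res) >= min_size & lengths(res) <= max_size
  gene_set_collection(res[keep], attr(gsc, "descriptions")[keep])
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header; `#`-prefixed comment lines are skipped. The
#' first column must be `sample_id`; remaining columns are the trait(s) and
#' covariates, read as numeric where possible.
#'
#' @param path path to a TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(d)) stop("phenotype table lacks a 'sample_id' column")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in phenotype table")
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Write a phenotype/covariate table
#'
#' @param pheno data.frame with a `sample_id` column.
#' @param path output file path.
#' @param comment optional character vector written as `#`-prefixed header
#'   lines (provenance: tool version, seed).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path, comment = NULL) {
  stopifnot("sample_id" %in% names(pheno))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(pheno, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant-to-gene map
#'
#' Two-column TSV (`variant_id`, `gene`) assigning every variant to exactly
#' one gene.
#'
#' @param path path to a TSV file.
#' @return data.frame with character columns `variant_id` and `gene`.
#' @export
read_genemap <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("variant_id", "gene")
  if (!all(need %in% names(d)))
    stop("gene map must have columns 'variant_id' and 'gene'")
  d <- d[, need]
  if (anyDuplicated(d$variant_id)) stop("duplicate variant_id in gene map")
  d$variant_id <- as.character(d$variant_id)
  d$gene <- as.character(d$gene)
  d
}

#' Write a variant-to-gene map
#' @param genemap data.frame with columns `variant_id`, `gene`.
#' @param path output file path.
#' @param comment optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_genemap <- function(genemap, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(genemap[, c("variant_id", "gene")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene map against a genotype matrix
#'
#' Checks that every mapped variant exists in the genotype matrix; unknown
#' variants are an error listing the offenders.
#'
#' @param genemap data.frame from [read_genemap()].
#' @param g a [genotype_matrix()].
#' @return the validated gene map, invisibly.
#' @export
validate_genemap <- function(genemap, g) {
  missing <- setdiff(genemap$variant_id, g$variant_ids)
  if (length(missing) > 0L)
    stop("gene map refers to variants absent from the genotypes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else "")
  invisible(genemap)
}
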