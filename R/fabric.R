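#' Chi-square correction coefficient for a pooled CV
#'
#' Mid-point of the chi-square-based confidence estimate of a coefficient
#' of variation with `r` degrees of freedom:
#' \deqn{\frac{1}{2}\left(\sqrt{r/\chi^2_{0.975}(r)} +
#'   \sqrt{r/\chi^2_{0.025}(r)}\right)}
#' The coefficient is > 1 and decreases monotonically toward 1 as `r`
#' grows, inflating the raw CV of small replicate sets to an unbiased-ish
#' variability estimate.
#'
#' @param r Degrees of freedom (>= 1); vectorized.
#' @return Correction coefficient(s).
#' @export
rev_correction <- function(r) {
  if (any(r < 1)) stop("domain error: degrees of freedom must be >= 1")
  0.5 * (sqrt(r / stats::qchisq(0.975, r)) +
         sqrt(r / stats::qchisq(0.025, r)))
}

#' Fit the genomic fabric of one region
#'
#' Computes the three per-gene coordinates of the genomic fabric from a
#' region expression set: average expression level (AVE: mean over spots of
#' the mean over replicas), relative expression variability (REV: the
#' chi-square-corrected pooled coefficient of variation across biological
#' replicas, in percent), and spot-averaged replicate profiles from which
#' expression correlations (COR) with every other gene are derived.
#'
#' @param rs A `region_set` from [build_region_set()].
#' @return A `gene_fabric` object: list with `region`, `stats` (data frame
#'   gene/AVE/REV/R/r), `profiles` (gene-by-replica spot-averaged matrix),
#'   per-spot means `mu` and SDs `s` (aligned with `rs$gene`), `J`,
#'   `median_AVE`, `median_REV`, and the underlying region set `rs`.
#' @export
fabric <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  J <- rs$J
  mu <- rowMeans(rs$expr)
  if (any(mu == 0)) stop("data error: spot with zero mean expression")
  s <- sqrt(rowSums((rs$expr - mu)^2) / (J - 1))

  genes <- rs$genes
  R <- rs$R
  ave <- rowMeans(rs$profiles)[genes]
  cv2_sum <- rowsum((s / mu)^2, rs$gene)[genes, 1L]
  r <- J * R - 1L
  rev <- rev_correction(r) * sqrt(cv2_sum / R) * 100

  stats <- data.frame(gene = genes, AVE = unname(ave), REV = unname(rev),
                      R = unname(R), r = unname(r),
                      stringsAsFactors = FALSE)
  rownames(stats) <- genes
  structure(list(region = rs$region, stats = stats,
                 profiles = rs$profiles, mu = mu, s = s, J = J,
                 median_AVE = stats::median(stats$AVE),
                 median_REV = stats::median(stats$REV),
                 rs = rs),
            class = "gene_fabric")
}

#' @export
print.gene_fabric <- function(x, ...) {
  cat("Genomic fabric of region '", x$region, "'\n", sep = "")
  cat("  genes: ", nrow(x$stats), ", replicas: ", x$J, "\n", sep = "")
  cat("  median AVE: ", signif(x$median_AVE, 4),
      ", median REV: ", signif(x$median_REV, 4), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.gene_fabric <- function(object, ...) {
  st <- object$stats
  out <- list(region = object$region, n_genes = nrow(st), J = object$J,
              median_AVE = object$median_AVE,
              median_REV = object$median_REV,
              AVE_range = range(st$AVE), REV_range = range(st$REV),
              most_stable = st$gene[which.min(st$REV)],
              most_variable = st$gene[which.max(st$REV)])
  class(out) <- "summary.gene_fabric"
  out
}

#' @export
print.summary.gene_fabric <- function(x, ...) {
  cat("Genomic fabric of region '", x$region, "': ", x$n_genes,
      " genes, ", x$J, " replicas\n", sep = "")
  cat("  AVE: median ", signif(x$median_AVE, 4), ", range [",
      signif(x$AVE_range[1], 4), ", ", signif(x$AVE_range[2], 4),
      "]\n", sep = "")
  cat("  REV: median ", signif(x$median_REV, 4), "%, range [",
      signif(x$REV_range[1], 4), "%, ", signif(x$REV_range[2], 4),
      "%]\n", sep = "")
  cat("  most stable: ", x$most_stable,
      ", most variable: ", x$most_variable, "\n", sep = "")
  invisible(x)
}

resolve_fabric <- function(x) {
  if (inherits(x, "gene_fabric")) x
  else if (inherits(x, "region_set")) fabric(x)
  else stop("expected a region_set or gene_fabric object")
}

#' Average expression level of one gene
#'
#' Mean over a gene's redundant spots of the mean over the biological
#' replicas.
#'
#' @param rs A `region_set` or `gene_fabric`.
#' @param gene Gene symbol.
#' @export
compute_ave <- function(rs, gene) {
  fb <- resolve_fabric(rs)
  if (!gene %in% fb$stats$gene) stop("unknown gene: ", gene)
  fb$stats[gene, "AVE"]
}

#' Relative expression variability of one gene
#'
#' Chi-square-corrected pooled coefficient of variation across biological
#' replicas, in percent: the correction coefficient for `r = J * R - 1`
#' degrees of freedom times the root mean square of the per-spot replicate
#' CVs, times 100.
#'
#' @inheritParams compute_ave
#' @export
compute_rev <- function(rs, gene) {
  fb <- resolve_fabric(rs)
  if (!gene %in% fb$stats$gene) stop("unknown gene: ", gene)
  fb$stats[gene, "REV"]
}

#' Expression correlation of two genes
#'
#' In the default `"profile"` mode, the Pearson correlation between the two
#' genes' spot-averaged replicate profiles (length J); this reduces exactly
#' to the pooled double-sum form when both genes are probed by a single
#' spot, and guarantees COR(g, g) = 1. The `"literal"` mode evaluates the
#' pooled double-sum form directly (cross-spot deviation products in the
#' numerator, per-gene sums in the denominator); for redundantly probed
#' genes it is not bounded by 1 and does not self-correlate to 1, and is
#' provided for comparison only.
#'
#' @inheritParams compute_ave
#' @param gene_i,gene_g Gene symbols.
#' @param mode `"profile"` (default) or `"literal"`.
#' @return Correlation value; `NA` (flagged, with a warning) for a
#'   zero-variance profile.
#' @export
compute_cor <- function(rs, gene_i, gene_g, mode = c("profile", "literal")) {
  mode <- match.arg(mode)
  fb <- resolve_fabric(rs)
  for (g in c(gene_i, gene_g))
    if (!g %in% fb$stats$gene) stop("unknown gene: ", g)
  if (mode == "profile") {
    x <- fb$profiles[gene_i, ]
    y <- fb$profiles[gene_g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance profile; correlation undefined")
      return(NA_real_)
    }
    return(stats::cor(x, y))
  }
  rsid <- fb$rs
  ai <- rsid$expr[rsid$gene == gene_i, , drop = FALSE]
  ag <- rsid$expr[rsid$gene == gene_g, , drop = FALSE]
  di <- ai - fb$stats[gene_i, "AVE"]
  dg <- ag - fb$stats[gene_g, "AVE"]
  # cross-spot products: sum over spot pairs (ki, kg) and replicas j
  num <- sum(colSums(di) * colSums(dg))
  den <- sqrt(sum(di^2) * sum(dg^2))
  if (den == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  num / den
}

#' Full correlation matrix of a region's spot-averaged profiles
#'
#' @param fb A `gene_fabric` (or `region_set`).
#' @param genes Optional subset of genes.
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   genes yield `NA` rows/columns.
#' @export
cor_matrix <- function(fb, genes = NULL) {
  fb <- resolve_fabric(fb)
  p <- fb$profiles
  if (!is.null(genes)) p <- p[genes, , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(p)))
  diag(C) <- ifelse(apply(p, 1L, stats::sd) > 0, 1, NA_real_)
  C
}

standardized_profiles <- function(fb) {
  p <- fb$profiles
  m <- rowMeans(p)
  sd <- sqrt(rowSums((p - m)^2))
  z <- (p - m) / sd
  z[sd == 0, ] <- NA_real_
  z
}

#' Mean squared expression correlation of each gene with all others
#'
#' Computes, for every gene i, the mean over all other genes g of
#' COR(i, g)^2, in blocks so that the full gene-by-gene matrix is never
#' materialized. Genes with zero-variance profiles are excluded pairwise
#' (and get `NA` themselves).
#'
#' @param fb A `gene_fabric` (or `region_set`).
#' @param block_size Number of genes per block.
#' @return Named vector of mean squared correlations.
#' @export
mean_cor2 <- function(fb, block_size = 512L) {
  fb <- resolve_fabric(fb)
  z <- standardized_profiles(fb)
  n <- nrow(z)
  valid <- !is.na(z[, 1L])
  zv <- z[valid, , drop = FALSE]
  nv <- nrow(zv)
  out <- rep(NA_real_, n)
  names(out) <- rownames(z)
  if (nv >= 2L) {
    acc <- numeric(nv)
    for (start in seq(1L, nv, by = block_size)) {
      idx <- start:min(start + block_size - 1L, nv)
      C <- zv[idx, , drop = FALSE] %*% t(zv)
      acc[idx] <- rowSums(C^2) - 1  # remove the self term (always 1)
    }
    out[valid] <- acc / (nv - 1L)
  }
  out
}

#' Region-level fabric summaries
#'
#' Medians of AVE and REV over all retained genes of a region.
#'
#' @param rs A `region_set` or `gene_fabric`.
#' @return List with `region`, `median_AVE`, `median_REV`, `n_genes`.
#' @export
region_stats <- function(rs) {
  fb <- resolve_fabric(rs)
  list(region = fb$region, median_AVE = fb$median_AVE,
       median_REV = fb$median_REV, n_genes = nrow(fb$stats))
}

#' Write per-region gene statistics as TSV
#'
#' @param fb A `gene_fabric`.
#' @param path Output path.
#' @export
write_gene_stats <- function(fb, path) {
  utils::write.table(fb$stats[, c("gene", "AVE", "REV", "R")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
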