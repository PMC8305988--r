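#' Signed expression ratio
#'
#' Fold change between two positive means with the signed-ratio
#' convention: the larger mean over the smaller, negated when the second
#' (regulated) mean is below the first (reference), so |x| >= 1 always and
#' x = 1 at equality.
#'
#' @param mu_ref Reference-region mean (> 0); vectorized.
#' @param mu_reg Regulated-region mean (> 0); vectorized.
#' @export
fold_change <- function(mu_ref, mu_reg) {
  if (any(mu_ref <= 0) || any(mu_reg <= 0))
    stop("domain error: means must be positive")
  ifelse(mu_reg >= mu_ref, mu_reg / mu_ref, -mu_ref / mu_reg)
}

#' Variability-dependent fold-change cut-off
#'
#' The minimum absolute fold change a gene must exceed to be called
#' regulated, combining the gene's replicate variability in both regions:
#' \deqn{CUT = 1 + \frac{1}{100}\sqrt{2\,(REV_{ref}^2 + REV_{reg}^2)}}
#' so that noisy genes need larger fold changes.
#'
#' @param rev_ref,rev_reg REV values in percent (>= 0); vectorized.
#' @export
expression_cutoff <- function(rev_ref, rev_reg) {
  if (any(rev_ref < 0) || any(rev_reg < 0))
    stop("domain error: REV must be non-negative")
  1 + sqrt(2 * (rev_ref^2 + rev_reg^2)) / 100
}

#' Weighted individual gene regulation
#'
#' \deqn{WIR = AVE_{ref} \cdot \mathrm{sign}(x) \cdot (|x| - 1) \cdot (1 - p)}
#' A signed contribution in reference-expression units: zero for
#' unregulated genes (|x| = 1), damped toward zero as the regulation
#' p-value approaches 1, and proportional to the reference expression so
#' that abundant genes weigh more.
#'
#' @param ave_ref Reference-region average expression; vectorized.
#' @param x Signed expression ratio, |x| >= 1.
#' @param p Regulation probability in [0, 1].
#' @export
compute_wir <- function(ave_ref, x, p) {
  if (any(abs(x) < 1)) stop("domain error: |x| must be >= 1")
  if (any(p < 0 | p > 1)) stop("domain error: p must be in [0, 1]")
  ave_ref * sign(x) * (abs(x) - 1) * (1 - p)
}

# Vectorized Welch (heteroscedastic) two-sample test on paired rows of
# two matrices; returns two-sided p-values.
welch_rows <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
  p
}

#' Score differential regulation of all shared genes between two regions
#'
#' For every gene retained in both regions: the signed expression ratio
#' `x` of the region AVEs, the REV-dependent cut-off `CUT`, a
#' heteroscedastic (Welch) test of replicate mean equality per matching
#' spot with Bonferroni correction over the redundant spots
#' (p = min(1, R * min spot p)), the composite significance call
#' (|x| > CUT and p < `p_cut`), and the weighted individual regulation WIR.
#' Genes failing the composite criterion still receive x and WIR.
#'
#' @param ref,reg `region_set` or `gene_fabric` objects (reference first).
#' @param genes Optional subset; default all genes shared by both regions.
#' @param p_cut Significance level of the composite criterion.
#' @return A `regulation_table`: data frame with columns gene, x, CUT, p,
#'   significant, WIR, plus attribute `"contrast"`.
#' @export
regulate <- function(ref, reg, genes = NULL, p_cut = 0.05) {
  fref <- resolve_fabric(ref)
  freg <- resolve_fabric(reg)
  shared <- intersect(fref$stats$gene, freg$stats$gene)
  if (!is.null(genes)) {
    missing <- setdiff(genes, shared)
    if (length(missing))
      warning("not comparable (absent in one region): ",
              paste(missing, collapse = ", "))
    shared <- intersect(genes, shared)
  }
  if (!length(shared)) stop("no genes shared between the two regions")

  x <- fold_change(fref$stats[shared, "AVE"], freg$stats[shared, "AVE"])
  CUT <- expression_cutoff(fref$stats[shared, "REV"],
                           freg$stats[shared, "REV"])

  # pair spots of each gene across regions: by spot id where possible,
  # otherwise by order, up to the smaller redundancy
  rref <- fref$rs; rreg <- freg$rs
  iref <- split(seq_along(rref$gene), rref$gene)[shared]
  ireg <- split(seq_along(rreg$gene), rreg$gene)[shared]
  pair_ref <- integer(0); pair_reg <- integer(0); pair_gene <- character(0)
  for (k in seq_along(shared)) {
    a <- iref[[k]]; b <- ireg[[k]]
    m <- match(rref$spot[a], rreg$spot[b])
    if (any(!is.na(m))) {
      keep <- !is.na(m)
      a <- a[keep]; b <- b[m[keep]]
    } else {
      n <- min(length(a), length(b))
      a <- a[seq_len(n)]; b <- b[seq_len(n)]
    }
    pair_ref <- c(pair_ref, a); pair_reg <- c(pair_reg, b)
    pair_gene <- c(pair_gene, rep(shared[k], length(a)))
  }
  p_spot <- welch_rows(rref$expr[pair_ref, , drop = FALSE],
                       rreg$expr[pair_reg, , drop = FALSE])
  p_min <- tapply(p_spot, factor(pair_gene, levels = shared), min)
  n_spots <- tapply(pair_gene, factor(pair_gene, levels = shared), length)
  p <- pmin(1, as.vector(n_spots) * as.vector(p_min))

  out <- data.frame(gene = shared, x = x, CUT = CUT, p = p,
                    significant = abs(x) > CUT & p < p_cut,
                    WIR = compute_wir(fref$stats[shared, "AVE"], x, p),
                    stringsAsFactors = FALSE)
  rownames(out) <- shared
  attr(out, "contrast") <- paste0(fref$region, "->", freg$region)
  class(out) <- c("regulation_table", "data.frame")
  out
}

#' @export
print.regulation_table <- function(x, ...) {
  cat("Regulation table ", attr(x, "contrast"), ": ", nrow(x), " genes, ",
      sum(x$significant & x$x > 0), " up / ",
      sum(x$significant & x$x < 0), " down significantly regulated\n",
      sep = "")
  invisible(x)
}

#' Regulation record for a single gene
#'
#' @inheritParams regulate
#' @param gene Gene symbol (must be retained in both regions).
#' @return One-row `regulation_table`.
#' @export
test_regulation <- function(ref, reg, gene, p_cut = 0.05) {
  regulate(ref, reg, genes = gene, p_cut = p_cut)
}

#' Pathway-level regulation summary
#'
#' Percentages of significantly up- and down-regulated genes among the
#' gene-set members quantified in the contrast, and the weighted pathway
#' regulation WPR (by default the mean of |WIR| over those members).
#'
#' @param records A `regulation_table`.
#' @param gene_set Character vector of gene symbols (one pathway).
#' @param name Optional pathway label.
#' @param signed If `TRUE`, WPR averages signed WIR instead of |WIR|.
#' @return List with `pathway`, `n`, `percent_up`, `percent_down`, `WPR`.
#' @export
summarize_pathway <- function(records, gene_set, name = NULL,
                              signed = FALSE) {
  members <- intersect(gene_set, records$gene)
  n <- length(members)
  if (n == 0L)
    return(list(pathway = name, n = 0L, percent_up = NA_real_,
                percent_down = NA_real_, WPR = NA_real_))
  r <- records[members, , drop = FALSE]
  wir <- if (signed) r$WIR else abs(r$WIR)
  list(pathway = name, n = n,
       percent_up = 100 * sum(r$significant & r$x > 0) / n,
       percent_down = 100 * sum(r$significant & r$x < 0) / n,
       WPR = mean(wir))
}

#' Summarize every set of a gene-set collection
#'
#' @param records A `regulation_table`.
#' @param gene_sets Named list of gene symbol vectors (e.g. from
#'   [read_gmt()]). A set named `"ALL"` containing every quantified gene
#'   is appended automatically.
#' @inheritParams summarize_pathway
#' @return Data frame, one row per pathway.
#' @export
summarize_pathways <- function(records, gene_sets, signed = FALSE) {
  gene_sets <- c(gene_sets, list(ALL = records$gene))
  rows <- lapply(names(gene_sets), function(nm)
    as.data.frame(summarize_pathway(records, gene_sets[[nm]], nm, signed)))
  do.call(rbind, rows)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of gene symbol vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param gene_sets Named list of gene symbol vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
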