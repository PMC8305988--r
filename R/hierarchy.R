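#' Gene Commanding Height from its two factors
#'
#' Pure arithmetic form of the GCH score: `(median_rev / rev) *
#' exp(4 * mean_cor2)`. The first factor measures how much more tightly
#' the gene is controlled than the median gene of its region; the second
#' grows with the gene's average squared expression correlation with all
#' other genes.
#'
#' @param rev Gene REV in percent (> 0); vectorized.
#' @param median_rev Region median REV in percent.
#' @param mean_cor2 Mean squared correlation with all other genes, in
#'   [0, 1].
#' @export
gch_score <- function(rev, median_rev, mean_cor2) {
  if (any(rev < 0) || any(median_rev <= 0))
    stop("domain error: REV values must be positive")
  if (any(mean_cor2 < 0 | mean_cor2 > 1))
    stop("domain error: mean squared correlation must be in [0, 1]")
  (median_rev / rev) * exp(4 * mean_cor2)
}

#' Gene Commanding Height of one gene
#'
#' The GCH score combines a transcription-control factor (how much tighter
#' the gene's expression is controlled than the median gene:
#' median REV / REV_i) with an exponential coordination factor
#' exp(4 * mean over all other genes of COR^2):
#' \deqn{GCH_i = \frac{\langle REV\rangle}{REV_i}\,
#'   \exp\!\left(4\,\overline{COR_{ij}^2}\right)}
#' Genes with undefined correlation against gene i are excluded pairwise
#' from the mean.
#'
#' @param rs A `region_set` or `gene_fabric`.
#' @param gene Gene symbol.
#' @param mean_cor2 Optional precomputed [mean_cor2()] vector (avoids
#'   recomputing the full correlation structure per gene).
#' @return List with `gene`, `region`, `GCH`, `transcription_control`,
#'   `coordination_factor`, `mean_cor2`.
#' @export
compute_gch <- function(rs, gene, mean_cor2 = NULL) {
  fb <- resolve_fabric(rs)
  if (!gene %in% fb$stats$gene) stop("unknown gene: ", gene)
  if (is.null(mean_cor2)) {
    z <- standardized_profiles(fb)
    others <- setdiff(fb$stats$gene, gene)
    r <- as.vector(z[others, , drop = FALSE] %*% z[gene, ])
    mc2 <- mean(r^2, na.rm = TRUE)
  } else mc2 <- mean_cor2[[gene]]
  rev_i <- fb$stats[gene, "REV"]
  if (rev_i == 0) {
    warning("REV = 0 for ", gene, ": infinite transcription control")
    tc <- Inf
  } else tc <- fb$median_REV / rev_i
  cf <- exp(4 * mc2)
  list(gene = gene, region = fb$region, GCH = tc * cf,
       transcription_control = tc, coordination_factor = cf,
       mean_cor2 = mc2)
}

#' Gene hierarchy of a region and its Gene Master Regulator
#'
#' Scores every retained gene by Gene Commanding Height and ranks them in
#' descending order; ties are broken by lower REV, then alphabetically.
#' The rank-1 gene is the region's Gene Master Regulator (GMR). Genes with
#' REV = 0 (infinite transcription control) are excluded from the ranking
#' with a warning.
#'
#' @param rs A `region_set` or `gene_fabric`.
#' @param top_k Number of rows in the printed top table.
#' @param block_size Block size for the correlation accumulation.
#' @return A `gene_hierarchy` object: list with `region`, `table` (gene,
#'   GCH, transcription_control, coordination_factor, mean_cor2, REV,
#'   rank), `gmr`, `top_k`.
#' @export
build_hierarchy <- function(rs, top_k = 25L, block_size = 512L) {
  fb <- resolve_fabric(rs)
  mc2 <- mean_cor2(fb, block_size = block_size)
  st <- fb$stats
  tc <- fb$median_REV / st$REV
  bad <- !is.finite(tc)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with REV = 0 excluded from ranking")
  }
  cf <- exp(4 * mc2[st$gene])
  tab <- data.frame(gene = st$gene, GCH = tc * cf,
                    transcription_control = tc,
                    coordination_factor = unname(cf),
                    mean_cor2 = unname(mc2[st$gene]),
                    REV = st$REV, stringsAsFactors = FALSE)
  tab <- tab[!bad & !is.na(tab$GCH), , drop = FALSE]
  ord <- order(-tab$GCH, tab$REV, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- tab$gene
  if (nrow(tab) < top_k)
    warning("fewer than top_k = ", top_k, " rankable genes")
  structure(list(region = fb$region, table = tab, gmr = tab$gene[1L],
                 top_k = as.integer(top_k)),
            class = "gene_hierarchy")
}

#' @export
print.gene_hierarchy <- function(x, ...) {
  cat("Gene hierarchy, region '", x$region, "': GMR = ", x$gmr,
      " (GCH = ", signif(x$table$GCH[1L], 4), ")\n", sep = "")
  k <- min(x$top_k, nrow(x$table))
  print(format(x$table[seq_len(k), c("gene", "GCH", "rank")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' Top-k slice of a hierarchy
#'
#' @param h A `gene_hierarchy`.
#' @param k Number of rows (default the hierarchy's `top_k`).
#' @export
top_genes <- function(h, k = h$top_k) {
  utils::head(h$table, k)
}

#' Restoration bookkeeping for a planned overexpression
#'
#' Given, for a set of genes significantly coordinated with a target and
#' significantly regulated in the cancer region, the coordination class
#' with the target and the observed regulation direction, predicts the
#' direction each gene moves when the target is overexpressed (up for
#' synergistic partners, down for antagonistic ones) and counts how many
#' are expected to restore their normal expression, i.e. move against
#' their cancer regulation.
#'
#' @param class Character vector: `"synergistic"` or `"antagonistic"`.
#' @param direction Character vector: observed regulation, `"up"` or
#'   `"down"`.
#' @return List with per-gene `table` (class, direction, predicted,
#'   restored) and `totals` (restored, considered, fraction).
#' @export
restoration_summary <- function(class, direction) {
  stopifnot(length(class) == length(direction),
            all(class %in% c("synergistic", "antagonistic")),
            all(direction %in% c("up", "down")))
  predicted <- ifelse(class == "synergistic", "up", "down")
  restored <- predicted != direction
  n <- length(class)
  list(table = data.frame(class = class, direction = direction,
                          predicted = predicted, restored = restored,
                          stringsAsFactors = FALSE),
       totals = list(restored = sum(restored), considered = n,
                     fraction = if (n) sum(restored) / n else NA_real_))
}

#' Forecast the transcriptomic consequences of overexpressing a gene
#'
#' Restricts a panel to genes both significantly coordinated with the
#' target (synergistic or antagonistic by [classify_pair()]) and
#' significantly regulated in the contrast, then applies
#' [restoration_summary()]: synergistic partners are predicted to go up
#' with the target, antagonistic ones down, and a gene is counted as
#' restored when that prediction opposes its observed cancer regulation.
#'
#' @param rs `region_set` or `gene_fabric` of the cancer region.
#' @param target Target gene (must be retained).
#' @param records `regulation_table` for the reference-to-region contrast.
#' @param panel Genes to consider (default: all genes in `records`).
#' @param alpha,indep_band Passed to [classify_pair()].
#' @return A `manipulation_forecast` object: list with `target`, `region`,
#'   `table` (gene, COR, class, x, direction, predicted, restored) and
#'   `totals`.
#' @export
forecast_overexpression <- function(rs, target, records, panel = NULL,
                                    alpha = 0.05, indep_band = 0.05) {
  fb <- resolve_fabric(rs)
  if (!target %in% fb$stats$gene) stop("target not retained: ", target)
  if (is.null(panel)) panel <- records$gene
  panel <- setdiff(intersect(panel, records$gene), target)
  panel <- intersect(panel, fb$stats$gene)

  reg <- records[records$gene %in% panel & records$significant, ,
                 drop = FALSE]
  if (nrow(reg)) {
    hp <- hub_profile(fb, target, reg$gene, alpha, indep_band)
    rec <- hp$records
    coordinated <- rec$class %in% c("synergistic", "antagonistic")
    rec <- rec[coordinated, , drop = FALSE]
  } else rec <- NULL
  if (is.null(rec) || nrow(rec) == 0L) {
    tab <- data.frame(gene = character(0), COR = numeric(0),
                      class = character(0), x = numeric(0),
                      direction = character(0), predicted = character(0),
                      restored = logical(0))
    totals <- list(restored = 0L, considered = 0L, fraction = NA_real_)
  } else {
    direction <- ifelse(records[rec$gene_g, "x"] > 0, "up", "down")
    rsum <- restoration_summary(rec$class, direction)
    tab <- data.frame(gene = rec$gene_g, COR = rec$COR,
                      class = rec$class, x = records[rec$gene_g, "x"],
                      direction = direction,
                      predicted = rsum$table$predicted,
                      restored = rsum$table$restored,
                      stringsAsFactors = FALSE)
    totals <- rsum$totals
  }
  structure(list(target = target, region = fb$region,
                 contrast = attr(records, "contrast"),
                 table = tab, totals = totals),
            class = "manipulation_forecast")
}

#' @export
print.manipulation_forecast <- function(x, ...) {
  cat("Overexpression forecast for ", x$target, " in region '",
      x$region, "' (contrast ", x$contrast, ")\n", sep = "")
  t <- x$totals
  if (t$considered == 0L) {
    cat("  no significantly coordinated and regulated genes\n")
  } else {
    cat("  ", t$restored, " of ", t$considered,
        " coordinated regulated genes predicted to restore (",
        round(100 * t$fraction), "%)\n", sep = "")
  }
  invisible(x)
}
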