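#' Critical Pearson correlation at a given significance level
#'
#' The two-sided significance boundary of a Pearson correlation on `n`
#' paired observations via the t-transform with n - 2 degrees of freedom.
#' With n = 4 replicas and alpha = 0.05 the boundary is |r| = 0.950.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Two-sided significance level.
#' @export
pearson_threshold <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("domain error: need at least 3 paired observations")
  t <- stats::qt(1 - alpha / 2, n - 2)
  t / sqrt(t^2 + (n - 2))
}

cor_pvalue <- function(r, n) {
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, n - 2)
}

classify_cor <- function(r, n, alpha, indep_band) {
  cls <- rep("undecided", length(r))
  p <- cor_pvalue(r, n)
  cls[!is.na(r) & p < alpha & r > 0] <- "synergistic"
  cls[!is.na(r) & p < alpha & r < 0] <- "antagonistic"
  cls[!is.na(r) & p >= alpha & abs(r) <= indep_band] <- "independent"
  cls[is.na(r)] <- "undecided"
  cls
}

coordination_record <- function(gene_i, gene_g, region, r, n, alpha,
                                indep_band) {
  data.frame(gene_i = gene_i, gene_g = gene_g, region = region,
             COR = r, n_points = n,
             p = ifelse(is.na(r), NA_real_, cor_pvalue(r, n)),
             class = classify_cor(r, n, alpha, indep_band),
             stringsAsFactors = FALSE)
}

#' Classify the expression coordination of a gene pair
#'
#' Pearson correlation of the two genes' spot-averaged replicate profiles,
#' tested two-sided at `alpha` via the t-transform: significant positive
#' correlation is synergism, significant negative is antagonism; a
#' non-significant correlation within `indep_band` of zero is
#' independence; anything else is undecided. Zero-variance profiles give
#' an undecided record with `COR = NA`.
#'
#' @param rs A `region_set` or `gene_fabric`.
#' @param gene_i,gene_g Gene symbols.
#' @param alpha Two-sided significance level.
#' @param indep_band Half-width of the independence band around zero.
#' @return One-row coordination record (gene_i, gene_g, region, COR,
#'   n_points, p, class).
#' @export
classify_pair <- function(rs, gene_i, gene_g, alpha = 0.05,
                          indep_band = 0.05) {
  fb <- resolve_fabric(rs)
  r <- suppressWarnings(compute_cor(fb, gene_i, gene_g))
  coordination_record(gene_i, gene_g, fb$region, r, fb$J, alpha, indep_band)
}

#' Coordination census of a gene panel
#'
#' Classifies every unordered pair of panel genes and tabulates the
#' percentages of synergistic, antagonistic, independent and undecided
#' pairs (a partition summing to 100).
#'
#' @inheritParams classify_pair
#' @param panel Character vector of at least 2 retained genes.
#' @return A `coordination_census` object: list with `region`, `panel`,
#'   `percent` (named numeric), `pairs` (records of all unordered pairs),
#'   and the triangular class matrix `class_matrix`.
#' @export
coordination_census <- function(rs, panel, alpha = 0.05,
                                indep_band = 0.05) {
  fb <- resolve_fabric(rs)
  panel <- unique(panel)
  if (length(panel) < 2L) stop("panel must contain at least 2 genes")
  missing <- setdiff(panel, fb$stats$gene)
  if (length(missing)) stop("panel genes not retained: ",
                            paste(missing, collapse = ", "))
  C <- cor_matrix(fb, panel)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  rec <- coordination_record(panel[idx[, 1L]], panel[idx[, 2L]],
                             fb$region, C[idx], fb$J, alpha, indep_band)
  cm <- matrix(NA_character_, length(panel), length(panel),
               dimnames = list(panel, panel))
  cm[upper.tri(cm)] <- rec$class
  pct <- 100 * table(factor(rec$class,
                            levels = c("synergistic", "antagonistic",
                                       "independent", "undecided"))) /
    nrow(rec)
  structure(list(region = fb$region, panel = panel,
                 percent = stats::setNames(as.numeric(pct), names(pct)),
                 pairs = rec, class_matrix = cm),
            class = "coordination_census")
}

#' @export
print.coordination_census <- function(x, ...) {
  cat("Coordination census, region '", x$region, "' (",
      length(x$panel), " genes, ", nrow(x$pairs), " pairs)\n", sep = "")
  for (nm in names(x$percent))
    cat(sprintf("  %-13s %6.2f%%\n", nm, x$percent[[nm]]))
  invisible(x)
}

#' In-phase / anti-phase expression across two regions
#'
#' Correlates gene_i's spot-averaged profile in region P with gene_g's
#' profile in region Q over paired replicas (default pairing: by quarter
#' index, i.e. replica 1 of P with replica 1 of Q, and so on). Significant
#' positive correlation is in-phase, significant negative anti-phase,
#' using the same thresholds as [classify_pair()].
#'
#' @param rsP,rsQ `region_set` or `gene_fabric` objects.
#' @param gene_i Gene in region P.
#' @param gene_g Gene in region Q (default: the same gene).
#' @param pairing Integer vector mapping each replica of P to a replica of
#'   Q; must be a complete pairing.
#' @inheritParams classify_pair
#' @return One-row record with `class` relabelled `in-phase` /
#'   `anti-phase` for significant pairs.
#' @export
interregion_phase <- function(rsP, rsQ, gene_i, gene_g = gene_i,
                              pairing = NULL, alpha = 0.05,
                              indep_band = 0.05) {
  fP <- resolve_fabric(rsP)
  fQ <- resolve_fabric(rsQ)
  if (is.null(pairing)) pairing <- seq_len(fP$J)
  if (length(pairing) != fP$J || anyNA(pairing) ||
      length(unique(pairing)) != fP$J || any(pairing > fQ$J))
    stop("incomplete replica pairing")
  if (!gene_i %in% fP$stats$gene) stop("unknown gene in P: ", gene_i)
  if (!gene_g %in% fQ$stats$gene) stop("unknown gene in Q: ", gene_g)
  x <- fP$profiles[gene_i, ]
  y <- fQ$profiles[gene_g, pairing]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  rec <- coordination_record(gene_i, gene_g,
                             paste0(fP$region, "~", fQ$region),
                             r, fP$J, alpha, indep_band)
  rec$class[rec$class == "synergistic"] <- "in-phase"
  rec$class[rec$class == "antagonistic"] <- "anti-phase"
  rec
}

#' Coordination of a hub gene with a target panel
#'
#' Classifies the hub against each target (the hub-self pair is skipped if
#' present) and reports synergism/antagonism counts.
#'
#' @inheritParams classify_pair
#' @param hub Hub gene symbol.
#' @param targets Character vector of target genes.
#' @return List with `records` (one row per target) and `counts`
#'   (synergisms, antagonisms).
#' @export
hub_profile <- function(rs, hub, targets, alpha = 0.05,
                        indep_band = 0.05) {
  fb <- resolve_fabric(rs)
  targets <- setdiff(unique(targets), hub)
  if (!length(targets))
    return(list(records = data.frame(gene_i = character(0),
                                     gene_g = character(0),
                                     region = character(0),
                                     COR = numeric(0),
                                     n_points = integer(0),
                                     p = numeric(0),
                                     class = character(0)),
                counts = c(synergisms = 0L, antagonisms = 0L)))
  rec <- do.call(rbind, lapply(targets, function(g)
    classify_pair(fb, hub, g, alpha, indep_band)))
  list(records = rec,
       counts = c(synergisms = sum(rec$class == "synergistic"),
                  antagonisms = sum(rec$class == "antagonistic")))
}

#' Similarity of two genes' coordination profiles
#'
#' The coordination profile of a gene is the ordered vector of its
#' correlations with every other retained gene. The similarity of two
#' genes is the Pearson correlation between their profiles over the panel
#' of all other genes (both query genes excluded). Under the see-saw
#' substitution logic, a similarity near +1 means manipulating either gene
#' should propagate alike through the network, near -1 oppositely.
#'
#' @inheritParams classify_pair
#' @return Similarity in [-1, 1], or `NA` (with warning) when a profile is
#'   constant.
#' @export
profile_similarity <- function(rs, gene_i, gene_g) {
  fb <- resolve_fabric(rs)
  panel <- setdiff(fb$stats$gene, c(gene_i, gene_g))
  if (length(panel) < 3L) stop("panel too small for profile similarity")
  C <- cor_matrix(fb, c(gene_i, gene_g, panel))
  vi <- C[gene_i, panel]
  vg <- C[gene_g, panel]
  ok <- !is.na(vi) & !is.na(vg)
  if (stats::sd(vi[ok]) == 0 || stats::sd(vg[ok]) == 0) {
    warning("constant coordination profile; similarity undefined")
    return(NA_real_)
  }
  stats::cor(vi[ok], vg[ok])
}

#' Write coordination records as a TSV edge list
#'
#' @param records Coordination records (e.g. `census$pairs`).
#' @param path Output path.
#' @export
write_edge_list <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
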