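#' Parse a spot-level expression table
#'
#' Reads a tab-separated table of microarray spot records, one row per
#' (spot, biological replica), with foreground and background fluorescence
#' and optional quality flags. Column names are resolved through `dialect`,
#' so tables exported under different headers can be ingested without
#' rewriting them.
#'
#' @param path Path to a TSV file.
#' @param dialect Named list mapping canonical field names (`spot_id`,
#'   `gene`, `replica`, `fg`, `bg`, `saturated`, `corrupted`) to the column
#'   names used in the file. Fields absent from the list keep their
#'   canonical name. `gene`, `saturated` and `corrupted` columns are
#'   optional in the file; `spot_id`, `replica`, `fg` and `bg` are
#'   mandatory.
#' @return A `spot_table`: a data frame with columns `spot_id`, `gene`
#'   (empty string for control spots), `replica`, `fg`, `bg`, `saturated`,
#'   `corrupted`.
#' @export
parse_spot_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  dialect <- utils::modifyList(default_dialect(), as.list(dialect))
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  mandatory <- c("spot_id", "replica", "fg", "bg")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw))
      stop("configuration error: mandatory column '", dialect[[f]],
           "' (field ", f, ") missing from ", path)
  }
  get_col <- function(f, default) {
    cn <- dialect[[f]]
    if (cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  num_col <- function(f) {
    cn <- dialect[[f]]
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error: non-numeric '", cn, "' value in row(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path)
    v
  }
  flag_col <- function(f) {
    v <- get_col(f, "FALSE")
    v %in% c("TRUE", "true", "T", "1", "yes")
  }
  replica <- suppressWarnings(as.integer(get_col("replica", NA)))
  if (anyNA(replica))
    stop("parse error: non-integer replica value in row(s) ",
         paste(which(is.na(replica)) + 1L, collapse = ", "), " of ", path)
  out <- data.frame(
    spot_id   = get_col("spot_id", NA),
    gene      = get_col("gene", ""),
    replica   = replica,
    fg        = num_col("fg"),
    bg        = num_col("bg"),
    saturated = flag_col("saturated"),
    corrupted = flag_col("corrupted"),
    stringsAsFactors = FALSE
  )
  if (any(out$fg < 0) || any(out$bg < 0))
    stop("parse error: negative fluorescence values in ", path)
  as_spot_table(out)
}

default_dialect <- function() {
  list(spot_id = "spot_id", gene = "gene", replica = "replica",
       fg = "fg", bg = "bg", saturated = "saturated",
       corrupted = "corrupted")
}

as_spot_table <- function(df) {
  class(df) <- c("spot_table", "data.frame")
  df
}

#' @export
print.spot_table <- function(x, ...) {
  cat("Spot table: ", length(unique(x$spot_id)), " spots x ",
      length(unique(x$replica)), " replicas (",
      nrow(x), " records, ",
      length(setdiff(unique(x$gene), "")), " genes)\n", sep = "")
  invisible(x)
}

#' Quality-filter spot records
#'
#' Removes records flagged saturated or corrupted, and records whose
#' fluorescence foreground is less than twice the fluorescence background.
#' A removal log (spot, replica, reason) is attached as attribute
#' `"removal_log"`.
#'
#' @param t A `spot_table`.
#' @return The filtered `spot_table`.
#' @export
filter_spots <- function(t) {
  stopifnot(inherits(t, "spot_table"))
  reason <- rep(NA_character_, nrow(t))
  reason[t$fg < 2 * t$bg] <- "fg<2bg"
  reason[t$corrupted] <- "corrupted"
  reason[t$saturated] <- "saturated"
  drop <- !is.na(reason)
  log <- data.frame(spot_id = t$spot_id[drop], replica = t$replica[drop],
                    reason = reason[drop], stringsAsFactors = FALSE)
  out <- t[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all spot records removed by quality filters")
  attr(out, "removal_log") <- log
  as_spot_table(out)
}

#' Iterative normalization of replica arrays
#'
#' Defines the signal of each record as background-subtracted fluorescence
#' (floored at `epsilon` to keep ratios finite) and brings the replica
#' arrays onto a common scale, anchored to the median background-subtracted
#' signal of all spots. Each round alternates an inter-array adjustment —
#' every array is divided by the median of its spot-wise ratios to the
#' per-spot geometric-mean reference (the paired median-of-ratios factor,
#' far less noisy than matching marginal medians, so genes with very low
#' replicate variability keep it) — with an intra-level adjustment that
#' restores the grand median of the signal. Rounds repeat until the
#' per-array factors stop changing.
#'
#' @param t A filtered `spot_table`.
#' @param tol Convergence tolerance on the relative change of the per-array
#'   scale factors.
#' @param max_iter Maximum number of alternation rounds.
#' @param epsilon Signal floor in fluorescence units.
#' @return The `spot_table` with an added `signal` column; attributes
#'   `"scale_factors"` (cumulative per-array factors) and `"iterations"`.
#' @export
normalize_arrays <- function(t, tol = 1e-6, max_iter = 100L, epsilon = 1.0) {
  stopifnot(inherits(t, "spot_table"))
  if (nrow(t) == 0L) stop("data error: empty spot table")
  raw <- t$fg - t$bg
  arrays <- sort(unique(t$replica))
  J <- length(arrays)
  for (j in arrays) {
    if (all(raw[t$replica == j] <= 0))
      stop("data error: replica ", j, " has no positive signals")
  }
  signal <- pmax(raw, epsilon)
  anchor <- stats::median(signal)
  # spots present in every array give the paired reference
  counts <- table(t$spot_id)
  complete <- names(counts)[counts == J]
  scale <- stats::setNames(rep(1, J), arrays)
  iter <- 0L
  delta <- Inf
  repeat {
    iter <- iter + 1L
    new_scale <- scale
    if (length(complete) >= 3L) {
      sel <- t$spot_id %in% complete
      ls <- log(signal[sel])
      ref <- rowsum(ls, t$spot_id[sel])[, 1L] / J     # log geometric mean
      ratio <- ls - ref[t$spot_id[sel]]
      f <- exp(tapply(ratio, factor(t$replica[sel], levels = arrays),
                      stats::median))
    } else {
      # no paired spots: fall back to matching marginal medians
      m <- tapply(signal, factor(t$replica, levels = arrays),
                  stats::median)
      f <- m / exp(mean(log(m)))
    }
    signal <- signal / f[as.character(t$replica)]
    g <- anchor / stats::median(signal)
    signal <- signal * g
    new_scale <- scale * g / f
    delta <- max(abs(new_scale / scale - 1))
    scale <- new_scale
    if (delta < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && delta >= tol)
    warning("normalization did not converge: residual ", signif(delta, 3))
  t$signal <- signal
  attr(t, "scale_factors") <- scale
  attr(t, "iterations") <- iter
  as_spot_table(t)
}

#' Assemble a region expression set
#'
#' Groups normalized spot records by gene symbol, drops control spots
#' (empty gene symbol) into a technical-replica store, and enforces replica
#' completeness: a (gene, spot) pair is retained only if all replicas
#' survived filtering. Genes left without any complete spot are excluded
#' and logged.
#'
#' @param t A normalized `spot_table` (from [normalize_arrays()]); if it
#'   has no `signal` column the floored background-subtracted fluorescence
#'   is used directly.
#' @param region_label Region label (e.g. `"N"`, `"A"`).
#' @param median_units If `TRUE`, rescale all values so that the median
#'   per-gene average expression equals 1 (expression in multiples of the
#'   median gene).
#' @param epsilon Signal floor used when `t` is not normalized.
#' @return A `region_set` object: list with the expression matrix `expr`
#'   ((gene, spot) rows by replica columns), row annotations `gene` and
#'   `spot`, spot counts `R`, replica count `J`, spot-averaged per-gene
#'   `profiles`, the control-spot matrix `controls`, and a `dropped` log.
#' @export
build_region_set <- function(t, region_label, median_units = FALSE,
                             epsilon = 1.0) {
  stopifnot(inherits(t, "spot_table"))
  if (is.null(t$signal)) t$signal <- pmax(t$fg - t$bg, epsilon)
  replicas <- sort(unique(t$replica))
  J <- length(replicas)
  if (J < 2L) stop("data error: fewer than 2 replicas; variance undefined")

  key <- paste(t$gene, t$spot_id, sep = "\r")
  counts <- table(key)
  complete <- names(counts)[counts == J]
  keep <- key %in% complete
  tt <- t[keep, , drop = FALSE]
  kk <- key[keep]

  ord <- order(kk, tt$replica)
  tt <- tt[ord, , drop = FALSE]
  ukey <- unique(kk[ord])
  expr <- matrix(tt$signal, ncol = J, byrow = TRUE)
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  spot <- vapply(parts, `[`, "", 2L)
  colnames(expr) <- replicas
  rownames(expr) <- spot

  is_ctrl <- gene == ""
  controls <- expr[is_ctrl, , drop = FALSE]
  expr <- expr[!is_ctrl, , drop = FALSE]
  gene <- gene[!is_ctrl]
  spot <- spot[!is_ctrl]

  all_genes <- setdiff(unique(t$gene), "")
  dropped <- setdiff(all_genes, unique(gene))
  if (nrow(expr) == 0L) stop("data error: no complete (gene, spot) pairs")

  R <- table(gene)
  genes <- sort(unique(gene))
  R <- stats::setNames(as.integer(R[genes]), genes)
  sums <- rowsum(expr, gene)
  profiles <- sums / as.vector(R[rownames(sums)])
  profiles <- profiles[genes, , drop = FALSE]

  scale <- 1
  if (median_units) {
    ave <- rowMeans(profiles)
    scale <- stats::median(ave)
    expr <- expr / scale
    profiles <- profiles / scale
    controls <- controls / scale
  }

  structure(list(region = region_label, expr = expr, gene = gene,
                 spot = spot, genes = genes, R = R, J = J,
                 profiles = profiles, controls = controls,
                 dropped = dropped, median_scale = scale),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region expression set '", x$region, "': ", length(x$genes),
      " genes, ", nrow(x$expr), " spots x ", x$J, " replicas",
      if (length(x$dropped)) paste0(" (", length(x$dropped),
                                    " genes dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Read a region set from a spot TSV in one call
#'
#' Convenience wrapper chaining [parse_spot_table()], [filter_spots()],
#' [normalize_arrays()] and [build_region_set()].
#'
#' @inheritParams parse_spot_table
#' @inheritParams build_region_set
#' @param ... Passed to [normalize_arrays()].
#' @export
read_region_set <- function(path, region_label, dialect = list(),
                            median_units = FALSE, ...) {
  t <- parse_spot_table(path, dialect)
  t <- filter_spots(t)
  t <- normalize_arrays(t, ...)
  build_region_set(t, region_label, median_units = median_units)
}

#' Write a region set as TSV plus a JSON provenance sidecar
#'
#' @param rs A `region_set`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param provenance Optional named list merged into the sidecar.
#' @export
write_region_set <- function(rs, path, provenance = list()) {
  df <- data.frame(gene = rep(rs$gene, rs$J),
                   spot = rep(rs$spot, rs$J),
                   replica = rep(colnames(rs$expr), each = nrow(rs$expr)),
                   value = as.vector(rs$expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(region = rs$region, genes = length(rs$genes),
                 replicas = rs$J, median_scale = rs$median_scale,
                 dropped_genes = rs$dropped), provenance)
  jsonlite::write_json(side, sub("\\.tsv$", "", path) |> paste0(".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ingest a GEO series-matrix file as a spot table
#'
#' Minimal convenience reader for GEO `*_series_matrix.txt` files: the
#' sample columns are taken as replicas in order of appearance and the
#' matrix values as already background-subtracted signals (fg = value,
#' bg = 0, no quality flags). Probe identifiers become spot ids; a
#' probe-to-gene map can be supplied to fill gene symbols.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @param gene_map Optional named character vector mapping probe id to
#'   gene symbol.
#' @return A `spot_table`.
#' @export
read_geo_series_matrix <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stop("series matrix not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L)
    stop("parse error: no series matrix table in ", path)
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           check.names = FALSE)
  probes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  J <- ncol(vals)
  genes <- if (is.null(gene_map)) rep("", length(probes)) else {
    g <- unname(gene_map[probes]); g[is.na(g)] <- ""; g
  }
  as_spot_table(data.frame(
    spot_id = rep(probes, J),
    gene = rep(genes, J),
    replica = rep(seq_len(J), each = length(probes)),
    fg = as.vector(vals),
    bg = 0,
    saturated = FALSE,
    corrupted = FALSE,
    stringsAsFactors = FALSE
  ))
}
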