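#' Configuration of a synthetic multi-region study
#'
#' Defines a simulated multi-region, multi-replicate spot-level expression
#' study with known ground truth. The defaults emulate the sampling design
#' the package targets: four regions (one reference "N", three lesions),
#' four biological replicas per region, mostly single-spot genes with a
#' minority probed redundantly by up to 11 spots, log-normal expression
#' with per-gene CVs spanning roughly 0.3% to 190%, block-correlated gene
#' modules, one planted low-variability / highly coordinated master
#' regulator per region, and planted fold changes between regions.
#'
#' @param n_genes Number of genes.
#' @param regions Region labels; the first is the reference.
#' @param J Biological replicas per region.
#' @param redundant_frac Fraction of genes probed by more than one spot.
#' @param max_spots Maximum spots per redundant gene.
#' @param mean_range Range of true mean signals (fluorescence a.u.),
#'   sampled log-uniformly.
#' @param cv_range Truncation bounds of the per-gene CV distribution.
#' @param cv_meanlog,cv_sdlog Parameters of the log-normal law the
#'   per-gene CVs are drawn from (truncated to `cv_range`); the defaults
#'   give a median CV of 15% with a thin low tail, so observed
#'   chi-square-corrected variabilities span roughly 0.3% (the planted
#'   GMR) to beyond 190%.
#' @param module_spec List of `list(size =, cor =)` module definitions;
#'   module 1 is the "largest correlated module" that hosts each region's
#'   planted GMR.
#' @param gmr_cv CV given to the planted GMR in its own region.
#' @param gmr_spots Spot redundancy of the planted GMR genes (key genes
#'   on expression arrays are often probed by many spots; redundancy also
#'   tightens the GMR's variability estimate the way it does for real
#'   redundantly probed genes).
#' @param gmr_genes Optional named character vector (region -> gene id);
#'   defaults to one reserved gene per region.
#' @param regulation_spec Data frame (gene, region, fold) of planted
#'   signed fold changes versus the reference (positive multiply, negative
#'   divide); `NULL` plants `n_regulated` genes at `default_fold` in each
#'   non-reference region.
#' @param n_regulated,default_fold Defaults used when `regulation_spec` is
#'   `NULL`.
#' @param regulated_cv CV given (in every region) to the planted regulated
#'   genes, so their detection power is a property of the configuration.
#' @param spot_jitter CV of the multiplicative spot-level jitter around
#'   the gene signal.
#' @param bg_range Range of the uniform background fluorescence (a.u.).
#' @param corrupted_rate Fraction of spot records randomly flagged
#'   corrupted (planted GMR and regulated genes are kept clean so the
#'   ground truth stays well defined).
#' @param n_controls Number of control spots (empty gene symbol).
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_genes = 2000L,
                         regions = c("N", "A", "B", "C"),
                         J = 4L,
                         redundant_frac = 0.10,
                         max_spots = 11L,
                         mean_range = c(120, 20000),
                         cv_range = c(0.05, 1.9),
                         cv_meanlog = log(0.15),
                         cv_sdlog = 0.8,
                         module_spec = list(list(size = 50L, cor = 0.9),
                                            list(size = 30L, cor = 0.8),
                                            list(size = 20L, cor = 0.7)),
                         gmr_cv = 0.003,
                         gmr_spots = 11L,
                         gmr_genes = NULL,
                         regulation_spec = NULL,
                         n_regulated = 40L,
                         default_fold = 4,
                         regulated_cv = 0.05,
                         spot_jitter = 0.02,
                         bg_range = c(20, 60),
                         corrupted_rate = 0.01,
                         n_controls = 24L,
                         seed = 1L) {
  stopifnot(n_genes >= 10L, J >= 2L, length(regions) >= 1L,
            all(cv_range > 0), gmr_cv > 0)
  sizes <- vapply(module_spec, function(m) as.integer(m$size), 0L)
  cors <- vapply(module_spec, function(m) as.numeric(m$cor), 0)
  if (sum(sizes) + length(regions) > n_genes)
    stop("configuration error: module sizes exceed n_genes")
  if (any(abs(cors) >= 1))
    stop("configuration error: |module correlations| must be < 1")
  if (is.null(gmr_genes)) {
    gmr_genes <- stats::setNames(
      gene_names(n_genes)[n_genes - seq_along(regions) + 1L], regions)
  }
  if (!is.null(regulation_spec)) {
    stopifnot(all(c("gene", "region", "fold") %in% names(regulation_spec)),
              all(regulation_spec$fold != 0),
              !anyDuplicated(regulation_spec[, c("gene", "region")]))
  }
  structure(list(n_genes = as.integer(n_genes), regions = regions,
                 J = as.integer(J), redundant_frac = redundant_frac,
                 max_spots = as.integer(max_spots),
                 mean_range = mean_range, cv_range = cv_range,
                 cv_meanlog = cv_meanlog, cv_sdlog = cv_sdlog,
                 module_spec = module_spec, gmr_cv = gmr_cv,
                 gmr_spots = as.integer(gmr_spots),
                 gmr_genes = gmr_genes,
                 regulation_spec = regulation_spec,
                 n_regulated = as.integer(n_regulated),
                 default_fold = default_fold,
                 regulated_cv = regulated_cv,
                 spot_jitter = spot_jitter, bg_range = bg_range,
                 corrupted_rate = corrupted_rate,
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "study_config")
}

gene_names <- function(n) sprintf("G%05d", seq_len(n))

lognormal_levels <- function(mean, cv, latent) {
  # levels with E[X] = mean and CV = cv given a standard-normal latent
  sigma <- sqrt(log(1 + cv^2))
  mean * exp(sigma * latent - sigma^2 / 2)
}

#' Generate a synthetic study with ground truth
#'
#' Draws, for every region, replicate gene signals from a log-normal model
#' with the configured per-gene means and CVs; within-module correlation
#' is induced by a shared per-replica latent factor per module. Each
#' region's planted GMR receives the lowest CV and membership in the
#' largest module in its own region only (elsewhere it keeps an ordinary
#' CV and no module). Redundant spots are multiplicative-jitter copies of
#' the gene signal; records get a uniform background, foreground =
#' background + signal, and a small fraction of random corruption flags.
#'
#' @param cfg A `study_config`.
#' @return List with `tables` (named list of `spot_table`, one per
#'   region), `truth` (ground-truth list: `mean` and `cv` gene-by-region
#'   matrices, `module` membership matrix, `regulated` per-region data
#'   frames, `gmr` named vector, `R` spots per gene), and `config`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- gene_names(n)
  regions <- cfg$regions
  J <- cfg$J

  # spots per gene, shared across regions so spot ids match in contrasts
  R <- rep(1L, n)
  n_red <- round(cfg$redundant_frac * n)
  red_idx <- sample.int(n, n_red)
  R[red_idx] <- sample(2:cfg$max_spots, n_red, replace = TRUE)
  names(R) <- genes
  R[cfg$gmr_genes] <- cfg$gmr_spots

  base_mean <- exp(stats::runif(n, log(cfg$mean_range[1]),
                                log(cfg$mean_range[2])))
  # per-gene CVs: log-normal, truncated by inverse-CDF sampling
  plo <- stats::plnorm(cfg$cv_range[1], cfg$cv_meanlog, cfg$cv_sdlog)
  phi <- stats::plnorm(cfg$cv_range[2], cfg$cv_meanlog, cfg$cv_sdlog)
  base_cv <- stats::qlnorm(stats::runif(n, plo, phi),
                           cfg$cv_meanlog, cfg$cv_sdlog)
  names(base_mean) <- names(base_cv) <- genes

  # base module membership: consecutive gene blocks, skipping the genes
  # reserved as per-region GMRs
  sizes <- vapply(cfg$module_spec, function(m) as.integer(m$size), 0L)
  cors <- vapply(cfg$module_spec, function(m) as.numeric(m$cor), 0)
  free <- setdiff(genes, cfg$gmr_genes)
  base_module <- stats::setNames(rep(0L, n), genes)
  at <- 1L
  for (m in seq_along(sizes)) {
    base_module[free[at:(at + sizes[m] - 1L)]] <- m
    at <- at + sizes[m]
  }

  # planted regulation
  reg_spec <- cfg$regulation_spec
  if (is.null(reg_spec) && length(regions) > 1L && cfg$n_regulated > 0L) {
    pool <- setdiff(free[base_module[free] == 0L], cfg$gmr_genes)
    rows <- lapply(regions[-1L], function(rg) {
      picked <- sample(pool, min(cfg$n_regulated, length(pool)))
      data.frame(gene = picked, region = rg,
                 fold = cfg$default_fold * sample(c(1, -1),
                                                  length(picked),
                                                  replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    reg_spec <- do.call(rbind, rows)
  }
  if (is.null(reg_spec))
    reg_spec <- data.frame(gene = character(0), region = character(0),
                           fold = numeric(0))

  protected <- unique(c(cfg$gmr_genes, reg_spec$gene))
  # planted genes get comfortably-above-background means so that quality
  # filtering cannot silently erase the ground truth
  safe_lo <- max(sqrt(prod(cfg$mean_range)), 8 * cfg$bg_range[2])
  base_mean[protected] <- exp(stats::runif(length(protected),
                                           log(safe_lo),
                                           log(cfg$mean_range[2])))
  base_cv[unique(reg_spec$gene)] <- cfg$regulated_cv

  true_mean <- matrix(base_mean, n, length(regions),
                      dimnames = list(genes, regions))
  true_cv <- matrix(base_cv, n, length(regions),
                    dimnames = list(genes, regions))
  module <- matrix(base_module, n, length(regions),
                   dimnames = list(genes, regions))
  for (k in seq_len(nrow(reg_spec))) {
    f <- reg_spec$fold[k]
    true_mean[reg_spec$gene[k], reg_spec$region[k]] <-
      true_mean[reg_spec$gene[k], reg_spec$region[k]] *
      if (f > 0) f else 1 / abs(f)
  }
  for (rg in regions) {
    g <- cfg$gmr_genes[[rg]]
    true_cv[g, rg] <- cfg$gmr_cv
    # median-ish ordinary CV outside the commanded region, no module
    true_cv[g, setdiff(regions, rg)] <- stats::median(base_cv)
    module[g, ] <- 0L
    if (length(sizes)) module[g, rg] <- 1L  # join the largest module
  }

  spot_sigma <- sqrt(log(1 + cfg$spot_jitter^2))
  tables <- list()
  for (rg in regions) {
    # shared per-replica latent factor per module induces the within-
    # module correlation; the idiosyncratic component is drawn per spot
    # so that redundant spots are independent replicate measurements of
    # the gene (the degrees-of-freedom model of the pooled CV)
    n_mod <- max(length(sizes), 1L)
    z_mod <- matrix(stats::rnorm(n_mod * J), n_mod, J)
    w <- ifelse(module[, rg] > 0L, cors[pmax(module[, rg], 1L)], 0)

    rows_gene <- rep(seq_len(n), R)
    spot_within <- sequence(R)
    n_rows <- length(rows_gene)
    w_row <- w[rows_gene]
    zc_row <- matrix(0, n_rows, J)
    in_mod_row <- module[rows_gene, rg] > 0L
    zc_row[in_mod_row, ] <-
      z_mod[module[rows_gene, rg][in_mod_row], , drop = FALSE]
    eps_row <- matrix(stats::rnorm(n_rows * J), n_rows, J)
    latent <- sqrt(w_row) * zc_row + sqrt(1 - w_row) * eps_row
    svals <- lognormal_levels(true_mean[rows_gene, rg],
                              true_cv[rows_gene, rg], latent)
    # fixed multiplicative probe-affinity factor per spot (constant
    # across replicas), so spot averaging keeps the replicate structure
    jitter <- exp(spot_sigma * stats::rnorm(n_rows) - spot_sigma^2 / 2)
    svals <- svals * jitter

    spot_id <- sprintf("S_%s_%d", genes[rows_gene], spot_within)
    rec_gene <- rep(genes[rows_gene], J)
    rec_spot <- rep(spot_id, J)
    rec_rep <- rep(seq_len(J), each = n_rows)
    sig_vec <- as.vector(svals)
    bg <- stats::runif(n_rows * J, cfg$bg_range[1], cfg$bg_range[2])
    corrupted <- stats::runif(n_rows * J) < cfg$corrupted_rate &
      !(rec_gene %in% protected)

    ctrl <- if (cfg$n_controls > 0L) {
      cb <- stats::runif(cfg$n_controls * J, cfg$bg_range[1],
                         cfg$bg_range[2])
      data.frame(spot_id = rep(sprintf("CTRL_%03d",
                                       seq_len(cfg$n_controls)), J),
                 gene = "",
                 replica = rep(seq_len(J), each = cfg$n_controls),
                 fg = cb + 500 * exp(0.05 * stats::rnorm(cfg$n_controls * J)),
                 bg = cb, saturated = FALSE, corrupted = FALSE,
                 stringsAsFactors = FALSE)
    } else NULL

    tab <- data.frame(spot_id = rec_spot, gene = rec_gene,
                      replica = rec_rep, fg = bg + sig_vec, bg = bg,
                      saturated = FALSE, corrupted = corrupted,
                      stringsAsFactors = FALSE)
    tables[[rg]] <- as_spot_table(rbind(tab, ctrl))
  }

  truth <- list(genes = genes, regions = regions, mean = true_mean,
                cv = true_cv, module = module,
                regulated = split(reg_spec[, c("gene", "fold")],
                                  factor(reg_spec$region,
                                         levels = regions[-1L])),
                gmr = cfg$gmr_genes, R = R, seed = cfg$seed)
  list(tables = tables, truth = truth, config = cfg)
}

#' Export a generated study as plain-text fixtures
#'
#' Writes one spot TSV per region (in the [parse_spot_table()] default
#' dialect), a GMT file with one gene set per configured module, and the
#' ground truth as JSON.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
export_fixture <- function(study, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", dir)
  }
  paths <- character(0)
  for (rg in names(study$tables)) {
    p <- file.path(dir, paste0("region_", rg, ".tsv"))
    utils::write.table(study$tables[[rg]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  truth <- study$truth
  mods <- truth$module[, 1L]
  mod_ids <- sort(unique(mods[mods > 0L]))
  sets <- lapply(mod_ids, function(m) names(mods)[mods == m])
  if (length(mod_ids)) names(sets) <- paste0("module_", mod_ids)
  gmt <- file.path(dir, "modules.gmt")
  write_gmt(sets, gmt, "synthetic module")
  tj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(genes = truth$genes, regions = truth$regions,
         mean = as.data.frame(truth$mean), cv = as.data.frame(truth$cv),
         module = as.data.frame(truth$module),
         regulated = lapply(truth$regulated, function(d)
           if (is.null(d)) list() else d),
         gmr = as.list(truth$gmr), R = as.list(truth$R),
         seed = truth$seed),
    tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, gmt, tj))
}
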