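# Shared fixtures, built in code once per test run.

# Assemble a region_set directly from a replicate-value matrix:
# one row per (gene, spot), J columns.
region_set_from_matrix <- function(values, genes, spots = NULL,
                                   region = "N", median_units = FALSE) {
  values <- as.matrix(values)
  J <- ncol(values)
  n <- nrow(values)
  if (is.null(spots)) spots <- paste0("s", seq_len(n))
  tab <- data.frame(
    spot_id = rep(spots, J),
    gene = rep(genes, J),
    replica = rep(seq_len(J), each = n),
    fg = as.vector(values),
    bg = 0,
    saturated = FALSE,
    corrupted = FALSE,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("spot_table", "data.frame")
  tab$signal <- tab$fg
  build_region_set(tab, region, median_units = median_units)
}

# A pair of replicate profiles (length n, positive) with an exact Pearson
# correlation r between them.
profiles_with_cor <- function(r, n = 4) {
  x <- seq_len(n)
  y0 <- rev(x)                       # cor(x, y0) = -1
  e <- stats::residuals(stats::lm(y0 ~ x))
  e <- e / sqrt(sum(e^2))
  xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  y <- r * xs + sqrt(1 - r^2) * e
  list(x = 10 + x, y = 10 + y)       # shift positive; cor unchanged
}

# One small default study shared across test files (built lazily).
.study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- generate_study(study_config(n_genes = 300,
                                                      seed = 42))
    dir <- file.path(tempdir(), "gfabric-small-study")
    export_fixture(.study_cache$study, dir)
    .study_cache$dir <- dir
    .study_cache$fabrics <- lapply(c(N = "N", A = "A", B = "B", C = "C"),
      function(rg) fabric(read_region_set(
        file.path(dir, paste0("region_", rg, ".tsv")), rg,
        median_units = TRUE)))
  }
  list(study = .study_cache$study, dir = .study_cache$dir,
       fabrics = .study_cache$fabrics)
}
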