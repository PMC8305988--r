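toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

toy_records <- function() {
  expand.grid(spot_id = c("s1", "s2", "s3"), replica = 1:4,
              stringsAsFactors = FALSE) |>
    transform(gene = ifelse(spot_id == "s3", "", sub("s", "G", spot_id)),
              fg = 200 + seq_len(12), bg = 40,
              saturated = FALSE, corrupted = FALSE)
}

test_that("parse_spot_table reads a toy table and resolves dialects", {
  p <- toy_tsv(toy_records())
  t <- parse_spot_table(p)
  expect_s3_class(t, "spot_table")
  expect_equal(nrow(t), 12L)

  # renamed columns via dialect
  df <- toy_records()
  names(df)[names(df) == "fg"] <- "F532.Median"
  p2 <- toy_tsv(df)
  t2 <- parse_spot_table(p2, dialect = list(fg = "F532.Median"))
  expect_equal(t2$fg, t$fg)
})

test_that("parse_spot_table rejects missing columns and bad numbers", {
  df <- toy_records()
  df$replica <- NULL
  expect_error(parse_spot_table(toy_tsv(df)), "configuration error")

  df2 <- toy_records()
  df2$fg[5] <- "NA"
  expect_error(parse_spot_table(toy_tsv(df2)), "row\\(s\\) 6")
})

test_that("filter_spots applies the three quality rules", {
  base <- data.frame(spot_id = c("a", "b", "c", "d"), gene = "G",
                     replica = 1L,
                     fg = c(150, 100, 600, 500),
                     bg = c(60, 60, 60, 60),
                     saturated = c(FALSE, FALSE, TRUE, FALSE),
                     corrupted = c(FALSE, FALSE, FALSE, TRUE))
  class(base) <- c("spot_table", "data.frame")
  out <- filter_spots(base)
  expect_equal(out$spot_id, "a")           # 150 >= 2*60 kept
  log <- attr(out, "removal_log")
  expect_setequal(log$spot_id, c("b", "c", "d"))
  expect_equal(log$reason[log$spot_id == "b"], "fg<2bg")
  expect_equal(log$reason[log$spot_id == "c"], "saturated")
})

test_that("filtering is order-independent", {
  set.seed(5)
  n <- 200
  t <- data.frame(spot_id = paste0("s", 1:n), gene = "G", replica = 1L,
                  fg = runif(n, 0, 300), bg = runif(n, 20, 60),
                  saturated = runif(n) < 0.1, corrupted = runif(n) < 0.1)
  class(t) <- c("spot_table", "data.frame")
  joint <- filter_spots(t)$spot_id
  # apply single rules in every order; intersection must equal joint set
  rules <- list(
    function(x) x[!(x$fg < 2 * x$bg), ],
    function(x) x[!x$saturated, ],
    function(x) x[!x$corrupted, ])
  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    y <- t
    for (k in ord) y <- rules[[k]](y)
    expect_setequal(y$spot_id, joint)
  }
})

test_that("normalization recovers a per-array scale factor", {
  set.seed(7)
  n <- 120
  sig <- exp(rnorm(n, log(500), 1))
  # replica 2 is an exact x3 copy of the shared signal
  df <- do.call(rbind, lapply(1:4, function(j)
    data.frame(spot_id = paste0("s", 1:n), gene = "G", replica = j,
               fg = sig * if (j == 2) 3 else 1 + 40, bg = 40,
               saturated = FALSE, corrupted = FALSE)))
  df$fg <- with(df, sig[as.integer(sub("s", "", spot_id))] *
                  ifelse(replica == 2, 3, 1) + 40)
  class(df) <- c("spot_table", "data.frame")
  out <- normalize_arrays(df)
  sc <- attr(out, "scale_factors")
  expect_equal(unname(sc[["2"]] / sc[["1"]]), 1 / 3, tolerance = 1e-9)
  m <- tapply(out$signal, out$replica, median)
  expect_lt(max(abs(m / m[1] - 1)), 1e-9)
  expect_equal(out$signal[out$replica == 2], out$signal[out$replica == 1],
               tolerance = 1e-9)

  # with replicate noise on top, the factor is still recovered closely
  df2 <- df
  df2$fg <- (df2$fg - 40) * exp(rnorm(nrow(df2), 0, 0.1)) + 40
  out2 <- normalize_arrays(df2)
  sc2 <- attr(out2, "scale_factors")
  expect_equal(unname(sc2[["2"]] / sc2[["1"]]), 1 / 3, tolerance = 0.05)
})

test_that("normalization is idempotent and rejects degenerate arrays", {
  set.seed(8)
  n <- 60
  df <- do.call(rbind, lapply(1:3, function(j)
    data.frame(spot_id = paste0("s", 1:n), gene = "G", replica = j,
               fg = exp(rnorm(n, log(300), 0.6)) + 40, bg = 40,
               saturated = FALSE, corrupted = FALSE)))
  class(df) <- c("spot_table", "data.frame")
  once <- normalize_arrays(df)
  df2 <- df
  df2$fg <- once$signal + df2$bg
  twice <- normalize_arrays(df2)
  expect_lte(attr(twice, "iterations"), 2L)
  expect_equal(twice$signal, once$signal, tolerance = 1e-6)

  bad <- df
  bad$fg[bad$replica == 2] <- bad$bg[bad$replica == 2]
  expect_error(normalize_arrays(bad), "data error")
})

test_that("normalization output is scale-equivariant up to the overall unit", {
  set.seed(9)
  n <- 100
  df <- do.call(rbind, lapply(1:4, function(j)
    data.frame(spot_id = paste0("s", 1:n), gene = paste0("G", 1:n),
               replica = j, fg = exp(rnorm(n, log(400), 0.8)) + 30,
               bg = 30, saturated = FALSE, corrupted = FALSE)))
  class(df) <- c("spot_table", "data.frame")
  df_scaled <- df
  sel <- df_scaled$replica == 3
  df_scaled$fg[sel] <- (df_scaled$fg[sel] - 30) * 5 + 30
  a <- normalize_arrays(df)
  b <- normalize_arrays(df_scaled)
  # identical after removing one global factor
  expect_equal(b$signal / median(b$signal), a$signal / median(a$signal),
               tolerance = 1e-6)
  # and exactly identical downstream in median-gene units
  ra <- build_region_set(a, "N", median_units = TRUE)
  rb <- build_region_set(b, "N", median_units = TRUE)
  expect_equal(rb$expr, ra$expr, tolerance = 1e-6)
})

test_that("build_region_set enforces replica completeness and counts spots", {
  vals <- matrix(100, 13, 4)
  genes <- c(rep("TP53", 11), "A1", "B1")
  spots <- c(paste0("tp", 1:11), "a1", "b1")
  tab <- data.frame(spot_id = rep(spots, 4), gene = rep(genes, 4),
                    replica = rep(1:4, each = 13), fg = as.vector(vals),
                    bg = 0, saturated = FALSE, corrupted = FALSE)
  class(tab) <- c("spot_table", "data.frame")
  tab$signal <- tab$fg
  # drop replica 3 of B1's only spot -> B1 must vanish, logged
  tab <- tab[!(tab$spot_id == "b1" & tab$replica == 3), ]
  rs <- build_region_set(tab, "N")
  expect_equal(unname(rs$R[["TP53"]]), 11L)
  expect_false("B1" %in% rs$genes)
  expect_true("B1" %in% rs$dropped)
})

test_that("median-unit rescaling sets the median gene AVE to 1", {
  s <- small_study()
  fb <- s$fabrics$N
  expect_equal(median(fb$stats$AVE), 1, tolerance = 1e-12)
})

test_that("a constant-value table yields AVE equal to that value", {
  rs <- region_set_from_matrix(matrix(7, 5, 4),
                               genes = paste0("G", c(1, 1, 2, 3, 3)))
  fb <- fabric(rs)
  expect_equal(fb$stats$AVE, rep(7, 3))
  expect_error(build_region_set(structure(
    data.frame(spot_id = "s", gene = "G", replica = 1L, fg = 1, bg = 0,
               saturated = FALSE, corrupted = FALSE, signal = 1),
    class = c("spot_table", "data.frame")), "N"),
    "fewer than 2 replicas")
})

test_that("region sets round-trip through TSV with provenance sidecar", {
  s <- small_study()
  rs <- s$fabrics$N$rs
  p <- tempfile(fileext = ".tsv")
  write_region_set(rs, p)
  df <- read.delim(p)
  expect_equal(nrow(df), nrow(rs$expr) * rs$J)
  expect_true(file.exists(sub("\\.tsv$", ".json", p)))
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", p))
  expect_equal(side$genes, length(rs$genes))
})

test_that("GEO series-matrix files are ingested as spot tables", {
  p <- tempfile()
  writeLines(c(
    "!Series_title\t\"toy\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"\t\"GSM4\"",
    "p1\t10\t11\t12\t13",
    "p2\t20\t21\t22\t23",
    "!series_matrix_table_end"), p)
  t <- read_geo_series_matrix(p, gene_map = c(p1 = "TP53"))
  expect_equal(nrow(t), 8L)
  expect_setequal(unique(t$gene), c("TP53", ""))
  expect_equal(t$fg[t$spot_id == "p2" & t$replica == 4], 23)
})
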