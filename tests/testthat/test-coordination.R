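test_that("the Pearson significance boundary at four replicas is 0.950", {
  expect_equal(round(pearson_threshold(4, 0.05), 3), 0.950)
  expect_error(pearson_threshold(2), "domain error")
})

test_that("pairs classify into synergism, antagonism and independence", {
  pr <- profiles_with_cor(0.99)
  rs <- region_set_from_matrix(rbind(pr$x, pr$y), genes = c("A", "B"))
  expect_equal(classify_pair(rs, "A", "B")$class, "synergistic")

  pr2 <- profiles_with_cor(-0.97)
  rs2 <- region_set_from_matrix(rbind(pr2$x, pr2$y), genes = c("A", "B"))
  expect_equal(classify_pair(rs2, "A", "B")$class, "antagonistic")

  pr3 <- profiles_with_cor(0.02)
  rs3 <- region_set_from_matrix(rbind(pr3$x, pr3$y), genes = c("A", "B"))
  expect_equal(classify_pair(rs3, "A", "B", indep_band = 0.05)$class,
               "independent")

  pr4 <- profiles_with_cor(0.5)
  rs4 <- region_set_from_matrix(rbind(pr4$x, pr4$y), genes = c("A", "B"))
  expect_equal(classify_pair(rs4, "A", "B")$class, "undecided")

  # classification is exactly symmetric under gene swap
  for (rs_k in list(rs, rs2, rs3, rs4)) {
    a <- classify_pair(rs_k, "A", "B")
    b <- classify_pair(rs_k, "B", "A")
    expect_identical(a$class, b$class)
    expect_equal(a$COR, b$COR)
  }

  # zero-variance gene: undecided, flagged
  rs5 <- region_set_from_matrix(rbind(c(3, 3, 3, 3), c(1, 2, 3, 4)),
                                genes = c("A", "B"))
  rec <- suppressWarnings(classify_pair(rs5, "A", "B"))
  expect_equal(rec$class, "undecided")
  expect_true(is.na(rec$COR))
})

test_that("classification flips exactly at the printed 0.95 boundary", {
  for (r in c(0.949, 0.951, -0.949, -0.951)) {
    pr <- profiles_with_cor(r)
    rs <- region_set_from_matrix(rbind(pr$x, pr$y), genes = c("A", "B"))
    cls <- classify_pair(rs, "A", "B")$class
    if (abs(r) > 0.95)
      expect_equal(cls, if (r > 0) "synergistic" else "antagonistic")
    else expect_equal(cls, "undecided")
  }
})

test_that("the census partitions all pairs and spots full synergy", {
  base <- c(1, 2, 3, 4)
  vals <- rbind(10 + base, 20 + 2 * base, 5 + 0.5 * base)
  rs <- region_set_from_matrix(vals, genes = c("A", "B", "C"))
  cen <- coordination_census(rs, c("A", "B", "C"))
  expect_equal(unname(cen$percent[["synergistic"]]), 100)
  expect_equal(sum(cen$percent), 100)
  expect_equal(nrow(cen$pairs), 3L)
  expect_error(coordination_census(rs, "A"), "at least 2")
})

test_that("a null panel shows about five percent coordination", {
  set.seed(18)
  frac <- replicate(10, {
    m <- matrix(exp(rnorm(25 * 4, 3, 0.3)), 25, 4)
    rs <- region_set_from_matrix(m, genes = sprintf("g%02d", 1:25))
    cen <- coordination_census(rs, sprintf("g%02d", 1:25))
    sum(cen$percent[c("synergistic", "antagonistic")]) / 100
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("inter-region phase classification handles mirrored profiles", {
  base <- c(1, 2, 3, 4)
  P <- region_set_from_matrix(rbind(10 + base), genes = "G")
  Q_same <- region_set_from_matrix(rbind(20 + 2 * base), genes = "G")
  Q_anti <- region_set_from_matrix(rbind(10 + rev(base)), genes = "G")

  rec1 <- interregion_phase(P, Q_same, "G")
  expect_equal(rec1$class, "in-phase")
  expect_equal(rec1$COR, 1)

  rec2 <- interregion_phase(P, Q_anti, "G")
  expect_equal(rec2$class, "anti-phase")
  expect_equal(rec2$COR, -1)

  expect_error(interregion_phase(P, Q_same, "G", pairing = c(1, 1, 2, 3)),
               "incomplete")
})

test_that("a gene can be anti-phase to one region and in-phase between others", {
  # the receptor-like pattern: opposite replicate swing in the reference,
  # the same swing in the two lesions
  up <- c(1, 2, 3, 4)
  N <- region_set_from_matrix(rbind(10 + rev(up)), genes = "ERBB2like")
  A <- region_set_from_matrix(rbind(12 + up), genes = "ERBB2like")
  B <- region_set_from_matrix(rbind(15 + 2 * up), genes = "ERBB2like")
  expect_equal(interregion_phase(N, A, "ERBB2like")$class, "anti-phase")
  expect_equal(interregion_phase(N, B, "ERBB2like")$class, "anti-phase")
  expect_equal(interregion_phase(A, B, "ERBB2like")$class, "in-phase")
})

test_that("hub profiles count synergisms and antagonisms", {
  base <- c(1, 2, 3, 4)
  vals <- rbind(10 + base, 20 + 3 * base, 8 + 0.5 * base, 10 + rev(base))
  rs <- region_set_from_matrix(vals, genes = c("HUB", "T1", "T2", "T3"))
  hp <- hub_profile(rs, "HUB", c("T1", "T2", "T3", "HUB"))
  expect_equal(nrow(hp$records), 3L)       # hub-self pair skipped
  expect_equal(unname(hp$counts["synergisms"]), 2L)
  expect_equal(unname(hp$counts["antagonisms"]), 1L)

  empty <- hub_profile(rs, "HUB", character(0))
  expect_equal(nrow(empty$records), 0L)
  expect_equal(unname(empty$counts), c(0L, 0L))
})

test_that("coordination-profile similarity identifies twins and mirrors", {
  set.seed(19)
  m <- matrix(exp(rnorm(8 * 4, 3, 0.4)), 8, 4)
  g1 <- 10 + c(1, 2, 3, 4)
  twin <- 5 + 2 * c(1, 2, 3, 4)            # identical shape, new name
  mirror <- 20 - 2 * c(1, 2, 3, 4)         # exactly opposite swing
  rs <- region_set_from_matrix(rbind(g1, twin, mirror, m),
                               genes = c("G1", "TWIN", "MIRROR",
                                         sprintf("x%d", 1:8)))
  expect_equal(profile_similarity(rs, "G1", "TWIN"), 1, tolerance = 1e-9)
  expect_equal(profile_similarity(rs, "G1", "MIRROR"), -1,
               tolerance = 1e-9)
})

test_that("profile similarity separates shared from disjoint modules", {
  # at four replicas the similarity of two unrelated genes tracks their
  # own (noisy) correlation, so the null property is symmetry around
  # zero across independent studies, while same-module pairs must score
  # consistently high
  cross <- numeric(0); within <- numeric(0)
  for (s in 1:12) {
    st <- generate_study(study_config(
      n_genes = 200, regions = "A", n_regulated = 0L, corrupted_rate = 0,
      module_spec = list(list(size = 20, cor = 0.9),
                         list(size = 20, cor = 0.9)), seed = 500L + s))
    d <- file.path(tempdir(), "simil-study")
    export_fixture(st, d)
    fb <- fabric(read_region_set(file.path(d, "region_A.tsv"), "A",
                                 median_units = TRUE))
    mods <- st$truth$module[, "A"]
    g1 <- intersect(names(mods)[mods == 1L], fb$stats$gene)
    g2 <- intersect(names(mods)[mods == 2L], fb$stats$gene)
    cross <- c(cross, profile_similarity(fb, g1[1], g2[1]))
    within <- c(within, profile_similarity(fb, g1[2], g1[3]))
    unlink(d, recursive = TRUE)
  }
  expect_lt(abs(mean(cross)), 0.35)
  expect_gt(mean(within), 0.6)
  expect_gt(mean(within) - abs(mean(cross)), 0.3)
})
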