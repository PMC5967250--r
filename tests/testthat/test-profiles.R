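test_that("build_pdf bins values on the anchored grid with exact densities", {
  p <- build_pdf(c(5.21, 5.23, 5.24), bin_width = 0.05, feature = "dblock")
  expect_equal(length(p$counts), 1L)
  expect_equal(p$breaks, c(5.20, 5.25), tolerance = 1e-12)
  expect_equal(p$counts, 3L)
  expect_equal(p$density, 20)  # 3 / (3 * 0.05)
  # boundary: an angle just below 360 lands in [355, 360)
  p2 <- build_pdf(c(359.999, 2), bin_width = 5, feature = "phi")
  expect_equal(p2$counts[length(p2$counts)], 1L)
  expect_equal(p2$breaks[length(p2$breaks)], 360)
  # uniform grid, one value per bin: all densities equal
  p3 <- build_pdf(seq(2.5, 357.5, by = 5), bin_width = 5, feature = "chi1")
  expect_true(all(p3$density == p3$density[1]))
  expect_error(build_pdf(numeric(), feature = "phi"), "no values")
})

test_that("profiles conserve counts and integrate to one", {
  set.seed(3)
  vals <- runif(777, 0, 360)
  p <- build_pdf(vals, bin_width = 5, feature = "psi")
  expect_equal(sum(p$counts), 777L)
  expect_equal(p$n_total, 777L)
  expect_equal(sum(p$density) * p$bin_width, 1, tolerance = 1e-12)
})

test_that("profiles are invariant under input permutation", {
  set.seed(8)
  vals <- rnorm(500, 5, 0.3)
  p1 <- build_pdf(vals, feature = "dblock")
  p2 <- build_pdf(sample(vals), feature = "dblock")
  expect_equal(p1$counts, p2$counts)
  expect_equal(p1$breaks, p2$breaks)
})

test_that("normalize_by_reference scales both curves by the reference peak", {
  set.seed(4)
  ref_vals <- rnorm(2000, 5.5, 0.2)
  p_ref <- build_pdf(ref_vals, feature = "dblock")
  np <- normalize_by_reference(p_ref, p_ref)
  expect_identical(max(np$reference$values), 1)    # exact
  expect_equal(np$target$values, np$reference$values)
  # a target twice as peaked reaches 2 on the reference scale
  tgt_vals <- rnorm(4000, 5.5, 0.1)
  p_tgt <- build_pdf(tgt_vals, feature = "dblock")
  np2 <- normalize_by_reference(p_tgt, p_ref)
  expect_identical(max(np2$reference$values), 1)
  expect_equal(max(np2$target$values),
               max(p_tgt$density) / max(p_ref$density), tolerance = 1e-12)
  expect_gt(max(np2$target$values), 1.5)
  expect_error(normalize_by_reference(p_ref, build_pdf(1:10, feature = "phi")))
})

test_that("build_hist2d normalizes by its own modal cell", {
  recs <- data.frame(phi = rep(298, 10), dblock = rep(5.71, 10))
  h <- build_hist2d(recs)
  expect_equal(sum(h$counts), 10L)
  expect_equal(sum(h$ratio == 1), 1L)
  expect_equal(sum(h$counts > 0), 1L)
  # two-cell arithmetic mirroring the population-ratio construct
  recs2 <- data.frame(phi = c(rep(301.8, 50), rep(58, 9)),
                      dblock = c(rep(3.78, 50), rep(3.79, 9)))
  h2 <- build_hist2d(recs2)
  expect_equal(max(h2$counts), 50L)
  expect_identical(max(h2$ratio), 1)
  expect_equal(population_ratio(h2, c(58, 3.79)), 0.18)
  expect_equal(population_ratio(h2, c(301.8, 3.78)), 1)
  expect_equal(population_ratio(h2, c(100, 3.78)), 0)
  expect_error(population_ratio(h2, c(58, 3.79), c(100, 3.78)), "undefined")
  expect_error(build_hist2d(recs2[0, ]), "no records")
})

test_that("find_peaks detects local maxima with the plateau tie rule", {
  mk <- function(density) {
    structure(list(mids = seq_along(density), density = density,
                   bin_width = 1, counts = density, n_total = sum(density)),
              class = "pdf_profile")
  }
  # monotone profile: one peak at the maximum
  p <- find_peaks(mk(1:6), min_prominence = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$center, 6)
  # flat profile: leftmost bin of the plateau
  p2 <- find_peaks(mk(rep(2, 5)), min_prominence = 0)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$center, 1)
  # interior plateau resolved to its leftmost bin
  p3 <- find_peaks(mk(c(0, 3, 3, 0, 5, 0)), min_prominence = 0)
  expect_equal(p3$center, c(5, 2))
  expect_equal(p3$height, c(5, 3))
  # prominence threshold suppresses minor peaks
  p4 <- find_peaks(mk(c(0, 0.1, 0, 5, 0)), min_prominence = 0.05)
  expect_equal(p4$center, 4)
})

test_that("two-component ensembles yield two recovered dBlock peaks", {
  spec <- synthetic_spec("LYS", list(
    list(phi = -62, psi = -41, chis = rep(180, 4), weight = 0.5, sigma = 0),
    list(phi = -62, psi = -41, chis = c(180, 180, 180, 60), weight = 0.5,
         sigma = 0)), n_samples = 2)
  ideal <- vapply(spec$components, function(cm) {
    block_length(central_residue(
      build_residue("LYS", cm$phi, cm$psi, cm$chis)))
  }, 0)
  expect_gt(abs(diff(ideal)), 0.4)  # components are separated
  spec5 <- synthetic_spec("LYS", spec$components, n_samples = 8000, seed = 17)
  spec5$components <- lapply(spec5$components, function(cm) {
    cm$sigma <- 5; cm
  })
  e <- sample_ensemble(spec5)
  prof <- build_pdf(e$truth$dblock, feature = "dblock")
  np <- normalize_by_reference(prof, prof)
  peaks <- find_peaks(np$reference, min_prominence = 0.05)
  expect_gte(nrow(peaks), 2L)
  top2 <- sort(peaks$center[1:2])
  for (i in 1:2) {
    expect_lte(abs(top2[i] - sort(ideal)[i]), 0.05)  # within one bin
  }
})

test_that("interval_mass handles full, empty and partial intervals", {
  p <- build_pdf(seq(2.5, 357.5, by = 5), bin_width = 5, feature = "phi")
  expect_equal(interval_mass(p, 0, 360), 1)
  expect_equal(interval_mass(p, 100, 100.0001), 0, tolerance = 1e-3)
  expect_equal(interval_mass(p, 0, 180), 0.5)
  # partial bins split proportionally
  expect_equal(interval_mass(p, 0, 2.5), 2.5 / 360, tolerance = 1e-12)
  expect_error(interval_mass(p, 10, 5))
})

test_that("compare_sets flags a shifted mixture as a B-above-A region", {
  base <- list(phi = -62, psi = -41, chis = rep(180, 4), weight = 0.7,
               sigma = 4)
  short <- list(phi = -62, psi = -41, chis = c(180, 180, 180, 60),
                weight = 0.3, sigma = 4)
  spec_a <- synthetic_spec("LYS", list(base), n_samples = 3000, seed = 21)
  spec_b <- synthetic_spec("LYS", list(base, short),
                           n_samples = 3000, seed = 22)
  recs_a <- sample_ensemble(spec_a)$truth
  recs_b <- sample_ensemble(spec_b)$truth
  recs_a$res_type <- "LYS"; recs_b$res_type <- "LYS"
  recs_a$chi1 <- recs_a$chi1 %% 360; recs_b$chi1 <- recs_b$chi1 %% 360
  recs_a$phi <- recs_a$phi %% 360; recs_b$phi <- recs_b$phi %% 360
  cmp <- compare_sets(recs_a, recs_b, "LYS", features = "dblock")
  ex <- cmp$features$dblock$exceedance
  expect_gt(nrow(ex), 0)
  # the shifted component's ideal length falls inside a reported interval
  shifted_len <- block_length(central_residue(
    build_residue("LYS", -62, -41, c(180, 180, 180, 60))))
  expect_true(any(ex$lo <= shifted_len & shifted_len <= ex$hi))
  expect_true(all(ex$mass_b >= ex$mass_a))
  # identical sets produce no exceedance
  cmp_same <- compare_sets(recs_a, recs_a, "LYS", features = "dblock")
  expect_equal(nrow(cmp_same$features$dblock$exceedance), 0L)
  # absent residue type is reported as not comparable
  cmp_absent <- compare_sets(recs_a, recs_b, "TYR", features = "dblock")
  expect_identical(cmp_absent$features$dblock, "not comparable")
})

test_that("B's npdf at A's modal bin drops when B's mass moves off the mode", {
  set.seed(9)
  a_vals <- rnorm(5000, 5.7, 0.08)
  b_vals <- c(rnorm(2500, 5.7, 0.08), rnorm(2500, 5.0, 0.08))
  np <- normalize_by_reference(build_pdf(b_vals, feature = "dblock"),
                               build_pdf(a_vals, feature = "dblock"))
  modal_bin <- which.max(np$reference$values)
  expect_lt(np$target$values[modal_bin], 1)
})

test_that("profile tables serialize with bin centers and values", {
  p <- build_pdf(c(5.21, 5.23, 5.24, 5.30), feature = "dblock")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(p, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(sum(df$count), 4)
  h <- build_hist2d(data.frame(phi = c(10, 10, 200), dblock = c(5, 5, 4)))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(h, path2)
  df2 <- read.table(path2, header = TRUE, sep = "\t")
  expect_equal(sum(df2$count), 3)
  expect_equal(max(df2$ratio), 1)
})
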