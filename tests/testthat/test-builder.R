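test_that("place_atom realizes the requested internal coordinates", {
  set.seed(5)
  for (i in 1:200) {
    a <- rnorm(3); b <- a + rnorm(3); c_ <- b + rnorm(3)
    bond <- runif(1, 1, 2); angle <- runif(1, 95, 175); tor <- runif(1, 0, 360)
    d <- place_atom(a, b, c_, bond, angle, tor)
    expect_lt(abs(sqrt(sum((d - c_)^2)) - bond), 1e-9)
    u <- (b - c_) / sqrt(sum((b - c_)^2))
    v <- (d - c_) / sqrt(sum((d - c_)^2))
    expect_lt(abs(acos(sum(u * v)) * 180 / pi - angle), 1e-6)
    expect_lt(ang_diff(dihedral_angle(a, b, c_, d), tor), 1e-6)
  }
})

test_that("place_atom matches the rotation-construction oracle", {
  q0 <- oracle_quadruple(0)  # cis frame with axis along x
  for (t in c(60, 147.5, 210, 300)) {
    q <- oracle_quadruple(t)
    bond <- sqrt(sum((q$d - q$c)^2))
    v <- q$d - q$c
    u <- (q$b - q$c) / sqrt(sum((q$b - q$c)^2))
    angle <- acos(sum(u * v) / bond) * 180 / pi
    d <- place_atom(q$a, q$b, q$c, bond, angle, t)
    expect_equal(d, q$d, tolerance = 1e-9)
  }
})

test_that("place_atom rejects a collinear reference frame", {
  expect_error(place_atom(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1.5, 109, 60),
               class = "blocklen_degenerate_geometry")
})

test_that("build_residue realizes backbone and side-chain torsions exactly", {
  trip <- build_residue("LYS", phi_r = -62, psi_r = -41,
                        chis = c(180, 170, 65, 300))
  recs <- extract_records(trip)
  expect_equal(recs$phi[2], 298, tolerance = 1e-9)
  expect_equal(recs$psi[2], 319, tolerance = 1e-9)
  expect_equal(recs$chi1[2], 180, tolerance = 1e-9)
  res <- central_residue(trip)
  chi <- function(nm) dihedral_angle(atom_coords(res, nm[1]),
                                     atom_coords(res, nm[2]),
                                     atom_coords(res, nm[3]),
                                     atom_coords(res, nm[4]))
  expect_equal(chi(c("CA", "CB", "CG", "CD")), 170, tolerance = 1e-8)
  expect_equal(chi(c("CB", "CG", "CD", "CE")), 65, tolerance = 1e-8)
  expect_equal(chi(c("CG", "CD", "CE", "NZ")), 300, tolerance = 1e-8)
})

test_that("build_residue uses the correct gamma atom for THR and ILE", {
  thr <- central_residue(build_residue("THR", -120, 130, 60))
  expect_equal(chi1_angle(thr), 60, tolerance = 1e-8)
  ile <- central_residue(build_residue("ILE", -120, 130, c(300, 180)))
  expect_equal(chi1_angle(ile), 300, tolerance = 1e-8)
})

test_that("build_residue reproduces its rigid geometry", {
  res <- central_residue(build_residue("LYS", -62, -41, c(180, 180, 180, 180)))
  blen <- function(x, y) sqrt(sum((atom_coords(res, x) - atom_coords(res, y))^2))
  expect_lt(abs(blen("N", "CA") - 1.458), 2e-3)
  expect_lt(abs(blen("CA", "C") - 1.525), 2e-3)
  expect_lt(abs(blen("CA", "CB") - 1.530), 2e-3)
  expect_lt(abs(blen("CE", "NZ") - 1.489), 2e-3)
  bang <- function(x, y, z) {
    u <- atom_coords(res, x) - atom_coords(res, y)
    v <- atom_coords(res, z) - atom_coords(res, y)
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  expect_lt(abs(bang("N", "CA", "C") - 111.2), 0.1)
  expect_lt(abs(bang("N", "CA", "CB") - 110.4), 0.1)
  expect_lt(abs(bang("C", "CA", "CB") - 110.5), 0.1)
})

test_that("build_residue is deterministic and validates its inputs", {
  t1 <- build_residue("TRP", -70, 140, c(180, 90))
  t2 <- build_residue("TRP", -70, 140, c(180, 90))
  expect_identical(t1[[2]]$xyz, t2[[2]]$xyz)
  expect_error(build_residue("XXX", -60, -40, numeric()), "unknown residue")
  expect_error(build_residue("LYS", -60, -40, c(180, 180)), "chi torsion")
})

test_that("aromatic rings close and stay planar", {
  res <- central_residue(build_residue("PHE", -120, 130, c(300, 90)))
  ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  xyz <- do.call(rbind, lapply(ring, function(nm) atom_coords(res, nm)))
  # closure: consecutive ring bonds all close to 1.38 A
  for (i in seq_along(ring)) {
    j <- if (i == length(ring)) 1L else i + 1L
    expect_lt(abs(sqrt(sum((xyz[i, ] - xyz[j, ])^2)) - 1.383), 0.01)
  }
  # planarity: all atoms within 1e-6 A of the best plane
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  expect_lt(sv$d[3], 1e-6)
})

test_that("clash screen accepts extended conformers and rejects folded ones", {
  expect_true(clash_filter(build_residue("LYS", -62, -41, rep(180, 4))))
  # find a folded grid conformer with a genuine < 2 A non-bonded contact
  grid <- expand.grid(c(60, 180, 300), c(60, 180, 300),
                      c(60, 180, 300), c(60, 180, 300))
  fails <- FALSE
  for (i in seq_len(nrow(grid))) {
    trip <- build_residue("LYS", -62, -41, as.numeric(grid[i, ]))
    if (!clash_filter(trip, 2.0)) { fails <- TRUE; break }
  }
  expect_true(fails)
  # the same folded conformer passes with the screen disabled
  expect_true(clash_filter(trip, 0))
})

test_that("sigma-zero ensembles are degenerate and seeds reproduce exactly", {
  spec <- synthetic_spec("ILE", list(
    list(phi = -120, psi = 130, chis = c(300, 180), weight = 1, sigma = 0)),
    n_samples = 20, seed = 99)
  e1 <- sample_ensemble(spec)
  expect_equal(nrow(e1$truth), 20)
  expect_equal(length(unique(round(e1$truth$dblock, 12))), 1L)
  e2 <- sample_ensemble(spec)
  expect_identical(e1$truth, e2$truth)
})

test_that("mixture components are drawn according to their weights", {
  spec <- synthetic_spec("LYS", list(
    list(phi = -62, psi = -41, chis = rep(180, 4), weight = 0.5, sigma = 2),
    list(phi = -62, psi = -41, chis = c(180, 180, 180, 60), weight = 0.5,
         sigma = 2)),
    n_samples = 4000, seed = 31)
  e <- sample_ensemble(spec)
  n1 <- sum(e$truth$component == 1L)
  # binomial(4000, 0.5): 3 sigma is about 95
  expect_lt(abs(n1 - 2000), 3 * sqrt(4000 * 0.25))
})

test_that("impossible clash specs fail after the retry cap", {
  spec <- synthetic_spec("LYS", list(
    list(phi = -62, psi = -41, chis = rep(180, 4), weight = 1, sigma = 0)),
    n_samples = 2, seed = 1, clash_threshold = 50)
  expect_error(sample_ensemble(spec, max_retries = 5L), "clash screen")
})

test_that("synthetic specs round trip through YAML", {
  spec <- synthetic_spec("PHE", list(
    list(phi = -120, psi = 130, chis = c(300, 90), weight = 0.7, sigma = 3),
    list(phi = -120, psi = 130, chis = c(60, 90), weight = 0.3, sigma = 3)),
    n_samples = 11, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, path)
  spec2 <- read_synthetic_spec(path)
  expect_equal(spec2$res_type, "PHE")
  expect_equal(spec2$n_samples, 11L)
  expect_equal(spec2$seed, 5L)
  expect_equal(length(spec2$components), 2L)
  expect_equal(spec2$components[[1]]$weight, 0.7, tolerance = 1e-9)
})

test_that("PDB write/read round trip preserves torsions to quantization", {
  spec <- synthetic_spec("LYS", list(
    list(phi = -62, psi = -41, chis = rep(180, 4), weight = 1, sigma = 8)),
    n_samples = 20, seed = 12)
  e <- sample_ensemble(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(e$structures, path)
  models <- read_ensemble(path)
  expect_length(models, 20)
  for (i in seq_along(models)) {
    recs <- extract_records(apply_selection(models[[i]],
                                            selection_policy("all")))
    expect_equal(nrow(recs), 3L)
    expect_lt(ang_diff(recs$phi[2], e$truth$phi[i] %% 360), 0.05)
    expect_lt(ang_diff(recs$chi1[2], e$truth$chi1[i] %% 360), 0.05)
    expect_lt(abs(recs$dblock[2] - e$truth$dblock[i]), 0.005)
  }
})

test_that("single structures and chain mode produce valid PDB output", {
  trip <- build_residue("TYR", -120, 130, c(300, 90))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(trip, path)
  st <- read_structure(path)
  expect_length(st, 1)
  expect_length(st[[1]], 3)
  # coordinates quantized to 3 decimals
  line <- grep("^ATOM", readLines(path), value = TRUE)[1]
  expect_match(line, "\\d+\\.\\d{3}")
  # two structures as two chains of one model
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(trip, trip), path2, multi_model = FALSE)
  st2 <- read_structure(path2)
  expect_length(st2, 2)
})
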