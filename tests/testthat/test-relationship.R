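test_that("shared-father probabilities are exact and well-behaved", {
  expect_equal(shared_father_probs(1, 8)$p_dpq, 1)
  expect_equal(shared_father_probs(3, 8)$p_dpq, 1 / 8 + (7 / 8) / 3)
  expect_equal(shared_father_probs(3, 8)$p_dr, 1 / 8)
  expect_lt(shared_father_probs(1e6, 1e6)$p_dpq, 1e-5)
  expect_error(shared_father_probs(0, 8), ">= 1")
  expect_error(shared_father_probs(3, 0), ">= 1")
  ## probabilities stay in (0, 1] over a grid (the S = 1 pathology of the
  ## 1/D + 1/S approximation does not occur)
  for (S in 1:12) for (D in 1:16)
    expect_lte(shared_father_probs(S, D)$p_dpq, 1)
})

test_that("the recursion reproduces closed-form toy relationships", {
  ped <- toy_identified()
  fg <- build_factor(ped, "group_level")
  Ag <- dense_relationship(fg)
  iw <- fg$index["4"]; i5 <- fg$index["5"]; i6 <- fg$index["6"]
  expect_equal(fg$entity$d[iw], (2 - 1) / (4 * 8))        # worker residual
  expect_equal(Ag[iw, iw], 0.53125)
  expect_equal(Ag[i5, i6], 0.5)                           # group-level sisters
  fe <- build_factor(ped, "exact_per_mating")
  Ae <- dense_relationship(fe)
  expect_equal(Ae[fe$index["5"], fe$index["6"]], 0.53125) # same-mating exact
  expect_equal(Ae[fe$index["4"], fe$index["4"]], 0.53125)
  ## open group of 100 unknown DPQs: self-relationship 1/S
  po <- validate_pedigree(ped_row(1, "MATE", style = "OPEN_GROUP",
                                  S = 100, D = 8))
  expect_equal(dense_relationship(build_factor(po))[1, 1], 0.01)
  ## queen diagonals are 1 + F in [1, 2]
  f3 <- build_factor(toy_three_gen())
  qs <- f3$entity$type == 1L
  expect_true(all(f3$entity$a_self[qs] >= 1 & f3$entity$a_self[qs] <= 2))
  expect_equal(f3$entity$a_self[qs], 1 + f3$entity$F[qs])
})

test_that("the sparse inverse is the exact inverse of the dense recursion", {
  p1 <- validate_pedigree(ped_row(1, "QUEEN"))
  expect_equal(as.matrix(invert_factor(build_factor(p1))), matrix(1),
               ignore_attr = TRUE)
  for (ped in list(toy_identified(), toy_three_gen())) {
    fac <- build_factor(ped, "group_level")
    A <- dense_relationship(fac)
    Ainv <- as.matrix(invert_factor(fac))
    expect_lt(max(abs(A %*% Ainv - diag(nrow(A)))), 1e-10)
    ## A is PSD: Cholesky succeeds
    expect_silent(chol(A + diag(1e-10, nrow(A))))
  }
  ## deterministic worker groups make the exact-mode factor non-invertible
  expect_error(invert_factor(build_factor(toy_identified(),
                                          "exact_per_mating")), "d > 0")
})

test_that("founder trio inverse matches the dense 3x3 oracle", {
  ped <- validate_pedigree(rbind(
    ped_row(1, "QUEEN"), ped_row(2, "QUEEN"),
    ped_row(3, "MATE", style = "IDENTIFIED_DPQ", member = 2, S = 1, D = 8),
    ped_row(4, "QUEEN", dam = 1, sire_entry = 3, birth_year = 1)))
  fac <- build_factor(ped, "group_level")
  A <- dense_relationship(fac)
  expect_equal(A, rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0.5, 0.5, 1)))
  expect_equal(as.matrix(invert_factor(fac)), solve(A), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("relationship matvec agrees with the dense matrix", {
  fac <- build_factor(toy_three_gen())
  A <- dense_relationship(fac)
  set.seed(8)
  v <- matrix(rnorm(2 * nrow(A)), ncol = 2)
  expect_equal(relationship_matvec(fac, v), A %*% v, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("same-mating sister relationship decreases with S and D", {
  sib_rel <- function(S, D) {
    ## S sister DPQs (daughters of queen 2, open-mated) serve one mating of
    ## queen 1; S = 1 is the dummy single-sire limit of the same structure
    entry <- if (S == 1L)
      ped_row(3, "MATE", style = "DUMMY_DPQ", dpq_dam = 2, dpq_dam_mate = 6,
              S = 1, D = D)
    else
      ped_row(3, "MATE", style = "PS_GROUP", dpq_dam = 2, dpq_dam_mate = 6,
              S = S, D = D)
    ped <- rbind(
      ped_row(1, "QUEEN"), ped_row(2, "QUEEN"),
      ped_row(6, "MATE", style = "OPEN_GROUP", S = 100, D = D),
      entry,
      ped_row(4, "QUEEN", dam = 1, sire_entry = 3),
      ped_row(5, "QUEEN", dam = 1, sire_entry = 3))
    fac <- build_factor(validate_pedigree(ped), "exact_per_mating")
    A <- dense_relationship(fac)
    A[fac$index["4"], fac$index["5"]]
  }
  for (D in c(4L, 8L, 16L)) {
    vals <- vapply(c(1L, 2L, 3L, 6L), sib_rel, 0, D = D)
    expect_true(all(diff(vals) < 1e-12))
  }
  for (S in c(1L, 3L)) {
    vals <- vapply(c(2L, 8L, 32L), sib_rel, 0, S = S)
    expect_true(all(diff(vals) < 1e-12))
  }
})

test_that("group-level and exact modes differ by at most (1/D)/2", {
  for (ped in list(toy_identified(), toy_three_gen())) {
    fg <- build_factor(ped, "group_level")
    fe <- build_factor(ped, "exact_per_mating")
    Ag <- dense_relationship(fg)
    Ae <- dense_relationship(fe)
    common <- intersect(fg$entity$ped_id, fe$entity$ped_id)
    ig <- match(common, fg$entity$ped_id)
    ie <- match(common, fe$entity$ped_id)
    D <- 8
    expect_lt(max(abs(Ag[ig, ig] - Ae[ie, ie])), (1 / D) / 2 + 1e-12)
  }
})

test_that("gene dropping confirms the exact-mode recursion on a mixed toy", {
  gd <- gene_drop_check(toy_three_gen(), n_loci = 2e4, seed = 9)
  expect_lt(gd$max_z, 5)
  expect_lt(gd$max_abs_dev, 0.02)
  ## founder pair: unrelated within Monte-Carlo noise
  i <- match(1L, gd$entities); j <- match(2L, gd$entities)
  expect_lt(abs(gd$empirical[i, j]), 3 * max(gd$se[i, j], 1e-3))
  expect_equal(gd$analytic[i, j], 0)
})

test_that("estimation-pedigree factor matches full dense recursion", {
  ## the production factor (core-set shortcut) must equal the dense tabular
  ## path entity by entity on a small simulated estimation pedigree
  s <- scheme_config(n_families = 3, n_bq = 4, n_dpq = 4, n_years = 4,
                     founders_per_family = 4)
  sim <- run_replicate(gene_params(), s, seed = 13)
  enc <- encode_scenario(sim, scenario_spec("I", "PS", "C_PSP"))
  fac <- build_factor(enc$ped)
  A <- dense_relationship(fac)
  ## diagonal identities by type: queens 1 + F, open group 1/S
  e <- fac$entity
  qs <- which(e$type == 1L)
  expect_equal(diag(A)[qs], e$a_self[qs], tolerance = 1e-12)
  expect_lt(max(abs(A %*% as.matrix(invert_factor(fac)) - diag(nrow(A)))),
            1e-8)
})
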