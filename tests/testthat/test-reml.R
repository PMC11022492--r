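test_that("MME assembly matches the hand-built Henderson system", {
  ## one founder colony: queen (1), open group (2), worker group (3)
  ped <- validate_pedigree(rbind(
    ped_row(1, "QUEEN"),
    ped_row(2, "MATE", style = "OPEN_GROUP", S = 100, D = 8),
    ped_row(3, "WORKER_GROUP", dam = 1, sire_entry = 2)))
  fac <- build_factor(ped, "group_level")
  perf <- data.frame(colony_id = 1, queen_id = 1, worker_group_id = 3,
                     mate_entry_id = 2, year = 0,
                     open_group_label = "BASE_OPEN", phenotype = 2.5)
  model <- build_model(perf, fac)
  G0 <- diag(2); ve <- 1
  mme <- assemble_mme(model, invert_factor(fac), G0, ve)
  ## dimension: 1 fixed + 2 traits x 3 entities
  expect_equal(dim(mme$C), c(7L, 7L))
  A <- dense_relationship(fac)
  M <- cbind(1, as.matrix(model$Zw), as.matrix(model$Zq))
  Cexp <- crossprod(M) / ve +
    rbind(0, cbind(0, kronecker(solve(G0), solve(A))))
  expect_equal(as.matrix(mme$C), Cexp, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(mme$rhs, drop(crossprod(M, 2.5)) / ve, ignore_attr = TRUE)
  ## zero phenotypes give identically zero BLUE/BLUP solutions
  expect_equal(max(abs(Matrix::solve(mme$C, mme$rhs * 0))), 0)
  expect_error(assemble_mme(model, invert_factor(fac), matrix(0, 2, 2), 1),
               "positive definite")
})

test_that("AI-REML matches dense restricted-likelihood maximization", {
  d <- toy_reml_data()
  fit <- reml_fit(d$model, d$factor)
  expect_true(fit$converged)
  A <- dense_relationship(d$factor)
  oracle <- dense_neg2rl(d$model, A)
  ## likelihood value identity at the fitted point (MME vs V formulation)
  expect_equal(oracle(fit$estimates[1:4]), fit$neg2logRL, tolerance = 1e-8)
  o <- optim(c(5, 0, 5, 35), oracle, method = "Nelder-Mead",
             control = list(maxit = 2e4, reltol = 1e-14))
  for (k in 1:3)
    o <- optim(o$par, oracle, method = "Nelder-Mead",
               control = list(maxit = 2e4, reltol = 1e-15))
  expect_lt(max(abs(o$par - fit$estimates[1:4])), 1e-4)
  expect_lt(abs(o$value - fit$neg2logRL), 1e-6)
  ## -2logRL never increases over accepted iterations
  expect_true(all(diff(fit$trace$neg2logRL) <= 1e-12))
  ## predicted SEs are positive and finite at the optimum
  expect_true(all(is.finite(fit$se_pred) & fit$se_pred > 0))
})

test_that("estimates are invariant to record permutation", {
  d <- toy_reml_data()
  fit1 <- reml_fit(d$model, d$factor)
  set.seed(10)
  perm <- sample(nrow(d$enc$perf))
  model2 <- build_model(d$enc$perf[perm, ], d$factor)
  fit2 <- reml_fit(model2, d$factor)
  expect_equal(fit1$estimates, fit2$estimates, tolerance = 1e-6)
  expect_equal(fit1$neg2logRL, fit2$neg2logRL, tolerance = 1e-8)
})

test_that("the estimated genetic correlation stays inside [-1, 1]", {
  ## a deliberately under-informative dataset drives r_wq to the boundary
  scheme <- scheme_config(n_families = 3, n_bq = 6, n_dpq = 4, n_years = 2,
                          founders_per_family = 6)
  sim <- run_replicate(gene_params(), scheme, seed = 12)
  enc <- encode_scenario(sim, scenario_spec("I", "SS", "C_SSP"))
  fac <- build_factor(enc$ped)
  fit <- reml_fit(build_model(enc$perf, fac), fac)
  expect_gte(fit$r_wq, -1)
  expect_lte(fit$r_wq, 1)
  expect_gte(min(eigen(fit$G0, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("residual-only reduction equals the OLS residual variance", {
  d <- toy_reml_data()
  X <- as.matrix(d$model$X); y <- d$model$y
  ve <- reml_residual_only(y, X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  r <- y - H %*% y
  expect_equal(ve, sum(r^2) / (length(y) - qr(X)$rank))
})

test_that("queens absent from the data get finite relative-regressed EBVs", {
  d <- toy_reml_data()
  fit <- reml_fit(d$model, d$factor)
  tab <- ebv_table(fit, d$factor, d$enc$ped)
  expect_equal(nrow(tab), sum(d$enc$ped$kind == "QUEEN"))
  expect_true(all(is.finite(tab$ebv_w) & is.finite(tab$ebv_q)))
  ## queens without own records (died before phenotyping) still have EBVs
  dead <- d$sim$queens$id[is.na(d$sim$queens$phenotype) &
                            d$sim$queens$year > 0]
  dead_ped <- d$enc$queen_map[dead]
  expect_true(all(dead_ped %in% tab$ped_id))
  expect_true(any(tab$ebv_w[tab$ped_id %in% dead_ped] != 0))
  ## EBVs track true breeding values across cohorts
  bq <- d$sim$queens[d$sim$queens$role == "BQ", ]
  eb <- tab[match(d$enc$queen_map[bq$id], tab$ped_id), ]
  expect_gt(cor(tapply(bq$bw, bq$year, mean),
                tapply(eb$ebv_w, bq$year, mean)), 0.5)
})
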