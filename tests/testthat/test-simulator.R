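test_that("haplodiploid inheritance has the stated moments and limits", {
  params <- gene_params()
  set.seed(1)
  ## degenerate variance: everything deterministic
  p0 <- gene_params(0, 0, 0, var_e = 30)
  f0 <- make_founders(p0, 50)
  expect_true(all(f0$bv == 0) && all(f0$drone_w == 0))
  dam <- c(4, -2); drone <- c(1, 0.5)
  expect_equal(drop(inherit_queen(dam, 0, drone, p0)), dam / 2 + drone)
  ## fully inbred dam: no Mendelian sampling on her gamete
  expect_equal(drop(inherit_queen(dam, 1, drone, params)), dam / 2 + drone)
  expect_equal(drop(inherit_drone(dam, 1, params)), dam / 2)

  n <- 1e5
  ## base dam x base drone: Var(w) = (1/4 + 1/4 + 1/2) var_w
  dams <- rbvn_test(n, params$G0)
  drones <- rbvn_test(n, params$G0 / 2)
  off <- inherit_queen(dams, 0, drones, params)
  se3 <- 3 * params$var_w * sqrt(2 / n)
  expect_lt(abs(var(off[, 1]) - params$var_w), se3)
  ## drones from non-inbred dams: Var = var_w / 2
  dr <- inherit_drone(dams, 0, params)
  expect_lt(abs(var(dr[, 1]) - params$var_w / 2), 3 * (params$var_w / 2) *
              sqrt(2 / n))
  ## Mendelian term only: zero dams
  dr0 <- inherit_drone(matrix(0, n, 2), 0, params)
  expect_lt(abs(var(dr0[, 1]) - params$var_w / 4), 3 * (params$var_w / 4) *
              sqrt(2 / n))
})

test_that("worker groups average the drone genomes", {
  expect_equal(drop(make_worker_group(c(0, 0), matrix(0, 1, 8),
                                      matrix(0, 1, 8))), c(0, 0))
  wg <- make_worker_group(c(2, 0), matrix(1, 1, 8), matrix(0, 1, 8))
  expect_equal(drop(wg), c(2, 0))              # 1/2 * 2 + mean(1) = 2
  ## variance of the drone mean: (1/D) * var_w/2 at zero queen
  set.seed(2)
  params <- gene_params()
  n <- 2e4
  dr <- rbvn_test(n * 8, params$G0 / 2)
  wg <- make_worker_group(matrix(0, n, 2), matrix(dr[, 1], n, 8),
                          matrix(dr[, 2], n, 8))
  expect_lt(abs(var(wg[, 1]) - 0.625), 3 * 0.625 * sqrt(2 / n))
})

test_that("founder sampling recovers the base-population covariance", {
  set.seed(3)
  params <- gene_params()
  fo <- make_founders(params, 1e4)
  se3 <- 3 * params$var_w * sqrt(2 / 1e4)
  expect_lt(abs(var(fo$bv[, 1]) - params$var_w), se3)
  expect_lt(abs(var(fo$bv[, 2]) - params$var_q), se3)
  expect_lt(abs(mean(fo$bv)), 3 * sqrt(10 / 2e4))
})

test_that("controlled mating allocates drone mothers as specified", {
  set.seed(4)
  ss <- controlled_mating(200, c(7L, 8L, 9L), "SS", 8)
  expect_true(all(apply(ss, 1, function(r) length(unique(r)) == 1L)))
  expect_true(all(ss %in% 7:9))
  ps <- controlled_mating(2000, c(7L, 8L, 9L), "PS", 8)
  shares <- table(ps) / length(ps)
  expect_true(all(abs(shares - 1 / 3) <
                    3 * sqrt((1 / 3) * (2 / 3) / length(ps))))
  expect_error(controlled_mating(2, integer(0), "SS"), "empty")
})

test_that("heterogeneous open mating centers drones on -alpha / +alpha", {
  set.seed(5)
  params <- gene_params(alpha = c(sqrt(10) / 2, sqrt(10) / 2))
  a <- open_mating(500, params, "A")
  b <- open_mating(500, params, "B")
  gap <- mean(b$drone_q) - mean(a$drone_q)
  expect_lt(abs(gap - sqrt(10)), 3 * sqrt(2 * 5 / 4000))
  base <- open_mating(500, params, "BASE")
  expect_lt(abs(mean(base$drone_q)), 3 * sqrt(5 / 4000))
})

test_that("one replicate reproduces the structural record counts", {
  sim <- cached_sim12()                        # 12 maternal families
  q <- sim$queens
  expect_equal(nrow(q), 216L + 10L * 12L * 44L)
  expect_equal(sum(!is.na(q$phenotype)), 216L + 10L * 12L * 33L)
  ## per family and year: 18 BQ and 15 DPQ colonies phenotyped
  ph <- q[!is.na(q$phenotype) & q$year > 0, ]
  cnt <- table(ph$role, ph$year)
  expect_true(all(cnt["BQ", ] == 12L * 18L))
  expect_true(all(cnt["DPQ", ] == 12L * 15L))
  ## balanced group use: every group serves the same number of matings
  tab <- table(q$mate_group[q$mate_group > 0])
  expect_true(all(tab == (12L * 24L) / 8L))
  ## fathers of controlled-mated cohorts are the recorded drone mothers
  ctrl <- q[q$mate_subpop == "CTRL", ]
  expect_true(all(ctrl$year >= 3L))
  kids <- q[q$dam %in% ctrl$id[ctrl$selected_dam], ]
  expect_true(all(kids$father > 0L))
})

test_that("replicates are bit-for-bit reproducible from the seed", {
  s <- scheme_config(n_families = 4, n_bq = 6, n_dpq = 4, n_years = 4,
                     founders_per_family = 5)
  a <- run_replicate(gene_params(), s, seed = 99)
  b <- run_replicate(gene_params(), s, seed = 99)
  expect_identical(a$queens, b$queens)
  expect_identical(a$drone_mothers, b$drone_mothers)
  c <- run_replicate(gene_params(), s, seed = 100)
  expect_false(identical(a$queens$bw, c$queens$bw))
})

test_that("selection creates positive genetic trends; random choice does not", {
  s <- scheme_config(n_families = 12L)
  sel <- cached_sim12()$queens
  rnd <- run_replicate(gene_params(), s, seed = 4242,
                       random_selection = TRUE)$queens
  tr_sel <- genetic_trend(with(sel[sel$role == "BQ", ],
                               data.frame(year = year, w = bw, q = bq)), 1:10)
  tr_rnd <- genetic_trend(with(rnd[rnd$role == "BQ", ],
                               data.frame(year = year, w = bw, q = bq)), 1:10)
  expect_gt(tr_sel[["w"]], 0.15)
  expect_gt(tr_sel[["q"]], 0.15)
  expect_lt(abs(tr_rnd[["w"]]), tr_sel[["w"]] / 2)
  expect_lt(abs(tr_rnd[["q"]]), tr_sel[["q"]] / 2)
})

test_that("two-subpopulation allocation is balanced within each year", {
  s <- scheme_config(n_families = 12L, open_structure = "TWO_SUBPOPS",
                     n_years = 4L)
  p <- gene_params(alpha = c(sqrt(10) / 2, sqrt(10) / 2))
  sim <- run_replicate(p, s, seed = 7)
  dpq <- sim$queens[sim$queens$role == "DPQ", ]
  alloc <- table(dpq$year, dpq$mate_subpop)
  expect_true(all(alloc[, c("A", "B")] == 6L * 20L))
  ## allocation is by whole sister-group
  byfam <- unique(dpq[, c("year", "family", "mate_subpop")])
  expect_equal(nrow(byfam), 4L * 12L)
})
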