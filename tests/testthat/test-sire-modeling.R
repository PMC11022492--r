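enc_cache <- new.env(parent = emptyenv())
enc_for <- function(set, sim_ctrl, estim_ctrl, estim_open = "O_SinglePSP") {
  key <- paste(set, sim_ctrl, estim_ctrl, estim_open, sep = "_")
  if (is.null(enc_cache[[key]])) {
    sc <- scenario_spec(set, sim_ctrl, estim_ctrl, estim_open)
    scheme <- list(n_families = 6L, n_years = 5L)
    params <- gene_params(alpha = if (set == "II") rep(sqrt(10) / 2, 2)
                          else c(0, 0))
    s <- do.call(scheme_config,
                 c(scheme, list(controlled_style = sim_ctrl,
                                open_structure = if (set == "II")
                                  "TWO_SUBPOPS" else "HOMOGENEOUS")))
    sim <- run_replicate(params, s, seed = 31)
    set.seed(55)   # encoding of PS matings as identified sires is random
    enc_cache[[key]] <- list(sim = sim, enc = encode_scenario(sim, sc))
  }
  enc_cache[[key]]
}

test_that("identified single-sire modeling reproduces the true sire side", {
  x <- enc_for("I", "SS", "C_SSP")
  ped <- x$enc$ped; sim <- x$sim
  expect_silent(validate_pedigree(ped))
  ## every identified member is the true drone mother of that mating; each
  ## phenotyped controlled queen's worker group points at her mate entry
  ctrl <- sim$queens[sim$queens$mate_subpop == "CTRL" &
                       !is.na(sim$queens$phenotype), ]
  truth <- x$enc$queen_map[sim$drone_mothers[ctrl$id, 1L]]
  wg <- ped[ped$kind == "WORKER_GROUP", ]
  wg_of <- setNames(wg$sire_entry, wg$dam)
  ent <- ped[match(wg_of[as.character(x$enc$queen_map[ctrl$id])], ped$id), ]
  expect_true(all(ent$style == "IDENTIFIED_DPQ"))
  expect_equal(ent$member, unname(truth))
  expect_true(all(ent$S == 1L & ent$D == 8L))
})

test_that("dummy-sire and pseudo-sire modes create the stated entry counts", {
  x1 <- enc_for("I", "PS", "C_dummySSP_per_DPQdam")
  ped1 <- x1$enc$ped
  dummies <- ped1[ped1$style == "DUMMY_DPQ", ]
  ## one shared dummy per used DPQ group: 4 groups/year in a 6-family scheme
  n_groups <- length(x1$sim$groups)
  expect_equal(nrow(dummies), n_groups)
  x2 <- enc_for("I", "PS", "C_dummySSP_per_Q")
  ped2 <- x2$enc$ped
  ctrl_n <- sum(x2$sim$queens$mate_subpop == "CTRL" &
                  !is.na(x2$sim$queens$phenotype))
  expect_equal(sum(ped2$style == "DUMMY_DPQ"), ctrl_n)
  x3 <- enc_for("I", "PS", "C_PSP")
  ps <- x3$enc$ped[x3$enc$ped$style == "PS_GROUP", ]
  expect_equal(nrow(ps), length(x3$sim$groups))
  expect_true(all(ps$S == 3L & ps$D == 8L))
  ## dummy entries descend from the true DPQ dam and her mate entry
  gd <- vapply(x1$sim$groups, function(g) g$dam, 0L)
  expect_setequal(dummies$dpq_dam, x1$enc$queen_map[gd])
})

test_that("dam links are never altered by sire re-encoding", {
  for (mode in c("C_SSP", "C_dummySSP_per_DPQdam", "C_dummySSP_per_Q",
                 "C_PSP")) {
    x <- enc_for("I", "PS", mode)
    ped <- x$enc$ped
    q <- ped[ped$kind == "QUEEN", ]
    simq <- x$sim$queens
    expect_equal(q$dam, unname(ifelse(simq$dam > 0,
                                      x$enc$queen_map[pmax(simq$dam, 1L)],
                                      0L)))
  }
})

test_that("open-mating sire models follow the scenario definitions", {
  x <- enc_for("II", "SS", "C_SSP", "O_TwoPSP")
  open <- x$enc$ped[x$enc$ped$style == "OPEN_GROUP", ]
  expect_equal(nrow(open), 3L)                  # base + one per subpopulation
  expect_true(all(open$S == 100L))
  ## DPQ worker groups use the subpopulation entry, initial BQs the base one
  perf <- x$enc$perf
  expect_setequal(unique(perf$mate_entry_id[perf$open_group_label %in%
                                              c("SUBPOP_A", "SUBPOP_B")]),
                  open$id[2:3])
  xn <- enc_for("II", "SS", "C_SSP", "O_NoPheno")
  full <- enc_for("II", "SS", "C_SSP", "O_TwoPSP")$enc$perf
  expect_equal(nrow(xn$enc$perf), sum(full$role != "DPQ"))
  expect_true(all(xn$enc$perf$role != "DPQ"))
  expect_equal(sum(xn$enc$ped$style == "OPEN_GROUP"), 1L)
  xf <- enc_for("II", "SS", "C_SSP", "O_FixedGroup")
  lab <- xf$enc$perf$open_group_label
  ctrl <- xf$sim$queens$mate_subpop[xf$enc$perf$colony_id] == "CTRL"
  expect_true(all(lab[ctrl] == "CONTROLLED"))
  expect_setequal(unique(lab[!ctrl]), c("BASE_OPEN", "SUBPOP_A", "SUBPOP_B"))
})

test_that("every scenario yields a valid estimation pedigree", {
  sim <- cached_sim12()
  for (sc in all_scenarios()) {
    if (sc$set == "II") next   # cached sim is homogeneous; Set II covered above
    enc <- encode_scenario(sim, sc)
    expect_silent(validate_pedigree(enc$ped))
    expect_equal(sum(sim$queens$survived & !is.na(sim$queens$phenotype)),
                 nrow(enc$perf))
  }
})
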