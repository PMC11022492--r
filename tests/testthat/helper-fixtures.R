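## Shared toy pedigrees and cached mid-size objects for the suite.

## Founder pair mated single-sire (identified DPQ, D = 8): worker group and
## two daughter queens. The textbook case for the worker-group residual and
## the same-mating sister relationship.
toy_identified <- function() {
  validate_pedigree(rbind(
    ped_row(1, "QUEEN"), ped_row(2, "QUEEN"),
    ped_row(3, "MATE", style = "IDENTIFIED_DPQ", member = 2, S = 1, D = 8),
    ped_row(4, "WORKER_GROUP", dam = 1, sire_entry = 3),
    ped_row(5, "QUEEN", dam = 1, sire_entry = 3, birth_year = 1),
    ped_row(6, "QUEEN", dam = 1, sire_entry = 3, birth_year = 1)))
}

## Three-generation toy covering every entity style: open group, identified
## single-sire mating (S = 1, D = 8), pseudo-sire group (S = 3, D = 8) and
## an inbred mating between relatives. 15 pedigree rows, < 50 entities.
toy_three_gen <- function() {
  validate_pedigree(rbind(
    ped_row(1, "QUEEN"), ped_row(2, "QUEEN"), ped_row(3, "QUEEN"),
    ped_row(4, "MATE", style = "OPEN_GROUP", S = 10, D = 8),
    ped_row(5, "MATE", style = "IDENTIFIED_DPQ", member = 2, S = 1, D = 8),
    ped_row(6, "WORKER_GROUP", dam = 1, sire_entry = 5),
    ped_row(7, "QUEEN", dam = 1, sire_entry = 5, birth_year = 1),
    ped_row(8, "QUEEN", dam = 1, sire_entry = 5, birth_year = 1),
    ped_row(9, "MATE", style = "PS_GROUP", dpq_dam = 3, dpq_dam_mate = 4,
            S = 3, D = 8),
    ped_row(10, "WORKER_GROUP", dam = 7, sire_entry = 9),
    ped_row(11, "QUEEN", dam = 7, sire_entry = 9, birth_year = 2),
    ped_row(12, "QUEEN", dam = 8, sire_entry = 9, birth_year = 2),
    ped_row(13, "MATE", style = "IDENTIFIED_DPQ", member = 11, S = 1, D = 8),
    ped_row(14, "WORKER_GROUP", dam = 12, sire_entry = 13),
    ped_row(15, "QUEEN", dam = 12, sire_entry = 13, birth_year = 3)))
}

## Small but identified REML dataset: 4 families, 5 years (the last three
## controlled-mated), 160 colony records. The seed is fixed to a dataset
## whose restricted-likelihood optimum is interior (|r_wq| < 1): datasets
## this small can otherwise have boundary or corner optima at which the
## component parameters are not separately identified and a parameter-wise
## comparison between optimizers is meaningless.
toy_reml_data <- function(seed = 3) {
  scheme <- scheme_config(n_families = 4, n_bq = 6, n_dpq = 4, n_years = 5,
                          founders_per_family = 5)
  params <- gene_params()
  sim <- run_replicate(params, scheme, seed = seed)
  enc <- encode_scenario(sim, scenario_spec("I", "SS", "C_SSP"))
  fac <- build_factor(enc$ped)
  model <- build_model(enc$perf, fac)
  list(sim = sim, enc = enc, factor = fac, model = model, params = params)
}

## Independent dense-matrix restricted likelihood (V-based formulation, no
## mixed-model equations): the oracle for the sparse-MME implementation.
dense_neg2rl <- function(model, A) {
  X <- as.matrix(model$X); y <- model$y
  Zw <- as.matrix(model$Zw); Zq <- as.matrix(model$Zq)
  ZwA <- Zw %*% A; ZqA <- Zq %*% A
  function(th) {
    G0 <- matrix(c(th[1], th[2], th[2], th[3]), 2)
    if (min(eigen(G0, TRUE, TRUE)$values) <= 1e-8 || th[4] <= 1e-8)
      return(1e10)
    V <- th[4] * diag(length(y)) + G0[1, 1] * ZwA %*% t(Zw) +
      G0[2, 2] * ZqA %*% t(Zq) +
      G0[1, 2] * (ZwA %*% t(Zq) + ZqA %*% t(Zw))
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
    as.numeric(determinant(V, logarithm = TRUE)$modulus +
                 determinant(XVX, logarithm = TRUE)$modulus +
                 t(y) %*% P %*% y)
  }
}

## Bivariate normal draws (thin wrapper over the package-internal sampler).
rbvn_test <- function(n, cov, center = c(0, 0)) {
  apisim:::rbvn(n, cov, center)
}

## Mid-size simulation shared by several structural tests (computed once).
.fixture_cache <- new.env(parent = emptyenv())
cached_sim12 <- function() {
  if (is.null(.fixture_cache$sim12)) {
    .fixture_cache$sim12 <- run_replicate(
      gene_params(), scheme_config(n_families = 12L), seed = 4242)
  }
  .fixture_cache$sim12
}
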