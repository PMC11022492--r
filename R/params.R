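#' Genetic parameter set for the colony model
#'
#' Holds the true (co)variances of the bivariate queen/worker genetic model:
#' a colony phenotype is `y = year + a_W(worker group) + a_Q(queen) + e`,
#' with `(a_W, a_Q)` additive genetic effects whose base-population
#' (co)variance matrix is `G0 = [[var_w, cov_wq], [cov_wq, var_q]]`.
#' Haploid drones carry breeding values with (co)variance `G0 / 2`.
#'
#' @param var_w Additive variance of worker effects (trait units squared).
#' @param var_q Additive variance of queen effects.
#' @param cov_wq Additive covariance between worker and queen effects.
#' @param var_e Residual variance.
#' @param var_year Variance of the yearly environmental level. Year effects
#'   are drawn once per calendar year in the simulation and always treated
#'   as *fixed* in the estimation model.
#' @param alpha Length-2 numeric `(alpha_w, alpha_q)`: half the gap between
#'   the mean breeding values of the two open-mating drone subpopulations
#'   (drones are centred on `-alpha` and `+alpha`). Only used when the
#'   open-mating structure is heterogeneous.
#' @return An object of class `gene_params`.
#' @examples
#' gene_params()               # base set: var_w = var_q = 10 = var_e / 3
#' gene_params_preset(4)       # doubled worker variance, r_wq = -0.5
#' @export
gene_params <- function(var_w = 10, var_q = 10, cov_wq = 0, var_e = 30,
                        var_year = 10, alpha = c(0, 0)) {
  G0 <- matrix(c(var_w, cov_wq, cov_wq, var_q), 2L, 2L)
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("G0 = [[var_w, cov_wq], [cov_wq, var_q]] must be positive semi-definite")
  if (var_e < 0 || var_year < 0) stop("variances must be non-negative")
  stopifnot(length(alpha) == 2L)
  structure(list(var_w = var_w, var_q = var_q, cov_wq = cov_wq,
                 var_e = var_e, var_year = var_year,
                 alpha = as.numeric(alpha), G0 = G0),
            class = "gene_params")
}

#' @describeIn gene_params The four canonical parameter sets: worker variance
#'   10 or 20, queen variance 10, residual variance 30, and `r_wq` 0 or -0.5
#'   (covariance 0, 0, -5, or -sqrt(200)/2).
#' @param set Integer 1-4.
#' @export
gene_params_preset <- function(set = 1L, var_year = 10, alpha = c(0, 0)) {
  tab <- list(c(10, 10, 0), c(20, 10, 0), c(10, 10, -5),
              c(20, 10, -0.5 * sqrt(200)))
  if (!set %in% 1:4) stop("parameter set must be 1, 2, 3 or 4")
  p <- tab[[set]]
  gene_params(var_w = p[1], var_q = p[2], cov_wq = p[3], var_e = 30,
              var_year = var_year, alpha = alpha)
}

#' @export
print.gene_params <- function(x, ...) {
  r <- if (x$var_w > 0 && x$var_q > 0) x$cov_wq / sqrt(x$var_w * x$var_q) else NA
  cat("Genetic parameters: var_w =", x$var_w, " var_q =", x$var_q,
      " cov_wq =", round(x$cov_wq, 3), sprintf("(r_wq = %.2f)", r), "\n",
      "  var_e =", x$var_e, " var_year =", x$var_year,
      " alpha = (", paste(round(x$alpha, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Breeding scheme configuration
#'
#' The selection and mating design of the closed nucleus: per-dam offspring
#' counts, survival after the winter mortality event, selection fractions,
#' mating-group composition, and the mating style used for controlled
#' inseminations.
#'
#' Defaults reproduce the reference design: 24 maternal families, founders
#' numbering `18 * n_families` (432), 24 breeding-queen (BQ) and 20
#' drone-producing-queen (DPQ) offspring per selected dam per year, 75%
#' colony survival (18 BQ and 15 DPQ colonies phenotyped per dam), one
#' replacement BQ selected within each maternal family, two-thirds of DPQ
#' dams selected across families, 3 sister DPQs used per mating group, 8
#' drones per mating, and 10 years of breeding after the founder year.
#'
#' @param n_families Number of maternal families in the nucleus (12, 24, 36).
#' @param n_bq Offspring BQs produced per selected dam per year.
#' @param n_dpq Offspring DPQs produced per selected dam per year.
#' @param survival Fraction of colonies surviving the winter mortality event;
#'   applied exactly per family (`floor((1-survival) * n)` colonies die).
#' @param dpq_dam_fraction Fraction of dams selected on mean DPQ-colony
#'   phenotype to contribute mating groups.
#' @param n_dpq_group Sister DPQs drawn at random per selected family to
#'   form a mating group.
#' @param n_drones Drones per mating (D).
#' @param n_years Breeding years after the founder year (cohorts 1..n_years).
#' @param controlled_style `"SS"` (all 8 drones from one DPQ chosen at random
#'   among the group) or `"PS"` (each drone's mother drawn with replacement
#'   from the group).
#' @param open_structure `"HOMOGENEOUS"` (all open-mating drones from one
#'   base population) or `"TWO_SUBPOPS"` (DPQs mate drones from one of two
#'   subpopulations shifted by -alpha / +alpha, families allocated balanced).
#' @param founders_per_family Founder BQs per family slot; founder count is
#'   `founders_per_family * n_families` (default 18, so 432 at 24 families).
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(n_families = 24L, n_bq = 24L, n_dpq = 20L,
                          survival = 0.75, dpq_dam_fraction = 2 / 3,
                          n_dpq_group = 3L, n_drones = 8L, n_years = 10L,
                          controlled_style = c("SS", "PS"),
                          open_structure = c("HOMOGENEOUS", "TWO_SUBPOPS"),
                          founders_per_family = 18L) {
  controlled_style <- match.arg(controlled_style)
  open_structure <- match.arg(open_structure)
  n_bq_surv <- round(survival * n_bq)
  n_dpq_surv <- round(survival * n_dpq)
  n_dpq_dams <- round(dpq_dam_fraction * n_families)
  if (n_families < 2L || n_bq < 2L || n_dpq < n_dpq_group || n_drones < 1L)
    stop("infeasible scheme counts")
  if (open_structure == "TWO_SUBPOPS" && n_families %% 2L != 0L)
    stop("TWO_SUBPOPS needs an even number of families for balanced allocation")
  structure(list(n_families = as.integer(n_families), n_bq = as.integer(n_bq),
                 n_dpq = as.integer(n_dpq), survival = survival,
                 n_bq_surv = as.integer(n_bq_surv),
                 n_dpq_surv = as.integer(n_dpq_surv),
                 dpq_dam_fraction = dpq_dam_fraction,
                 n_dpq_dams = as.integer(n_dpq_dams),
                 n_dpq_group = as.integer(n_dpq_group),
                 n_drones = as.integer(n_drones),
                 n_years = as.integer(n_years),
                 controlled_style = controlled_style,
                 open_structure = open_structure,
                 n_founders = as.integer(founders_per_family * n_families)),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("Breeding scheme:", x$n_founders, "founders,", x$n_families,
      "families x", x$n_years, "years;", x$controlled_style,
      "controlled mating;", x$open_structure, "open mating\n",
      " per dam/year:", x$n_bq, "BQ /", x$n_dpq, "DPQ offspring;",
      x$n_bq_surv, "BQ /", x$n_dpq_surv, "DPQ colonies phenotyped\n",
      " ", x$n_dpq_dams, "DPQ dams selected,", x$n_dpq_group,
      "DPQs per mating group,", x$n_drones, "drones per mating\n")
  invisible(x)
}

#' Scenario specification: how sires are modeled in the estimation pedigree
#'
#' Pairs a simulation configuration with an estimation-side sire model.
#' Set I varies the controlled-mating sire model under a homogeneous
#' open-mating drone population; Set II fixes single-sire controlled mating
#' but mates DPQs to a heterogeneous (two-subpopulation) drone population
#' and varies how that heterogeneity is accommodated.
#'
#' @param set `"I"` or `"II"`.
#' @param sim_controlled Simulated controlled mating, `"SS"` or `"PS"`.
#' @param estim_controlled Sire model for controlled matings:
#'   `"C_SSP"` (identified single DPQ; the true one under SS, a random
#'   sister under PS), `"C_dummySSP_per_DPQdam"` (one dummy DPQ shared by
#'   all matings of a DPQ dam's group), `"C_dummySSP_per_Q"` (a fresh dummy
#'   DPQ per mating), `"C_PSP"` (a pseudo-sire group of 3 sister DPQs).
#' @param estim_open Open-mating model: `"O_SinglePSP"` (one shared
#'   100-member open pseudo-sire), `"O_NoPheno"` (single pseudo-sire, DPQ
#'   colony records excluded), `"O_TwoPSP"` (one open pseudo-sire per drone
#'   subpopulation plus the base one), `"O_FixedGroup"` / `"O_RandGroup"`
#'   (single pseudo-sire plus a fixed/random non-genetic drone-origin effect
#'   with levels base, subpopulation A, subpopulation B).
#' @param open_group_size Assumed number of unknown unrelated DPQs in an
#'   open-mating pseudo-sire (default 100).
#' @param params_set Genetic parameter set id (1-4), see
#'   [gene_params_preset()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(set = c("I", "II"),
                          sim_controlled = c("SS", "PS"),
                          estim_controlled = c("C_SSP",
                                               "C_dummySSP_per_DPQdam",
                                               "C_dummySSP_per_Q", "C_PSP"),
                          estim_open = c("O_SinglePSP", "O_NoPheno",
                                         "O_TwoPSP", "O_FixedGroup",
                                         "O_RandGroup"),
                          open_group_size = 100L, params_set = 1L) {
  set <- match.arg(set)
  sim_controlled <- match.arg(sim_controlled)
  estim_controlled <- match.arg(estim_controlled)
  estim_open <- match.arg(estim_open)
  if (set == "I" && estim_open != "O_SinglePSP")
    stop("Set I pairs any controlled sire model with O_SinglePSP only")
  if (set == "II" && (sim_controlled != "SS" || estim_controlled != "C_SSP"))
    stop("Set II fixes SS simulation and C_SSP controlled modeling")
  structure(list(set = set, sim_controlled = sim_controlled,
                 estim_controlled = estim_controlled, estim_open = estim_open,
                 open_group_size = as.integer(open_group_size),
                 params_set = as.integer(params_set),
                 id = paste0("set", set, "_", sim_controlled, "_",
                             if (set == "I") estim_controlled else estim_open)),
            class = "scenario_spec")
}

#' All scenarios of the study design
#'
#' @return A list of [scenario_spec()] objects: the 8 Set I combinations
#'   (SS/PS simulation crossed with the four controlled sire models) and the
#'   4 Set II open-mating models.
#' @export
all_scenarios <- function(params_set = 1L) {
  set1 <- unlist(lapply(c("SS", "PS"), function(sim) {
    lapply(c("C_SSP", "C_dummySSP_per_DPQdam", "C_dummySSP_per_Q", "C_PSP"),
           function(em) scenario_spec("I", sim, em, "O_SinglePSP",
                                      params_set = params_set))
  }), recursive = FALSE)
  set2 <- lapply(c("O_NoPheno", "O_TwoPSP", "O_FixedGroup", "O_RandGroup"),
                 function(om) scenario_spec("II", "SS", "C_SSP", om,
                                            params_set = params_set))
  c(set1, set2)
}
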