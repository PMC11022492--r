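#' Matrix square root used for bivariate breeding-value draws
#'
#' Eigen-based, tolerant of singular (even all-zero) covariance matrices.
#' @noRd
cov_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  diag(sqrt(vals), nrow = length(vals)) %*% t(e$vectors)
}

rbvn <- function(n, cov, center = c(0, 0)) {
  z <- matrix(rnorm(2L * n), n, 2L) %*% cov_sqrt(cov)
  z[, 1L] <- z[, 1L] + center[1L]
  z[, 2L] <- z[, 2L] + center[2L]
  z
}

#' Breeding-value inheritance under the haplodiploid infinitesimal model
#'
#' Queens are diploid: an offspring queen's breeding value is
#' `a = a_dam / 2 + psi + g_drone`, where `psi` is the dam-gamete Mendelian
#' sampling deviation with covariance `(1 - F_dam) * G0 / 4` and `g_drone`
#' is the (haploid) value of the father drone. Drones carry a single
#' maternal gamete: `g = a_dam / 2 + phi` with `phi` of covariance
#' `(1 - F_dam) * G0 / 4`, so unconditionally `Var(g) = G0 / 2` at any dam
#' inbreeding level. A colony's worker group takes the average worker
#' genome: `a_W = a_queen / 2 + mean(drone values)` with no further
#' worker-side Mendelian term (infinite worker-group limit).
#'
#' All three functions are vectorised over rows of the breeding-value
#' matrices (columns: worker trait, queen trait).
#'
#' @param dam_bv n x 2 matrix of dam breeding values.
#' @param dam_f Dam inbreeding coefficients (length n or 1).
#' @param drone_bv n x 2 matrix of father-drone haploid values.
#' @param params A [gene_params()] object.
#' @return An n x 2 matrix of breeding values.
#' @export
inherit_queen <- function(dam_bv, dam_f, drone_bv, params) {
  dam_bv <- rbind(dam_bv)
  n <- nrow(dam_bv)
  psi <- matrix(rnorm(2L * n), n, 2L) %*% cov_sqrt(params$G0 / 4)
  dam_bv / 2 + psi * sqrt(pmax(1 - dam_f, 0)) + rbind(drone_bv)
}

#' @rdname inherit_queen
#' @export
inherit_drone <- function(dam_bv, dam_f, params) {
  dam_bv <- rbind(dam_bv)
  n <- nrow(dam_bv)
  phi <- matrix(rnorm(2L * n), n, 2L) %*% cov_sqrt(params$G0 / 4)
  dam_bv / 2 + phi * sqrt(pmax(1 - dam_f, 0))
}

#' @rdname inherit_queen
#' @param queen_bv n x 2 matrix of colony-queen breeding values.
#' @param drone_w,drone_q n x D matrices of the D mating drones' haploid
#'   values (worker and queen trait).
#' @export
make_worker_group <- function(queen_bv, drone_w, drone_q) {
  queen_bv <- rbind(queen_bv)
  drone_w <- rbind(drone_w)
  if (ncol(drone_w) < 1L) stop("worker group needs at least one drone")
  cbind(queen_bv[, 1L] / 2 + rowMeans(drone_w),
        queen_bv[, 2L] / 2 + rowMeans(rbind(drone_q)))
}

#' Founder population
#'
#' Generates the base breeding queens: unrelated, non-inbred, with
#' breeding values drawn from `N(0, G0)`, each open-mated to `n_drones`
#' independent base drones with haploid values `N(0, G0/2)`.
#'
#' @param params A [gene_params()] object.
#' @param n Number of founder queens.
#' @param n_drones Drones per mating.
#' @return A list with `bv` (n x 2 founder breeding values), `drone_w` and
#'   `drone_q` (n x n_drones haploid drone values), and `worker` (n x 2
#'   worker-group values).
#' @export
make_founders <- function(params, n, n_drones = 8L) {
  bv <- rbvn(n, params$G0)
  dr <- rbvn(n * n_drones, params$G0 / 2)
  drone_w <- matrix(dr[, 1L], n, n_drones)
  drone_q <- matrix(dr[, 2L], n, n_drones)
  list(bv = bv, drone_w = drone_w, drone_q = drone_q,
       worker = make_worker_group(bv, drone_w, drone_q))
}

#' Drone-mother allocation for one controlled mating group assignment
#'
#' Under single-sire (`"SS"`) mating one DPQ is chosen uniformly from the
#' sister group and produces all D drones; under pseudo-sire (`"PS"`)
#' mating each drone's mother is drawn uniformly *with replacement* from
#' the group.
#'
#' @param n_matings Number of matings to allocate.
#' @param group_members Vector of member DPQ ids (typically 3 sisters).
#' @param style `"SS"` or `"PS"`.
#' @param n_drones Drones per mating.
#' @return An `n_matings x n_drones` integer matrix of drone-mother ids.
#' @export
controlled_mating <- function(n_matings, group_members, style = c("SS", "PS"),
                              n_drones = 8L) {
  style <- match.arg(style)
  if (length(group_members) < 1L) stop("empty DPQ group")
  if (style == "SS") {
    chosen <- sample(group_members, n_matings, replace = TRUE)
    matrix(rep(chosen, n_drones), n_matings, n_drones)
  } else {
    matrix(sample(group_members, n_matings * n_drones, replace = TRUE),
           n_matings, n_drones)
  }
}

#' Open-mating drone draws
#'
#' Draws `n x n_drones` unrelated non-inbred drones. For the homogeneous
#' (base) population drones are centred on zero; for a heterogeneous
#' population, subpopulation `"A"` drones are centred on `-alpha` and
#' subpopulation `"B"` drones on `+alpha` (both traits).
#'
#' @param n Number of matings.
#' @param params A [gene_params()] object.
#' @param subpop `"BASE"`, `"A"` or `"B"`.
#' @param n_drones Drones per mating.
#' @return A list with `drone_w` and `drone_q` (`n x n_drones` matrices).
#' @export
open_mating <- function(n, params, subpop = c("BASE", "A", "B"),
                        n_drones = 8L) {
  subpop <- match.arg(subpop)
  center <- switch(subpop, BASE = c(0, 0), A = -params$alpha,
                   B = params$alpha)
  dr <- rbvn(n * n_drones, params$G0 / 2, center = center)
  list(drone_w = matrix(dr[, 1L], n, n_drones),
       drone_q = matrix(dr[, 2L], n, n_drones))
}

#' Simulate one replicate of the breeding program
#'
#' Runs the full closed-nucleus program: founder queens are phenotyped and
#' the best `n_families` across families become dams; every subsequent year
#' each selected dam produces `n_bq` breeding-queen (BQ) and `n_dpq`
#' drone-producing-queen (DPQ) offspring. BQ cohorts of years 1-2 are
#' open-mated (no DPQs are available yet); from year 3 on they are
#' controlled-mated to groups of `n_dpq_group` sister DPQs born two years
#' earlier (16 of 24 DPQ dams selected across families on mean DPQ-colony
#' phenotype, group-to-queen assignment balanced). All DPQ cohorts are
#' open-mated. Each cohort loses exactly 25% of its colonies per family
#' before phenotyping; one replacement BQ per family is then selected on
#' its own colony phenotype. Colony phenotypes are
#' `y = year_t + a_W + a_Q + e`.
#'
#' @param params A [gene_params()] object.
#' @param scheme A [scheme_config()] object.
#' @param seed Integer seed; all replicate randomness flows from it.
#' @param random_selection If `TRUE`, replaces both selection steps by
#'   random choice (used to verify that genetic trends vanish without
#'   selection).
#' @return An object of class `bee_sim`: a list with `queens` (one row per
#'   queen ever created: parents, true father DPQ, breeding values,
#'   inbreeding, mating and colony outcome), `drone_mothers`, `drone_w`,
#'   `drone_q` (per-mating drone data), `groups` (DPQ mating groups),
#'   `year_effects`, and the configuration.
#' @export
run_replicate <- function(params, scheme, seed = NULL,
                          random_selection = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nf <- scheme$n_families
  nb <- scheme$n_bq; nd <- scheme$n_dpq
  D <- scheme$n_drones; ny <- scheme$n_years
  n0 <- scheme$n_founders
  ntot <- n0 + ny * nf * (nb + nd)

  ## queen table (grown in creation order; id = row index)
  Q <- list(
    dam = integer(ntot), father = integer(ntot), year = integer(ntot),
    family = integer(ntot), role = character(ntot),
    bw = numeric(ntot), bq = numeric(ntot), F = numeric(ntot),
    survived = logical(ntot), phenotype = rep(NA_real_, ntot),
    mate_style = character(ntot), mate_group = integer(ntot),
    mate_subpop = character(ntot),
    worker_w = numeric(ntot), worker_q = numeric(ntot),
    selected_dam = logical(ntot))
  drone_mothers <- matrix(0L, ntot, D)
  drone_w <- matrix(NA_real_, ntot, D)
  drone_q <- matrix(NA_real_, ntot, D)

  year_effects <- rnorm(ny + 1L, 0, sqrt(params$var_year))

  ## tracked kinship over potential parents (a-scale: K[i,i] = 1 + F_i)
  kmax <- nf + ny * (nf + scheme$n_dpq_dams * scheme$n_dpq_group) + 8L
  K <- matrix(0, kmax, kmax)
  kidx <- integer(ntot)   # queen id -> row of K (0 = untracked)
  kn <- 0L
  track <- function(ids) {
    for (id in ids) {
      if (kidx[id] > 0L) next
      kn <<- kn + 1L
      d <- Q$dam[id]; f <- Q$father[id]
      di <- if (d > 0L) kidx[d] else 0L
      fi <- if (f > 0L) kidx[f] else 0L
      if (d > 0L && di == 0L) stop("untracked dam for queen ", id)
      if (kn > 1L) {
        row <- numeric(kn - 1L)
        if (di > 0L) row <- row + K[di, seq_len(kn - 1L)] / 2
        if (fi > 0L) row <- row + K[fi, seq_len(kn - 1L)] / 2
        K[kn, seq_len(kn - 1L)] <<- row
        K[seq_len(kn - 1L), kn] <<- row
      }
      K[kn, kn] <<- 1 + (if (di > 0L && fi > 0L) K[di, fi] / 2 else 0)
      kidx[id] <<- kn
    }
  }
  kin_a <- function(i, j) {       # additive relationship between tracked ids
    if (i == 0L || j == 0L) return(0)
    K[kidx[i], kidx[j]]
  }

  ## --- year 0: founders ---------------------------------------------------
  fid <- seq_len(n0)
  fo <- make_founders(params, n0, D)
  Q$role[fid] <- "FOUNDER"; Q$year[fid] <- 0L
  Q$bw[fid] <- fo$bv[, 1L]; Q$bq[fid] <- fo$bv[, 2L]
  Q$mate_style[fid] <- "OPEN"; Q$mate_subpop[fid] <- "BASE"
  Q$survived[fid] <- TRUE
  drone_w[fid, ] <- fo$drone_w; drone_q[fid, ] <- fo$drone_q
  Q$worker_w[fid] <- fo$worker[, 1L]; Q$worker_q[fid] <- fo$worker[, 2L]
  Q$phenotype[fid] <- year_effects[1L] + fo$worker[, 1L] + fo$bv[, 2L] +
    rnorm(n0, 0, sqrt(params$var_e))
  crit <- if (random_selection) runif(n0) else Q$phenotype[fid]
  dams <- fid[order(-crit, runif(n0))][seq_len(nf)]
  Q$selected_dam[dams] <- TRUE
  track(dams)

  groups <- list()      # per group: members, dam, year_used
  group_of_year <- list()  # group ids available for matings of year t
  next_id <- n0
  gid <- 0L

  for (t in seq_len(ny)) {
    ## --- produce offspring of the current dams ---------------------------
    n_off_b <- nf * nb; n_off_d <- nf * nd
    bq_ids <- next_id + seq_len(n_off_b)
    dpq_ids <- next_id + n_off_b + seq_len(n_off_d)
    next_id <- next_id + n_off_b + n_off_d
    for (blk in list(list(ids = bq_ids, per = nb, role = "BQ"),
                     list(ids = dpq_ids, per = nd, role = "DPQ"))) {
      ids <- blk$ids
      dam_of <- rep(dams, each = blk$per)
      fam_of <- rep(seq_len(nf), each = blk$per)
      pick <- sample.int(D, length(ids), replace = TRUE)
      fa <- drone_mothers[cbind(dam_of, pick)]
      dbv <- cbind(drone_w[cbind(dam_of, pick)],
                   drone_q[cbind(dam_of, pick)])
      bv <- inherit_queen(cbind(Q$bw[dam_of], Q$bq[dam_of]),
                          Q$F[dam_of], dbv, params)
      Q$dam[ids] <- dam_of; Q$father[ids] <- fa
      Q$year[ids] <- t; Q$family[ids] <- fam_of; Q$role[ids] <- blk$role
      Q$bw[ids] <- bv[, 1L]; Q$bq[ids] <- bv[, 2L]
      Q$F[ids] <- vapply(seq_along(ids),
                         function(k) kin_a(dam_of[k], fa[k]) / 2, 0)
    }

    ## --- mate the BQ cohort ----------------------------------------------
    if (t <= 2L || length(group_of_year) < t || is.null(group_of_year[[t]])) {
      om <- open_mating(n_off_b, params, "BASE", D)
      drone_w[bq_ids, ] <- om$drone_w; drone_q[bq_ids, ] <- om$drone_q
      Q$mate_style[bq_ids] <- "OPEN"; Q$mate_subpop[bq_ids] <- "BASE"
    } else {
      gids <- group_of_year[[t]]
      assign_g <- sample(rep(gids, length.out = n_off_b))
      Q$mate_style[bq_ids] <- scheme$controlled_style
      Q$mate_subpop[bq_ids] <- "CTRL"
      Q$mate_group[bq_ids] <- assign_g
      for (g in gids) {
        rows <- bq_ids[assign_g == g]
        mem <- groups[[g]]$members
        dm <- controlled_mating(length(rows), mem, scheme$controlled_style, D)
        drone_mothers[rows, ] <- dm
        mother_bw <- matrix(Q$bw[dm], nrow(dm), D)
        mother_bq <- matrix(Q$bq[dm], nrow(dm), D)
        mother_f <- matrix(Q$F[dm], nrow(dm), D)
        phi <- matrix(rnorm(2L * length(dm)), ncol = 2L) %*%
          cov_sqrt(params$G0 / 4)
        sc <- sqrt(pmax(1 - as.vector(mother_f), 0))
        drone_w[rows, ] <- mother_bw / 2 + matrix(phi[, 1L] * sc, nrow(dm), D)
        drone_q[rows, ] <- mother_bq / 2 + matrix(phi[, 2L] * sc, nrow(dm), D)
      }
    }

    ## --- mate the DPQ cohort (always open) --------------------------------
    if (scheme$open_structure == "TWO_SUBPOPS") {
      fam_sub <- rep("A", nf)
      fam_sub[sample.int(nf, nf %/% 2L)] <- "B"
      sub_of <- fam_sub[Q$family[dpq_ids]]
      for (sp in c("A", "B")) {
        rows <- dpq_ids[sub_of == sp]
        om <- open_mating(length(rows), params, sp, D)
        drone_w[rows, ] <- om$drone_w; drone_q[rows, ] <- om$drone_q
      }
      Q$mate_subpop[dpq_ids] <- sub_of
    } else {
      om <- open_mating(n_off_d, params, "BASE", D)
      drone_w[dpq_ids, ] <- om$drone_w; drone_q[dpq_ids, ] <- om$drone_q
      Q$mate_subpop[dpq_ids] <- "BASE"
    }
    Q$mate_style[dpq_ids] <- "OPEN"

    ## --- worker groups, mortality, phenotypes ------------------------------
    cohort <- c(bq_ids, dpq_ids)
    wg <- make_worker_group(cbind(Q$bw[cohort], Q$bq[cohort]),
                            drone_w[cohort, , drop = FALSE],
                            drone_q[cohort, , drop = FALSE])
    Q$worker_w[cohort] <- wg[, 1L]; Q$worker_q[cohort] <- wg[, 2L]
    surv <- logical(length(cohort))
    names(surv) <- cohort
    for (f in seq_len(nf)) {
      bf <- bq_ids[Q$family[bq_ids] == f]
      df <- dpq_ids[Q$family[dpq_ids] == f]
      surv[as.character(sample(bf, scheme$n_bq_surv))] <- TRUE
      surv[as.character(sample(df, scheme$n_dpq_surv))] <- TRUE
    }
    alive <- cohort[surv[as.character(cohort)]]
    Q$survived[alive] <- TRUE
    Q$phenotype[alive] <- year_effects[t + 1L] + Q$worker_w[alive] +
      Q$bq[alive] + rnorm(length(alive), 0, sqrt(params$var_e))

    ## --- select replacement dams (one per family, own phenotype) ----------
    if (t < ny) {
      new_dams <- integer(nf)
      for (f in seq_len(nf)) {
        cand <- bq_ids[Q$family[bq_ids] == f & Q$survived[bq_ids]]
        crit <- if (random_selection) runif(length(cand))
                else Q$phenotype[cand]
        new_dams[f] <- cand[order(-crit, runif(length(cand)))][1L]
      }
      dams <- new_dams
      Q$selected_dam[dams] <- TRUE
      track(dams)
    }

    ## --- select DPQ dams; groups usable two years later --------------------
    if (t + 2L <= ny) {
      fam_mean <- vapply(seq_len(nf), function(f) {
        ph <- Q$phenotype[dpq_ids[Q$family[dpq_ids] == f & Q$survived[dpq_ids]]]
        mean(ph)
      }, 0)
      crit <- if (random_selection) runif(nf) else fam_mean
      sel_fams <- order(-crit, runif(nf))[seq_len(scheme$n_dpq_dams)]
      year_gids <- integer(0)
      for (f in sel_fams) {
        cand <- dpq_ids[Q$family[dpq_ids] == f & Q$survived[dpq_ids]]
        mem <- sample(cand, scheme$n_dpq_group)
        gid <- gid + 1L
        groups[[gid]] <- list(id = gid, members = mem,
                              dam = Q$dam[mem[1L]], year_used = t + 2L)
        year_gids <- c(year_gids, gid)
        track(mem)
      }
      group_of_year[[t + 2L]] <- year_gids
    }
  }

  queens <- data.frame(id = seq_len(ntot), dam = Q$dam, father = Q$father,
                       year = Q$year, family = Q$family, role = Q$role,
                       bw = Q$bw, bq = Q$bq, F = Q$F,
                       survived = Q$survived, phenotype = Q$phenotype,
                       mate_style = Q$mate_style, mate_group = Q$mate_group,
                       mate_subpop = Q$mate_subpop,
                       worker_w = Q$worker_w, worker_q = Q$worker_q,
                       selected_dam = Q$selected_dam)
  structure(list(queens = queens, drone_mothers = drone_mothers,
                 groups = groups, year_effects = year_effects,
                 params = params, scheme = scheme, seed = seed),
            class = "bee_sim")
}

#' @export
print.bee_sim <- function(x, ...) {
  q <- x$queens
  cat("Simulated breeding program:", nrow(q), "queens,",
      sum(!is.na(q$phenotype)), "phenotyped colonies, years 0-",
      x$scheme$n_years, "\n", sep = " ")
  invisible(x)
}
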