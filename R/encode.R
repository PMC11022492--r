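#' Build the estimation pedigree and performance file for a scenario
#'
#' Re-encodes the true matings of a simulated replicate under the
#' scenario's (possibly deliberately wrong) sire model, producing the
#' pedigree of queens, mate entries and worker groups used for genetic
#' evaluation, together with the performance records.
#'
#' Dam links are never altered; only the sire side is re-encoded:
#' \itemize{
#'   \item `C_SSP`: an identified DPQ per mating — the true one under SS
#'     simulation, a random member of the sister group under PS simulation.
#'   \item `C_dummySSP_per_DPQdam`: one dummy DPQ (an unobserved daughter of
#'     the true DPQ dam) shared by all matings that used the dam's group.
#'   \item `C_dummySSP_per_Q`: a fresh dummy DPQ per mating.
#'   \item `C_PSP`: one pseudo-sire group (`S = 3` sister DPQs) shared by
#'     all matings of the group.
#' }
#' Open matings are modeled by open pseudo-sire groups of
#' `open_group_size` unknown unrelated DPQs: a single shared group, or
#' under `O_TwoPSP` one per drone subpopulation in addition to the base
#' group. Under `O_NoPheno` the DPQ colony records are excluded from the
#' performance data. Under `O_FixedGroup` / `O_RandGroup` records carry a
#' three-level drone-origin label (base / subpopulation A / B); controlled
#' colonies are the reference level with no loading.
#'
#' @param sim A [run_replicate()] result.
#' @param scenario A [scenario_spec()].
#' @return A list with `ped` (a validated `bee_pedigree`), `perf`
#'   (performance records; column `open_group_label` holds the
#'   drone-origin level), `queen_map` (simulation queen id to pedigree id),
#'   and `scenario`.
#' @export
encode_scenario <- function(sim, scenario) {
  q <- sim$queens
  scheme <- sim$scheme
  D <- scheme$n_drones
  ny <- scheme$n_years
  two_psp <- scenario$estim_open == "O_TwoPSP"
  rows <- list()
  nid <- 0L
  new_ids <- function(k) { ids <- nid + seq_len(k); nid <<- nid + k; ids }

  ## open-mating pseudo-sire groups
  open_base <- new_ids(1L)
  rows[[length(rows) + 1L]] <- ped_row(open_base, "MATE", style = "OPEN_GROUP",
                                       S = scenario$open_group_size, D = D)
  open_sub <- c(A = open_base, B = open_base)
  if (two_psp) {
    ids <- new_ids(2L)
    rows[[length(rows) + 1L]] <- ped_row(ids, "MATE", style = "OPEN_GROUP",
                                         S = scenario$open_group_size, D = D)
    open_sub <- c(A = ids[1L], B = ids[2L])
  }

  qmap <- integer(nrow(q))          # sim queen id -> pedigree id
  mate_of <- integer(nrow(q))       # sim queen id -> her mate entry id
  group_entry <- integer(length(sim$groups))  # shared entry per DPQ group

  ## founders
  fid <- which(q$year == 0L)
  qids <- new_ids(length(fid))
  qmap[fid] <- qids
  rows[[length(rows) + 1L]] <- ped_row(qids, "QUEEN", birth_year = 0L)
  mate_of[fid] <- open_base
  wg <- new_ids(length(fid))
  rows[[length(rows) + 1L]] <- ped_row(wg, "WORKER_GROUP", dam = qids,
                                       sire_entry = open_base, S = 0L, D = D,
                                       birth_year = 0L)
  perf <- list(data.frame(colony_id = fid, queen_id = qids,
                          worker_group_id = wg, mate_entry_id = open_base,
                          year = 0L, open_group_label = "BASE_OPEN",
                          role = "FOUNDER",
                          phenotype = q$phenotype[fid]))

  for (t in seq_len(ny)) {
    coh <- which(q$year == t)
    qids <- new_ids(length(coh))
    qmap[coh] <- qids
    rows[[length(rows) + 1L]] <-
      ped_row(qids, "QUEEN", dam = qmap[q$dam[coh]],
              sire_entry = mate_of[q$dam[coh]], birth_year = t)

    ## mate entries for this cohort's matings; queens whose colony died
    ## unphenotyped head no worker group and leave no offspring, so their
    ## matings never enter the evaluation pedigree
    mated <- coh[!is.na(q$phenotype[coh])]
    ctrl <- mated[q$mate_subpop[mated] == "CTRL"]
    open_rows <- setdiff(mated, ctrl)
    if (length(open_rows)) {
      lab <- q$mate_subpop[open_rows]
      mate_of[open_rows] <- ifelse(lab == "BASE", open_base, open_sub[lab])
    }
    if (length(ctrl)) {
      g_of <- q$mate_group[ctrl]
      mode <- scenario$estim_controlled
      if (mode == "C_SSP") {
        member <- integer(length(ctrl))
        ss <- sim$queens$mate_style[ctrl] == "SS"
        member[ss] <- sim$drone_mothers[ctrl[ss], 1L]
        if (any(!ss)) {
          member[!ss] <- vapply(g_of[!ss], function(g)
            sample(sim$groups[[g]]$members, 1L), 0L)
        }
        ids <- new_ids(length(ctrl))
        gd <- vapply(sim$groups[g_of], function(gr) gr$dam, 0L)
        rows[[length(rows) + 1L]] <-
          ped_row(ids, "MATE", style = "IDENTIFIED_DPQ",
                  member = qmap[member], dpq_dam = qmap[gd],
                  dpq_dam_mate = mate_of[gd], S = 1L, D = D, birth_year = t)
        mate_of[ctrl] <- ids
      } else if (mode == "C_dummySSP_per_Q") {
        ids <- new_ids(length(ctrl))
        gd <- vapply(sim$groups[g_of], function(gr) gr$dam, 0L)
        rows[[length(rows) + 1L]] <-
          ped_row(ids, "MATE", style = "DUMMY_DPQ", dpq_dam = qmap[gd],
                  dpq_dam_mate = mate_of[gd], S = 1L, D = D, birth_year = t)
        mate_of[ctrl] <- ids
      } else {                       # shared entry per DPQ group
        style <- if (mode == "C_PSP") "PS_GROUP" else "DUMMY_DPQ"
        S <- if (mode == "C_PSP") scheme$n_dpq_group else 1L
        for (g in unique(g_of)) {
          if (group_entry[g] == 0L) {
            gd <- sim$groups[[g]]$dam
            id <- new_ids(1L)
            rows[[length(rows) + 1L]] <-
              ped_row(id, "MATE", style = style, dpq_dam = qmap[gd],
                      dpq_dam_mate = mate_of[gd], S = S, D = D,
                      birth_year = t)
            group_entry[g] <- id
          }
        }
        mate_of[ctrl] <- group_entry[g_of]
      }
    }

    ## worker groups + records for phenotyped colonies
    ph <- coh[!is.na(q$phenotype[coh])]
    wg <- new_ids(length(ph))
    rows[[length(rows) + 1L]] <-
      ped_row(wg, "WORKER_GROUP", dam = qmap[ph], sire_entry = mate_of[ph],
              S = 0L, D = D, birth_year = t)
    lab <- ifelse(q$mate_subpop[ph] == "CTRL", "CONTROLLED",
                  ifelse(q$mate_subpop[ph] == "A", "SUBPOP_A",
                         ifelse(q$mate_subpop[ph] == "B", "SUBPOP_B",
                                "BASE_OPEN")))
    perf[[length(perf) + 1L]] <-
      data.frame(colony_id = ph, queen_id = qmap[ph], worker_group_id = wg,
                 mate_entry_id = mate_of[ph], year = t,
                 open_group_label = lab, role = q$role[ph],
                 phenotype = q$phenotype[ph])
  }

  ped <- do.call(rbind, rows)
  ped <- validate_pedigree(ped)
  perf <- do.call(rbind, perf)
  if (scenario$estim_open == "O_NoPheno")
    perf <- perf[perf$role != "DPQ", , drop = FALSE]
  rownames(perf) <- NULL
  list(ped = ped, perf = perf, queen_map = qmap, scenario = scenario)
}
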