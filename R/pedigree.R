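#' @importFrom utils read.delim write.table head tail
#' @importFrom stats rnorm runif var coef lm lm.fit sd setNames aggregate optim
NULL

PED_COLS <- c("id", "kind", "dam", "sire_entry", "style", "member",
              "dpq_dam", "dpq_dam_mate", "S", "D", "birth_year")

KINDS <- c("QUEEN", "MATE", "WORKER_GROUP")
STYLES <- c("IDENTIFIED_DPQ", "DUMMY_DPQ", "PS_GROUP", "OPEN_GROUP")

#' Pedigree of queens, mate entries and worker groups
#'
#' A pedigree is a data frame with one row per entity and columns
#' `id, kind, dam, sire_entry, style, member, dpq_dam, dpq_dam_mate, S, D,
#' birth_year`. Unknown references are encoded `0`. Three kinds of entity
#' exist:
#' \describe{
#'   \item{QUEEN}{`dam` is the dam queen (or 0), `sire_entry` the dam's mate
#'     entry (or 0).}
#'   \item{MATE}{a mate entry: `style` is one of `IDENTIFIED_DPQ` (wraps an
#'     existing queen, `member`), `DUMMY_DPQ` (an unobserved daughter of
#'     `dpq_dam` mated to `dpq_dam_mate`), `PS_GROUP` (`S >= 2` unidentified
#'     sister DPQs, daughters of `dpq_dam` x `dpq_dam_mate`), or
#'     `OPEN_GROUP` (`S` unknown unrelated non-inbred DPQs). `D` is the
#'     number of drones the entry contributes to each mating.}
#'   \item{WORKER_GROUP}{the workers of one colony: `dam` is the colony
#'     queen, `sire_entry` the mate entry that sired the workers.}
#' }
#' `validate_pedigree()` checks referential integrity, kind/style
#' consistency, and that every parent precedes its children (ids are
#' assigned in creation order, so the row order is the canonical
#' topological order).
#'
#' @param ped A data frame with the columns above.
#' @return `ped`, invisibly, with class `bee_pedigree`.
#' @export
validate_pedigree <- function(ped) {
  if (!all(PED_COLS %in% names(ped)))
    stop("pedigree must have columns: ", paste(PED_COLS, collapse = ", "))
  ped <- as.data.frame(ped)[, PED_COLS]
  n <- nrow(ped)
  if (anyDuplicated(ped$id))
    stop("duplicate id in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)])[1], collapse = ", "))
  if (any(ped$id <= 0)) stop("ids must be positive integers")
  if (!all(ped$kind %in% KINDS)) stop("unknown entity kind")
  look <- function(ref) {
    idx <- match(ref, ped$id)
    idx[ref == 0L] <- 0L
    idx
  }
  for (col in c("dam", "sire_entry", "member", "dpq_dam", "dpq_dam_mate")) {
    ref <- ped[[col]]
    idx <- look(ref)
    bad <- is.na(idx)
    if (any(bad))
      stop("dangling ", col, " reference in row id ",
           ped$id[which(bad)[1]], " -> ", ref[which(bad)[1]])
    prec <- idx >= seq_len(n) & ref != 0L
    if (any(prec))
      stop("parent does not precede child (possible cycle): row id ",
           ped$id[which(prec)[1]], " references ", ref[which(prec)[1]])
  }
  isq <- ped$kind == "QUEEN"; ism <- ped$kind == "MATE"; isw <- ped$kind == "WORKER_GROUP"
  if (any(ism & !ped$style %in% STYLES)) stop("MATE entry with unknown style")
  if (any(isw & (ped$dam == 0L | ped$sire_entry == 0L)))
    stop("WORKER_GROUP must reference a queen and a mate entry")
  kind_of <- function(ref) {
    idx <- look(ref)
    out <- rep(NA_character_, length(ref))
    ok <- !is.na(idx) & idx > 0L
    out[ok] <- ped$kind[idx[ok]]
    out
  }
  if (any(isq & ped$dam != 0L & kind_of(ped$dam) != "QUEEN"))
    stop("a QUEEN's dam must be a QUEEN")
  if (any(isq & ped$sire_entry != 0L & kind_of(ped$sire_entry) != "MATE"))
    stop("a QUEEN's sire_entry must be a MATE entry")
  if (any(isw & (kind_of(ped$dam) != "QUEEN" | kind_of(ped$sire_entry) != "MATE")))
    stop("a WORKER_GROUP must reference one QUEEN and one MATE")
  if (any(ism & ped$style == "IDENTIFIED_DPQ" &
          (ped$member == 0L | ped$S != 1L)))
    stop("IDENTIFIED_DPQ entries need a member queen and S = 1")
  if (any(ism & ped$style == "DUMMY_DPQ" & ped$S != 1L))
    stop("DUMMY_DPQ entries have S = 1")
  if (any(ism & ped$style == "PS_GROUP" & ped$S < 2L))
    stop("PS_GROUP entries have S >= 2")
  if (any(ism & ped$style == "OPEN_GROUP" &
          (ped$dpq_dam != 0L | ped$dpq_dam_mate != 0L)))
    stop("OPEN_GROUP entries have no known parents")
  if (any(ism & ped$D < 1L)) stop("mate entries need D >= 1 drones")
  class(ped) <- c("bee_pedigree", "data.frame")
  invisible(ped)
}

#' Construct pedigree rows
#'
#' Convenience constructor for one or more pedigree entities (vectorised
#' over `id`); see [validate_pedigree()] for the column semantics.
#'
#' @param id Entity id(s).
#' @param kind `"QUEEN"`, `"MATE"` or `"WORKER_GROUP"`.
#' @param dam,sire_entry,style,member,dpq_dam,dpq_dam_mate,S,D,birth_year
#'   Column values (defaults encode "unknown").
#' @return A data frame of pedigree rows.
#' @export
ped_row <- function(id, kind, dam = 0L, sire_entry = 0L, style = "",
                    member = 0L, dpq_dam = 0L, dpq_dam_mate = 0L,
                    S = 0L, D = 0L, birth_year = 0L) {
  data.frame(id = id, kind = kind, dam = dam, sire_entry = sire_entry,
             style = style, member = member, dpq_dam = dpq_dam,
             dpq_dam_mate = dpq_dam_mate, S = S, D = D,
             birth_year = birth_year)
}

#' Read / write the pedigree and performance TSV dialects
#'
#' Tab-separated files with a header and the canonical column order; unknown
#' references are encoded `0`. `read_pedigree()` validates referential
#' integrity and topological (parent-before-child) order and fails with the
#' offending row named. Writing then re-reading is the identity.
#'
#' @param path File path.
#' @return `read_pedigree()`: a validated `bee_pedigree` data frame.
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in setdiff(PED_COLS, c("kind", "style")))
    ped[[col]] <- as.integer(ped[[col]])
  ped <- validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped A `bee_pedigree` data frame (topologically ordered).
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  write.table(as.data.frame(ped)[, PED_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

PERF_COLS <- c("colony_id", "queen_id", "worker_group_id", "mate_entry_id",
               "year", "open_group_label", "phenotype")

OPEN_LABELS <- c("CONTROLLED", "BASE_OPEN", "SUBPOP_A", "SUBPOP_B")

#' @rdname read_pedigree
#' @export
read_performance <- function(path) {
  perf <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(PERF_COLS %in% names(perf)))
    stop("performance file must have columns: ",
         paste(PERF_COLS, collapse = ", "))
  perf[, PERF_COLS]
}

#' @rdname read_pedigree
#' @param records A performance data frame (one row per phenotyped colony)
#'   with columns `colony_id, queen_id, worker_group_id, mate_entry_id,
#'   year, open_group_label, phenotype`.
#' @export
write_performance <- function(records, path) {
  if (!all(PERF_COLS %in% names(records)))
    stop("performance records must have columns: ",
         paste(PERF_COLS, collapse = ", "))
  write.table(records[, PERF_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a sparse matrix in MatrixMarket coordinate format
#'
#' Symmetric matrices are stored as the lower triangle with the `symmetric`
#' MatrixMarket qualifier (1-based coordinates).
#'
#' @param m A matrix or `Matrix` sparse matrix.
#' @param path Output `.mtx` path.
#' @param symmetric If `TRUE`, `m` must be symmetric (to 1e-10) and is
#'   written in symmetric lower-triangular storage.
#' @export
export_sparse <- function(m, path, symmetric = TRUE) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  if (symmetric) {
    if (!Matrix::isSymmetric(m, tol = 1e-10))
      stop("matrix is not symmetric but symmetric export was requested")
    m <- Matrix::forceSymmetric(Matrix::tril(m), uplo = "L")
  }
  Matrix::writeMM(m, path)
  invisible(path)
}

#' @rdname export_sparse
#' @export
read_sparse <- function(path) {
  m <- Matrix::readMM(path)
  ## binary matrices are stored as MatrixMarket "pattern"; return numeric
  methods::as(1 * m, "CsparseMatrix")
}
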