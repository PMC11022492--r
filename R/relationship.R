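#' Probability that two offspring of one mating share a father
#'
#' With `D` drones drawn (with replacement) from `S` sister DPQs, two
#' offspring of the mating have the same father drone with probability
#' `p_dr = 1/D`, and the same father DPQ with probability
#' `p_dpq = 1/D + (1 - 1/D)/S` (exact under uniform allocation; the
#' literature often quotes the approximation `1/D + 1/S`, which exceeds 1
#' when `S = 1`).
#'
#' @param S Number of sister DPQs contributing drones (>= 1).
#' @param D Number of drones per mating (>= 1).
#' @return A list with `p_dr` and `p_dpq`, both in (0, 1].
#' @examples
#' shared_father_probs(1, 8)$p_dpq   # 1: single sire
#' shared_father_probs(3, 8)$p_dpq   # 1/8 + (7/8)/3
#' @export
shared_father_probs <- function(S, D) {
  if (any(S < 1) || any(D < 1)) stop("S and D must be >= 1")
  p_dr <- 1 / D
  list(p_dr = p_dr, p_dpq = p_dr + (1 - p_dr) / S)
}

## internal type codes for relationship entities
TYP_QUEEN <- 1L; TYP_OPEN <- 2L; TYP_PS <- 3L; TYP_WORKER <- 4L; TYP_LATENT <- 5L

#' Relationship factor of a honeybee pedigree
#'
#' Computes, in one pass over a topologically ordered pedigree, the
#' generalized Cholesky factorization `A = T D T'` of the additive
#' relationship matrix over queens, (pseudo-)sire entries and worker
#' groups: for every entity the regression coefficients `b` on its (at
#' most two) parent entities and the residual variance `d`, plus
#' inbreeding coefficients of queens. The sparse inverse of `A` follows
#' directly from the factor ([invert_factor()]).
#'
#' Entity rules (`a_ii` denotes the self-relationship):
#' \itemize{
#'   \item founder queen: `a = 1`, `d = 1`;
#'   \item open pseudo-sire group of `S` unknown unrelated DPQs: the entity
#'     is the group mean, so `a = 1/S`, `d = 1/S`;
#'   \item queen (or dummy DPQ) with dam `Dm` and sire node `M`:
#'     `b = (1/2, 1/2)`, `F = a(Dm, M)/2`, `a = 1 + F`,
#'     `d = a - (a(Dm,Dm) + 2 a(Dm,M) + a(M,M))/4`;
#'   \item pseudo-sire group of `S` unidentified sister DPQs, daughters of
#'     `(Dm', M')`: member self-relationship `amm = 1 + a(Dm',M')/2`,
#'     member cross-relationship
#'     `amm' = (a(Dm',Dm') + 2 a(Dm',M') + a(M',M'))/4 + c2` with the
#'     same-mating correction `c2 = (1/D') (1/2 - a(M',M')/4)` (two sisters
#'     share their father drone with probability `1/D'`); the group mean
#'     then has `a = amm/S + (1-1/S) amm'` and `d = a - quad(parents)`;
#'   \item worker group of queen `Q` mated to `M` with `D` drones:
#'     `b = (1/2, 1/2)`, `d = (2 - a(M,M)) / (4D)` (drone-sampling
#'     variance of the worker-group mean).
#' }
#'
#' Three modes are provided, differing in how much of the within-mating
#' father sharing (two offspring of one mating share their father drone
#' with probability `1/D`) enters `A`:
#' \itemize{
#'   \item `"per_mating"` (default, the production path): one latent sire
#'     per mating (the mating's mean drone genome in diploid units, a
#'     child of the mate entry with `b = 1` and `d = (2 - a_MM)/D`)
#'     carries the sire side of queen offspring and of pseudo-sire group
#'     members, so same-mating *queen* covariances are exact — the
#'     father-sharing probabilities that single-sire matings make
#'     essential (`p_dpq = 1` at `S = 1`); worker groups stay attached to
#'     the shared mate entry with `d_W = (2 - a_MM)/(4D) > 0`, keeping
#'     `A` invertible.
#'   \item `"group_level"`: no latent sires; mate entries shared exactly
#'     as in the pedigree file, all within-mating sharing absorbed in the
#'     worker-group `d`. Sister queens of one single-sire mating then have
#'     `a = 0.5` instead of the exact `0.53125`.
#'   \item `"exact_per_mating"`: latent sires carry worker groups too, so
#'     *all* same-mating covariances are exact, but worker groups become
#'     deterministic (`d = 0`) and the factor is not invertible — a
#'     verification mode (it is what gene dropping reproduces).
#' }
#'
#' @param ped A validated [bee_pedigree][validate_pedigree] data frame.
#' @param mode `"group_level"` or `"exact_per_mating"`.
#' @return An object of class `bee_factor`: a list with `entity` (data
#'   frame: pedigree id or `NA` for latent sires, type, parents as factor
#'   row indices, `b1`, `b2`, `d`, `F`, `a_self`, `birth_year`), `index`
#'   (map from pedigree id to factor row; identified-DPQ mate entries map
#'   to their member queen), `mode`, and `logdet` (`sum(log d)`, the
#'   log-determinant of `A` in group-level mode).
#' @export
build_factor <- function(ped, mode = c("per_mating", "group_level",
                                       "exact_per_mating")) {
  mode <- match.arg(mode)
  exact <- mode != "group_level"            # latent per-mating sires
  workers_on_latent <- mode == "exact_per_mating"
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  rowof <- function(ids) { i <- match(ids, ped$id); i[ids == 0L] <- 0L; i }
  dam_r <- rowof(ped$dam); sire_r <- rowof(ped$sire_entry)
  member_r <- rowof(ped$member)
  gd_r <- rowof(ped$dpq_dam); gm_r <- rowof(ped$dpq_dam_mate)
  is_mate <- ped$kind == "MATE"
  is_ident <- is_mate & ped$style == "IDENTIFIED_DPQ"

  ## mate entry of each queen's own mating (discovered from references)
  mate_of <- integer(n)                       # ped row -> entry ped row
  ref_dam <- c(dam_r[ped$kind != "MATE"], gd_r[is_mate & !is_ident])
  ref_ent <- c(sire_r[ped$kind != "MATE"], gm_r[is_mate & !is_ident])
  ok <- ref_dam > 0L & ref_ent > 0L
  mate_of[ref_dam[ok]] <- ref_ent[ok]

  nmax <- n + if (exact) n else 0L
  typ <- integer(nmax); p1 <- integer(nmax); p2 <- integer(nmax)
  b1 <- numeric(nmax); b2 <- numeric(nmax); dd <- numeric(nmax)
  FF <- rep(NA_real_, nmax); aself <- rep(NA_real_, nmax)
  pid <- rep(NA_integer_, nmax); byear <- rep(NA_integer_, nmax)
  SS <- integer(nmax); DD <- integer(nmax)
  m <- 0L
  aidx <- integer(n)                          # ped row -> factor row
  latent <- integer(n)                        # queen ped row -> latent row

  ## --- decide the core set: entities whose pairwise relationships are kept
  ## densely (parents of queens and of group entries, closed over parents)
  node_of <- function(r) ifelse(r > 0L & is_ident[pmax(r, 1L)],
                                member_r[pmax(r, 1L)], r)
  core_q <- logical(n); core_l <- logical(n)
  push_q <- integer(0); push_l <- integer(0)
  add_pair <- function(dam, sire_entry_row) {
    if (dam > 0L) push_q <<- c(push_q, dam)
    if (sire_entry_row > 0L) {
      if (exact && dam > 0L) push_l <<- c(push_l, dam)
      else push_q <<- c(push_q, node_of(sire_entry_row))
    }
  }
  for (i in seq_len(n)) {
    if (ped$kind[i] == "QUEEN") {
      if (dam_r[i] > 0L || sire_r[i] > 0L) add_pair(dam_r[i], sire_r[i])
    } else if (is_mate[i] && !is_ident[i] &&
               ped$style[i] %in% c("DUMMY_DPQ", "PS_GROUP")) {
      add_pair(gd_r[i], gm_r[i])
    }
  }
  while (length(push_q) || length(push_l)) {
    qs <- unique(push_q); ls <- unique(push_l)
    qs <- qs[qs > 0L & !core_q[qs]]; ls <- ls[ls > 0L & !core_l[ls]]
    core_q[qs] <- TRUE; core_l[ls] <- TRUE
    push_q <- integer(0); push_l <- integer(0)
    for (i in qs) {
      if (ped$kind[i] == "QUEEN") {
        if (dam_r[i] > 0L || sire_r[i] > 0L) add_pair(dam_r[i], sire_r[i])
      } else if (is_mate[i] && ped$style[i] %in% c("DUMMY_DPQ", "PS_GROUP")) {
        add_pair(gd_r[i], gm_r[i])
      }
    }
    for (k in ls) {                 # latent's parent is its entry's node
      e <- mate_of[k]
      if (e > 0L) push_q <- c(push_q, node_of(e))
      push_q <- c(push_q, k)        # exact-mode F also reads a(dam, entry)
    }
  }
  ncore <- sum(core_q) + sum(core_l)
  K <- matrix(0, ncore, ncore)
  kq <- integer(n); kl <- integer(n)          # ped row / latent key -> K row
  kn <- 0L

  quad <- function(s1, s12, s2) (s1 + 2 * s12 + s2) / 4

  emit <- function(type, par1, par2, bb1, bb2, dval, f, a, ped_row, key_l,
                   year) {
    m <<- m + 1L
    typ[m] <<- type; p1[m] <<- par1; p2[m] <<- par2
    b1[m] <<- bb1; b2[m] <<- bb2; dd[m] <<- dval
    FF[m] <<- f; aself[m] <<- a; byear[m] <<- year
    if (!is.na(ped_row)) { pid[m] <<- ped$id[ped_row]; aidx[ped_row] <<- m }
    if (!is.na(key_l)) latent[key_l] <<- m
    ## maintain the dense core block
    in_core <- (!is.na(ped_row) && core_q[ped_row]) ||
      (!is.na(key_l) && core_l[key_l])
    if (in_core) {
      kn <<- kn + 1L
      if (!is.na(ped_row)) kq[ped_row] <<- kn else kl[key_l] <<- kn
      if (kn > 1L) {
        row <- numeric(kn - 1L)
        kp1 <- if (par1 > 0L) kcore_row(par1) else 0L
        kp2 <- if (par2 > 0L) kcore_row(par2) else 0L
        if (bb1 != 0 && kp1 > 0L) row <- row + bb1 * K[kp1, seq_len(kn - 1L)]
        if (bb2 != 0 && kp2 > 0L) row <- row + bb2 * K[kp2, seq_len(kn - 1L)]
        K[kn, seq_len(kn - 1L)] <<- row
        K[seq_len(kn - 1L), kn] <<- row
      }
      K[kn, kn] <<- a
    }
    m
  }
  kcore_row <- function(frow) {               # factor row -> K row (0 if out)
    pr <- pid_row[frow]
    if (!is.na(pr) && pr > 0L) return(kq[pr])
    lk <- lat_key[frow]
    if (!is.na(lk) && lk > 0L) return(kl[lk])
    0L
  }
  pid_row <- rep(NA_integer_, nmax)           # factor row -> ped row
  lat_key <- rep(NA_integer_, nmax)           # factor row -> latent key row
  k_of <- function(frow) if (frow > 0L) kcore_row(frow) else 0L
  apair <- function(f1, f2) {                 # a between two factor rows
    if (f1 == 0L || f2 == 0L) return(0)
    k1 <- k_of(f1); k2 <- k_of(f2)
    if (k1 == 0L || k2 == 0L)
      stop("internal: relationship requested outside the core set")
    K[k1, k2]
  }

  ensure_latent <- function(key_row) {        # key_row: mated queen ped row
    if (latent[key_row] > 0L) return(latent[key_row])
    e <- mate_of[key_row]
    if (e == 0L) stop("internal: latent sire requested for unmated queen id ",
                      ped$id[key_row])
    en <- aidx[node_of(e)]
    a_e <- aself[en]
    De <- ped$D[e]
    d_l <- (2 - a_e) / De
    fr <- emit(TYP_LATENT, en, 0L, 1, 0, d_l, NA_real_, a_e + d_l,
               NA_integer_, key_row, ped$birth_year[e])
    pid_row[fr] <<- NA_integer_; lat_key[fr] <<- key_row
    fr
  }

  for (i in seq_len(n)) {
    if (is_ident[i]) { aidx[i] <- aidx[member_r[i]]; next }
    kind <- ped$kind[i]
    if (kind == "MATE" && ped$style[i] == "OPEN_GROUP") {
      fr <- emit(TYP_OPEN, 0L, 0L, 0, 0, 1 / ped$S[i], NA_real_,
                 1 / ped$S[i], i, NA_integer_, ped$birth_year[i])
      pid_row[fr] <- i
      SS[fr] <- ped$S[i]; DD[fr] <- ped$D[i]
      next
    }
    if (kind == "QUEEN" || (kind == "MATE" && ped$style[i] == "DUMMY_DPQ")) {
      if (kind == "QUEEN") { dr <- dam_r[i]; er <- sire_r[i] }
      else { dr <- gd_r[i]; er <- gm_r[i] }
      if (dr == 0L && er == 0L) {
        fr <- emit(TYP_QUEEN, 0L, 0L, 0, 0, 1, 0, 1, i, NA_integer_,
                   ped$birth_year[i])
        pid_row[fr] <- i
      } else {
        siref <- if (er == 0L) 0L else if (exact && dr > 0L)
          ensure_latent(dr) else aidx[node_of(er)]
        damf <- if (dr > 0L) aidx[dr] else 0L
        a12 <- if (damf > 0L && siref > 0L) apair(damf, siref) else 0
        f <- a12 / 2
        s1 <- if (damf > 0L) aself[damf] else 0
        s2 <- if (siref > 0L) aself[siref] else 0
        bb1 <- if (damf > 0L) 0.5 else 0
        bb2 <- if (siref > 0L) 0.5 else 0
        qd <- bb1^2 * s1 + 2 * bb1 * bb2 * a12 + bb2^2 * s2
        fr <- emit(TYP_QUEEN, damf, siref, bb1, bb2, (1 + f) - qd, f, 1 + f,
                   i, NA_integer_, ped$birth_year[i])
        pid_row[fr] <- i
      }
      if (kind == "MATE") { SS[aidx[i]] <- ped$S[i]; DD[aidx[i]] <- ped$D[i] }
      next
    }
    if (kind == "MATE" && ped$style[i] == "PS_GROUP") {
      dr <- gd_r[i]; er <- gm_r[i]
      if (dr == 0L || er == 0L)
        stop("PS_GROUP entry id ", ped$id[i], " needs known parents")
      siref <- if (exact) ensure_latent(dr) else aidx[node_of(er)]
      damf <- aidx[dr]
      a12 <- apair(damf, siref)
      s1 <- aself[damf]; s2 <- aself[siref]
      amm <- 1 + a12 / 2
      amm2 <- quad(s1, a12, s2)
      if (!exact) {                 # same-mating father sharing correction
        Dp <- ped$D[er]
        amm2 <- amm2 + (1 / Dp) * (0.5 - s2 / 4)
      }
      S <- ped$S[i]
      app <- amm / S + (1 - 1 / S) * amm2
      d_p <- app - quad(s1, a12, s2)
      fr <- emit(TYP_PS, damf, siref, 0.5, 0.5, d_p, NA_real_, app, i,
                 NA_integer_, ped$birth_year[i])
      pid_row[fr] <- i
      SS[fr] <- S; DD[fr] <- ped$D[i]
      next
    }
    ## worker group
    qr <- dam_r[i]; er <- sire_r[i]
    en <- aidx[node_of(er)]
    a_mm <- aself[en]
    De <- ped$D[er]
    if (workers_on_latent) {
      lf <- ensure_latent(qr)
      fr <- emit(TYP_WORKER, aidx[qr], lf, 0.5, 0.5, 0, NA_real_, NA_real_,
                 i, NA_integer_, ped$birth_year[i])
    } else {
      d_w <- (2 - a_mm) / (4 * De)
      fr <- emit(TYP_WORKER, aidx[qr], en, 0.5, 0.5, d_w, NA_real_, NA_real_,
                 i, NA_integer_, ped$birth_year[i])
    }
    pid_row[fr] <- i
  }

  ent <- data.frame(ped_id = pid[seq_len(m)], type = typ[seq_len(m)],
                    p1 = p1[seq_len(m)], p2 = p2[seq_len(m)],
                    b1 = b1[seq_len(m)], b2 = b2[seq_len(m)],
                    d = dd[seq_len(m)], F = FF[seq_len(m)],
                    a_self = aself[seq_len(m)],
                    birth_year = byear[seq_len(m)],
                    S = SS[seq_len(m)], D = DD[seq_len(m)])
  if (any(ent$d < 0))
    stop("negative residual variance d for entity ped id ",
         ent$ped_id[which(ent$d < 0)[1]],
         " (d = ", signif(min(ent$d), 4), ")")
  index <- aidx
  names(index) <- ped$id
  structure(list(entity = ent, index = index, ped_id = ped$id,
                 kind = ped$kind, mode = mode,
                 logdet = sum(log(ent$d[ent$d > 0])),
                 n = m), class = "bee_factor")
}

#' @export
print.bee_factor <- function(x, ...) {
  cat("Relationship factor (", x$mode, "): ", x$n, " entities, ",
      sum(x$entity$type == TYP_WORKER), " worker groups, logdet(A) = ",
      signif(x$logdet, 6), "\n", sep = "")
  invisible(x)
}

#' Sparse inverse of the relationship matrix
#'
#' Assembles `A^{-1} = sum_i (1/d_i) (e_i - sum_p b_ip e_p)
#' (e_i - sum_p b_ip e_p)'` directly from the relationship factor — `A` is
#' never formed or numerically inverted. Each entity contributes at most 9
#' nonzeros.
#'
#' @param factor A [build_factor()] result with all `d > 0`.
#' @return A symmetric sparse matrix (`dsCMatrix`) of dimension
#'   `factor$n`.
#' @export
invert_factor <- function(factor) {
  e <- factor$entity
  if (any(e$d <= 0))
    stop("invert_factor needs d > 0 for every entity (mode '", factor$mode,
         "' has deterministic entities); use the per_mating or group_level ",
         "factor")
  w <- 1 / e$d
  i <- seq_len(nrow(e))
  ii <- list(i); jj <- list(i); xx <- list(w)
  add <- function(a, b, v) {
    ii[[length(ii) + 1L]] <<- a; jj[[length(jj) + 1L]] <<- b
    xx[[length(xx) + 1L]] <<- v
  }
  h1 <- e$p1 > 0L & e$b1 != 0
  h2 <- e$p2 > 0L & e$b2 != 0
  add(i[h1], e$p1[h1], -e$b1[h1] * w[h1])
  add(e$p1[h1], i[h1], -e$b1[h1] * w[h1])
  add(e$p1[h1], e$p1[h1], e$b1[h1]^2 * w[h1])
  add(i[h2], e$p2[h2], -e$b2[h2] * w[h2])
  add(e$p2[h2], i[h2], -e$b2[h2] * w[h2])
  add(e$p2[h2], e$p2[h2], e$b2[h2]^2 * w[h2])
  b <- h1 & h2
  add(e$p1[b], e$p2[b], e$b1[b] * e$b2[b] * w[b])
  add(e$p2[b], e$p1[b], e$b1[b] * e$b2[b] * w[b])
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(factor$n, factor$n))
  Matrix::forceSymmetric(M, uplo = "L")
}

#' Dense relationship matrix by tabular recursion
#'
#' Reconstructs the full `A` from the factor: cross-relationships by
#' `a(i, .) = b1 a(p1, .) + b2 a(p2, .)` and diagonals by
#' `a(i, i) = quad(parents) + d_i`. Intended for small pedigrees
#' (verification, gene-drop comparison); refuses more than `max_n`
#' entities.
#'
#' @param factor A [build_factor()] result.
#' @param max_n Size guard (default 2000).
#' @return A dense symmetric matrix with rows/columns in factor order.
#' @export
dense_relationship <- function(factor, max_n = 2000L) {
  e <- factor$entity
  n <- nrow(e)
  if (n > max_n) stop("pedigree too large to densify (", n, " entities)")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    q <- 0
    if (e$p1[i] > 0L && e$b1[i] != 0) {
      row <- row + e$b1[i] * A[e$p1[i], prev]
      q <- q + e$b1[i]^2 * A[e$p1[i], e$p1[i]]
    }
    if (e$p2[i] > 0L && e$b2[i] != 0) {
      row <- row + e$b2[i] * A[e$p2[i], prev]
      q <- q + e$b2[i]^2 * A[e$p2[i], e$p2[i]]
      if (e$p1[i] > 0L && e$b1[i] != 0)
        q <- q + 2 * e$b1[i] * e$b2[i] * A[e$p1[i], e$p2[i]]
    }
    A[i, prev] <- row
    A[prev, i] <- row
    A[i, i] <- q + e$d[i]
  }
  A
}

#' Multiply the relationship matrix onto a vector via its factor
#'
#' Computes `A v = T D T' v` with two sparse triangular sweeps; `A` is
#' never formed.
#'
#' @param factor A [build_factor()] result.
#' @param v Numeric vector or matrix with `factor$n` rows.
#' @return `A %*% v`.
#' @export
relationship_matvec <- function(factor, v) {
  tm <- factor_tri(factor)
  v <- as.matrix(v)
  u <- Matrix::solve(tm$IBt, v)               # T' v
  u <- u * factor$entity$d
  as.matrix(Matrix::solve(tm$IB, u))          # T (D T' v)
}

## (I - B) and its transpose as triangular sparse matrices, cached on the
## factor via an environment would complicate the object; rebuild cheaply.
factor_tri <- function(factor) {
  e <- factor$entity
  i <- seq_len(nrow(e))
  h1 <- e$p1 > 0L & e$b1 != 0
  h2 <- e$p2 > 0L & e$b2 != 0
  B <- Matrix::sparseMatrix(i = c(i[h1], i[h2]), j = c(e$p1[h1], e$p2[h2]),
                            x = c(e$b1[h1], e$b2[h2]),
                            dims = c(factor$n, factor$n))
  IB <- Matrix::Diagonal(factor$n) - B
  list(IB = methods::as(IB, "triangularMatrix"),
       IBt = methods::as(Matrix::t(IB), "triangularMatrix"))
}

#' Inbreeding coefficients from a relationship factor
#'
#' @param factor A [build_factor()] result.
#' @return A data frame with `ped_id` and `F` for all queen-like entities
#'   (queens and dummy DPQs).
#' @export
inbreeding <- function(factor) {
  e <- factor$entity
  sel <- e$type == TYP_QUEEN & !is.na(e$ped_id)
  data.frame(ped_id = e$ped_id[sel], F = e$F[sel])
}
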