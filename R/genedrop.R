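#' Gene-dropping verification of the relationship recursion
#'
#' Drops unique founder alleles through the pedigree, re-sampling the
#' drone allocation of every mating per locus (which DPQ mothered each
#' drone, which drone fathered each queen — matching the allocation model
#' the analytic recursion averages over), and estimates every pairwise
#' additive relationship among pedigree-backed entities as the mean
#' identity-by-descent sharing of their genomes (2 x kinship, the scale of
#' `A`). Group entities are the mean of their member genomes; worker
#' groups are half the queen genome plus the drone-column average. The
#' estimates are compared with the analytic `A` of
#' [build_factor()]/[dense_relationship()] (exact per-mating mode by
#' default, which the dropping reproduces including same-mating sharing).
#'
#' Standard errors are estimated by splitting loci into `n_blocks`
#' independent blocks.
#'
#' @param ped A small validated pedigree (dense comparison).
#' @param n_loci Number of independent loci to drop (>= 1e4 for the
#'   default tolerances).
#' @param seed Seed for the dropping.
#' @param mode Factor mode to compare against.
#' @param n_blocks Locus blocks for the SE estimate.
#' @return A list with matrices `analytic`, `empirical`, `se` (over
#'   compared entities, in factor order), `max_abs_dev`, and `max_z`
#'   (largest absolute deviation in SE units, pairs with `se > 0`).
#' @export
gene_drop_check <- function(ped, n_loci = 1e4, seed = NULL,
                            mode = "exact_per_mating", n_blocks = 20L) {
  if (!is.null(seed)) set.seed(seed)
  ped <- validate_pedigree(ped)
  fac <- build_factor(ped, mode)
  A <- dense_relationship(fac)
  n <- nrow(ped)
  nb <- as.integer(n_blocks)
  nl <- (as.integer(n_loci) %/% nb) * nb
  rowof <- function(ids) { i <- match(ids, ped$id); i[ids == 0L] <- 0L; i }
  dam_r <- rowof(ped$dam); sire_r <- rowof(ped$sire_entry)
  member_r <- rowof(ped$member); gd_r <- rowof(ped$dpq_dam)
  is_ident <- ped$kind == "MATE" & ped$style == "IDENTIFIED_DPQ"

  mate_of <- integer(n)
  src_d <- c(dam_r[ped$kind != "MATE"], gd_r[ped$kind == "MATE" & !is_ident])
  src_e <- c(sire_r[ped$kind != "MATE"],
             rowof(ped$dpq_dam_mate)[ped$kind == "MATE" & !is_ident])
  ok <- src_d > 0L & src_e > 0L
  mate_of[src_d[ok]] <- src_e[ok]

  gmat <- vector("list", n); gpat <- vector("list", n)
  vmat <- vector("list", n); vpat <- vector("list", n)  # virtual members
  drones <- vector("list", n)                            # per mated queen
  label <- 0L
  fresh <- function() { label <<- label + 1L; rep.int(label, nl) }
  gamete <- function(r) {
    u <- runif(nl) < 0.5
    out <- gpat[[r]]
    out[u] <- gmat[[r]][u]
    out
  }
  member_allele <- function(e) {           # one random member gamete/locus
    S <- ped$S[e]
    sidx <- sample.int(S, nl, replace = TRUE)
    u <- runif(nl) < 0.5
    out <- vpat[[e]][cbind(seq_len(nl), sidx)]
    mm <- vmat[[e]][cbind(seq_len(nl), sidx)]
    out[u] <- mm[u]
    out
  }
  get_drones <- function(k) {
    if (!is.null(drones[[k]])) return(drones[[k]])
    e <- mate_of[k]
    if (e == 0L) stop("internal: drones requested for unmated queen")
    D <- ped$D[e]
    cols <- matrix(0L, nl, D)
    for (j in seq_len(D)) {
      cols[, j] <- if (is_ident[e]) gamete(member_r[e])
        else if (ped$style[e] == "DUMMY_DPQ") gamete(e)
        else member_allele(e)
    }
    drones[[k]] <<- cols
    cols
  }
  paternal <- function(dam_row) {          # father-drone allele per locus
    cols <- get_drones(dam_row)
    j <- sample.int(ncol(cols), nl, replace = TRUE)
    cols[cbind(seq_len(nl), j)]
  }

  for (i in seq_len(n)) {
    kind <- ped$kind[i]
    if (kind == "QUEEN") {
      if (dam_r[i] == 0L) { gmat[[i]] <- fresh(); gpat[[i]] <- fresh() }
      else {
        gmat[[i]] <- gamete(dam_r[i])
        gpat[[i]] <- if (sire_r[i] > 0L) paternal(dam_r[i]) else fresh()
      }
    } else if (kind == "MATE" && !is_ident[i]) {
      if (ped$style[i] == "DUMMY_DPQ") {
        gmat[[i]] <- gamete(gd_r[i])
        gpat[[i]] <- paternal(gd_r[i])
      } else if (ped$style[i] == "PS_GROUP") {
        S <- ped$S[i]
        vmat[[i]] <- vapply(seq_len(S), function(s) gamete(gd_r[i]),
                            integer(nl))
        vpat[[i]] <- vapply(seq_len(S), function(s) paternal(gd_r[i]),
                            integer(nl))
      } else {                             # OPEN_GROUP
        S <- ped$S[i]
        vmat[[i]] <- vapply(seq_len(S), function(s) fresh(), integer(nl))
        vpat[[i]] <- vapply(seq_len(S), function(s) fresh(), integer(nl))
      }
    }
  }

  ## entity decomposition into primitives: genome columns with coefficients
  prim_cols <- list()                      # key -> matrix of allele columns
  pcol <- function(key, make) {
    if (is.null(prim_cols[[key]])) prim_cols[[key]] <<- make()
    key
  }
  decomp <- function(ped_row) {
    kind <- ped$kind[ped_row]
    if (kind == "QUEEN" ||
        (kind == "MATE" && ped$style[ped_row] == "DUMMY_DPQ")) {
      k <- pcol(paste0("g", ped_row), function()
        cbind(gmat[[ped_row]], gpat[[ped_row]]))
      return(data.frame(key = k, coef = 1))
    }
    if (kind == "MATE") {                  # PS or OPEN group: member mean
      S <- ped$S[ped_row]
      keys <- vapply(seq_len(S), function(s)
        pcol(paste0("v", ped_row, "_", s), function()
          cbind(vmat[[ped_row]][, s], vpat[[ped_row]][, s])), "")
      return(data.frame(key = keys, coef = 1 / S))
    }
    ## worker group: half queen + drone-column mean
    qr <- dam_r[ped_row]
    cols <- get_drones(qr)
    D <- ncol(cols)
    kq <- pcol(paste0("g", qr), function() cbind(gmat[[qr]], gpat[[qr]]))
    kd <- vapply(seq_len(D), function(j)
      pcol(paste0("d", qr, "_", j), function() cols[, j, drop = FALSE]), "")
    rbind(data.frame(key = kq, coef = 0.5),
          data.frame(key = kd, coef = 1 / D))
  }

  blk <- rep(seq_len(nb), each = nl %/% nb)
  dot_cache <- new.env(parent = emptyenv())
  pdot <- function(k1, k2) {
    key <- paste(sort(c(k1, k2)), collapse = "|")
    hit <- get0(key, envir = dot_cache)
    if (!is.null(hit)) return(hit)
    c1 <- prim_cols[[k1]]; c2 <- prim_cols[[k2]]
    cnt <- numeric(nl)
    for (a in seq_len(ncol(c1)))
      for (b in seq_len(ncol(c2)))
        cnt <- cnt + (c1[, a] == c2[, b])
    v <- as.numeric(rowsum(cnt, blk)) / (nl / nb)
    assign(key, v, envir = dot_cache)
    v
  }

  compare <- which(!is.na(fac$entity$ped_id))
  ped_rows <- match(fac$entity$ped_id[compare], ped$id)
  dec <- lapply(ped_rows, decomp)
  ne <- length(compare)
  emp <- matrix(0, ne, ne); sem <- matrix(0, ne, ne)
  for (i in seq_len(ne)) {
    for (j in i:ne) {
      di <- dec[[i]]; dj <- dec[[j]]
      acc <- numeric(nb)
      for (a in seq_len(nrow(di)))
        for (b in seq_len(nrow(dj)))
          acc <- acc + di$coef[a] * dj$coef[b] * pdot(di$key[a], dj$key[b])
      acc <- acc / 2
      emp[i, j] <- emp[j, i] <- mean(acc)
      sem[i, j] <- sem[j, i] <- sd(acc) / sqrt(nb)
    }
  }
  an <- A[compare, compare, drop = FALSE]
  dev <- abs(an - emp)
  z <- dev / pmax(sem, 1e-12)
  list(analytic = an, empirical = emp, se = sem,
       max_abs_dev = max(dev), max_z = max(z[sem > 1e-12]),
       entities = fac$entity$ped_id[compare])
}
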