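#' Design matrices for the colony mixed model
#'
#' Builds the incidence structure of
#' `y = X b + Z_w a_w + Z_q a_q (+ Z_g g) + e` from encoded performance
#' records: `X` holds fixed year effects (one column per year, cell-means
#' coding) plus, for the fixed drone-origin model, one column per open
#' drone-origin level (base / subpopulation A / B; controlled colonies are
#' the zero reference). `Z_w` maps each record to its worker-group entity
#' and `Z_q` to its queen entity in the relationship factor; the stacked
#' genetic effects have covariance `G0 (x) A`. Collinear fixed-effect
#' columns are dropped with a warning.
#'
#' @param perf Performance records from [encode_scenario()].
#' @param factor The [build_factor()] of the matching estimation pedigree.
#' @param group_effect `"none"`, `"fixed"` or `"random"`: how the
#'   drone-origin label enters the model.
#' @return A list with `y`, `X`, `Zw`, `Zq`, `Zg` (`NULL` unless random),
#'   `m` (number of genetic entities) and bookkeeping columns.
#' @export
build_model <- function(perf, factor, group_effect = c("none", "fixed",
                                                       "random")) {
  group_effect <- match.arg(group_effect)
  nrec <- nrow(perf)
  y <- perf$phenotype
  yrs <- sort(unique(perf$year))
  X <- 1 * outer(perf$year, yrs, "==")
  colnames(X) <- paste0("year", yrs)
  glev <- c("BASE_OPEN", "SUBPOP_A", "SUBPOP_B")
  G <- 1 * outer(perf$open_group_label, glev, "==")
  colnames(G) <- glev
  if (group_effect == "fixed") {
    keep <- colSums(G) > 0
    X <- cbind(X, G[, keep, drop = FALSE])
  }
  ## drop collinear columns (e.g. a year fully confounded with an origin level)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop), " collinear fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  m <- factor$n
  widx <- factor$index[as.character(perf$worker_group_id)]
  qidx <- factor$index[as.character(perf$queen_id)]
  if (anyNA(widx) || anyNA(qidx))
    stop("performance records reference entities missing from the pedigree")
  Zw <- Matrix::sparseMatrix(i = seq_len(nrec), j = widx, x = 1,
                             dims = c(nrec, m))
  Zq <- Matrix::sparseMatrix(i = seq_len(nrec), j = qidx, x = 1,
                             dims = c(nrec, m))
  Zg <- NULL
  if (group_effect == "random") {
    keep <- colSums(G) > 0
    Zg <- methods::as(Matrix::Matrix(G[, keep, drop = FALSE], sparse = TRUE),
                      "CsparseMatrix")
  }
  list(y = y, X = methods::as(Matrix::Matrix(X, sparse = TRUE),
                              "CsparseMatrix"),
       Zw = Zw, Zq = Zq, Zg = Zg, m = m, group_effect = group_effect)
}

#' Henderson mixed-model equations for the colony model
#'
#' Assembles the sparse symmetric coefficient matrix and right-hand side of
#' the BLUP equations at given variance components: the data part
#' `M' M / var_e` (with `M = [X, Z_w, Z_q, Z_g]`) plus
#' `G0^{-1} (x) A^{-1}` on the stacked genetic block and `I / var_g` on
#' the group block. Solving the system yields BLUE fixed effects and BLUP
#' breeding values.
#'
#' @param model A [build_model()] result.
#' @param Ainv Sparse inverse relationship matrix ([invert_factor()]).
#' @param G0 2x2 genetic covariance matrix (worker, queen).
#' @param var_e Residual variance.
#' @param var_g Variance of the random drone-origin effect (if present).
#' @return A list with `C` (coefficient matrix), `rhs`, and the block
#'   offsets (`p` fixed effects, `m` entities per trait, `qg` group
#'   levels).
#' @export
assemble_mme <- function(model, Ainv, G0, var_e, var_g = NULL) {
  if (var_e <= 0) stop("var_e must be positive")
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("G0 must be positive definite in the MME")
  M <- cbind(model$X, model$Zw, model$Zq,
             if (!is.null(model$Zg)) model$Zg)
  MtM <- Matrix::crossprod(M)
  rhs <- as.numeric(Matrix::crossprod(M, model$y)) / var_e
  p <- ncol(model$X); m <- model$m
  qg <- if (is.null(model$Zg)) 0L else ncol(model$Zg)
  G0i <- solve(G0)
  blocks <- list(Matrix::Matrix(0, p, p), kronecker(G0i, Ainv))
  if (qg > 0L) {
    if (is.null(var_g) || var_g <= 0) stop("var_g must be positive")
    blocks <- c(blocks, list(Matrix::Diagonal(qg) / var_g))
  }
  C <- MtM / var_e + Matrix::bdiag(blocks)
  list(C = Matrix::forceSymmetric(C), rhs = rhs, p = p, m = m, qg = qg)
}
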