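## Log-determinant of a CHOLMOD factor's original matrix. The `sqrt`
## argument of determinant() changed defaults across Matrix versions, so be
## explicit and defensive.
chol_logdet <- function(ch) {
  dt <- tryCatch(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE),
                 error = function(e) NULL)
  if (!is.null(dt)) return(2 * as.numeric(dt$modulus))
  2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE)$modulus)
}

#' AI-REML for the colony mixed model with correlated queen/worker effects
#'
#' Estimates `(var_w, cov_wq, var_q, var_e[, var_g])` by restricted maximum
#' likelihood. The restricted log-likelihood is evaluated exactly through
#' the sparse mixed-model equations
#' (`-2 logRL = log|C| + m log|G0| + 2 log|A| + n log(var_e) + y'Py` up to
#' a constant); updates use the average-information matrix (computed
#' exactly from working variates and MME solves) with gradients from
#' central finite differences of the exact likelihood. Iterations run on a
#' log-Cholesky parameterization of `(G0, var_e, var_g)`, which keeps `G0`
#' positive definite by construction and lets boundary optima
#' (`r_wq -> +/-1`) be approached smoothly; steps that fail to decrease
#' `-2 logRL` are halved. Convergence is declared when the
#' largest relative parameter change falls below `tol` (or the likelihood
#' improvement is below numerical resolution); after 200 iterations the
#' fit is flagged non-converged.
#'
#' Predicted standard errors of the (co)variance estimates come from the
#' inverse average-information matrix at the optimum. The estimated
#' genetic correlation is clamped to `[-1, 1]`.
#'
#' @param model A [build_model()] result.
#' @param factor The matching [build_factor()] in an invertible mode
#'   (`per_mating` or `group_level`).
#' @param start Starting values `(var_w, cov_wq, var_q, var_e)`.
#' @param start_vg Starting value of the random drone-origin variance
#'   (used only when the model has one).
#' @param maxit,tol Iteration cap and relative-change tolerance.
#' @param verbose Print the iteration log.
#' @return An object of class `bee_reml`: `estimates` (named vector),
#'   `G0`, `r_wq`, `se_pred`, `converged`, `n_iter`, `neg2logRL`,
#'   solutions (`fixed`, `ebv_w`, `ebv_q`, `group`), and the iteration log.
#' @export
reml_fit <- function(model, factor, start = c(5, 0, 5, 35), start_vg = 1,
                     maxit = 200L, tol = 1e-8, verbose = FALSE) {
  y <- model$y
  n <- length(y)
  if (var(y) == 0) stop("zero-variance response")
  has_g <- !is.null(model$Zg)
  npar <- 4L + has_g
  M <- cbind(model$X, model$Zw, model$Zq, if (has_g) model$Zg)
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(M))
  Mty <- as.numeric(Matrix::crossprod(M, y))
  yty <- sum(y^2)
  p <- ncol(model$X); m <- model$m
  qg <- if (has_g) ncol(model$Zg) else 0L
  Ainv <- invert_factor(factor)
  logdetA <- factor$logdet
  zp <- Matrix::Matrix(0, p, p)
  zg <- if (qg > 0L) Matrix::Matrix(0, qg, qg) else NULL
  bd <- function(mid) {
    blocks <- list(zp, mid)
    if (qg > 0L) blocks <- c(blocks, list(zg))
    Matrix::forceSymmetric(Matrix::bdiag(blocks))
  }
  B11 <- bd(kronecker(matrix(c(1, 0, 0, 0), 2L), Ainv))
  B12 <- bd(kronecker(matrix(c(0, 1, 1, 0), 2L), Ainv))
  B22 <- bd(kronecker(matrix(c(0, 0, 0, 1), 2L), Ainv))
  Bg <- if (qg > 0L) {
    blocks <- list(zp, Matrix::Matrix(0, 2L * m, 2L * m),
                   Matrix::Diagonal(qg))
    Matrix::forceSymmetric(Matrix::bdiag(blocks))
  } else NULL

  G0_of <- function(th) matrix(c(th[1], th[2], th[2], th[3]), 2L)
  in_space <- function(th) {
    ev <- eigen(G0_of(th), symmetric = TRUE, only.values = TRUE)$values
    min(ev) > 0 && th[4] > 0 && (npar == 4L || th[5] > 0)
  }

  ## log-Cholesky parameterization: G0 = L L' with L = [[e^t1, 0],
  ## [t2, e^t3]], var_e = e^t4, var_g = e^t5 — positive definite by
  ## construction, so the r_wq = +/-1 boundary is approached smoothly.
  LCAP <- log(1e8)
  t_clamp <- function(tt) {
    i <- c(1L, 3L, 4L, if (npar == 5L) 5L)
    tt[i] <- pmin(pmax(tt[i], -LCAP), LCAP)
    tt[2L] <- pmin(pmax(tt[2L], -1e4), 1e4)
    tt
  }
  t_of_theta <- function(th) {
    vw <- max(th[1], 1e-8)
    t1 <- log(vw) / 2
    t2 <- th[2] / sqrt(vw)
    resid <- max(th[3] - t2^2, 1e-8 * max(th[3], 1))
    t_clamp(c(t1, t2, log(resid) / 2, log(max(th[4], 1e-10)),
              if (npar == 5L) log(max(th[5], 1e-10))))
  }
  theta_of_t <- function(tt) {
    l11 <- exp(tt[1]); l22 <- exp(tt[3])
    c(l11^2, tt[2] * l11, tt[2]^2 + l22^2, exp(tt[4]),
      if (npar == 5L) exp(tt[5]))
  }
  jac_t <- function(tt) {            # d theta / d t
    l11 <- exp(tt[1]); l22 <- exp(tt[3])
    J <- matrix(0, npar, npar)
    J[1, 1] <- 2 * l11^2
    J[2, 1] <- tt[2] * l11; J[2, 2] <- l11
    J[3, 2] <- 2 * tt[2];   J[3, 3] <- 2 * l22^2
    J[4, 4] <- exp(tt[4])
    if (npar == 5L) J[5, 5] <- exp(tt[5])
    J
  }

  evaluate <- function(th, want_sol = FALSE) {
    if (!in_space(th)) return(list(val = Inf))
    G0 <- G0_of(th)
    G0i <- tryCatch(solve(G0), error = function(e) NULL)
    if (is.null(G0i)) return(list(val = Inf))
    C <- MtM / th[4] + G0i[1, 1] * B11 + G0i[1, 2] * B12 + G0i[2, 2] * B22
    if (qg > 0L) C <- C + Bg / th[5]
    ## an indefinite C (extreme probe values of theta) surfaces as a CHOLMOD
    ## warning plus a NaN log-determinant; it is rejected via val = Inf below
    ch <- tryCatch(suppressWarnings(
      Matrix::Cholesky(Matrix::forceSymmetric(C))),
      error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    rhs <- Mty / th[4]
    sol <- as.numeric(suppressWarnings(Matrix::solve(ch, rhs)))
    yPy <- yty / th[4] - sum(rhs * sol)
    ldG <- m * as.numeric(determinant(G0, logarithm = TRUE)$modulus) +
      2 * logdetA + if (qg > 0L) qg * log(th[5]) else 0
    val <- chol_logdet(ch) + n * log(th[4]) + ldG + yPy
    if (!is.finite(val)) return(list(val = Inf))
    out <- list(val = val)
    if (want_sol) { out$ch <- ch; out$sol <- sol }
    out
  }

  ai_matrix <- function(th, ch, sol) {
    ve <- th[4]
    ehat <- y - as.numeric(M %*% sol)
    Py <- ehat / ve
    uw <- as.numeric(Matrix::crossprod(model$Zw, Py))
    uq <- as.numeric(Matrix::crossprod(model$Zq, Py))
    Auw <- as.numeric(relationship_matvec(factor, uw))
    Auq <- as.numeric(relationship_matvec(factor, uq))
    Fm <- cbind(vw = as.numeric(model$Zw %*% Auw),
                cwq = as.numeric(model$Zw %*% Auq) +
                  as.numeric(model$Zq %*% Auw),
                vq = as.numeric(model$Zq %*% Auq),
                ve = Py)
    if (has_g)
      Fm <- cbind(Fm, vg = as.numeric(
        model$Zg %*% as.numeric(Matrix::crossprod(model$Zg, Py))))
    S <- Matrix::solve(ch, Matrix::crossprod(M, Fm) / ve)
    PF <- (Fm - as.matrix(M %*% S)) / ve
    AI <- crossprod(Fm, PF) / 2
    (AI + t(AI)) / 2
  }

  gradient_t <- function(tt, f0) {     # finite differences in t-space
    g <- numeric(npar)
    for (i in seq_len(npar)) {
      h <- 1e-5 * max(abs(tt[i]), 1)
      up <- tt; up[i] <- up[i] + h
      dn <- tt; dn[i] <- dn[i] - h
      fu <- evaluate(theta_of_t(up))$val
      fd <- evaluate(theta_of_t(dn))$val
      g[i] <- if (is.finite(fu) && is.finite(fd)) (fu - fd) / (2 * h)
      else if (is.finite(fu)) (fu - f0) / h
      else if (is.finite(fd)) (f0 - fd) / h
      else 0
    }
    g
  }

  st <- c(start[seq_len(4L)], if (has_g) start_vg)
  if (!in_space(st)) stop("start must be strictly inside the parameter space")
  tt <- t_of_theta(st)
  th <- theta_of_t(tt)
  cur <- evaluate(th, want_sol = TRUE)
  if (!is.finite(cur$val)) stop("restricted likelihood undefined at start")
  converged <- FALSE
  trace_log <- data.frame()
  it <- 0L
  stalled <- FALSE
  fallbacks <- 2L                # quasi-Newton rescue budget per fit
  while (it < maxit) {
    it <- it + 1L
    g <- gradient_t(tt, cur$val)
    AI <- ai_matrix(th, cur$ch, cur$sol)
    J <- jac_t(tt)
    It <- crossprod(J, AI %*% J)            # information in t coordinates
    ridge <- 1e-8 * max(diag(It), 1)
    step <- tryCatch(solve(It + diag(ridge, npar), -g / 2),
                     error = function(e) -g / (2 * pmax(diag(It), 1)))
    smax <- 2 / max(abs(step), 1e-12)       # cap huge early steps (t units)
    s <- min(1, smax)
    improved <- FALSE
    for (half in 1:30) {
      cand_t <- t_clamp(tt + s * step)
      cand <- theta_of_t(cand_t)
      ev <- evaluate(cand, want_sol = TRUE)
      if (is.finite(ev$val) && ev$val < cur$val - 1e-12) {
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    dval <- if (improved) cur$val - ev$val else 0
    if (improved) {
      rel <- max(abs(cand - th) / pmax(abs(th), 1))
      if (verbose)
        cat(sprintf("it %3d  -2logRL %.6f  step %.3g  rel %.3g\n",
                    it, ev$val, s, rel))
      trace_log <- rbind(trace_log,
                         data.frame(iter = it, neg2logRL = ev$val,
                                    step = s, rel_change = rel))
      tt <- cand_t
      th <- cand
      cur <- ev
      if (rel < tol) { converged <- TRUE; break }
      if (dval >= 1e-9) next
    }
    ## AI step exhausted (flat ridge or boundary): quasi-Newton fallback on
    ## the exact likelihood in t-space, then resume or stop
    if (stalled || fallbacks <= 0L) { converged <- TRUE; break }
    stalled <- TRUE
    fallbacks <- fallbacks - 1L
    ob <- tryCatch(
      optim(tt, function(z) evaluate(theta_of_t(t_clamp(z)))$val,
            method = "BFGS",
            control = list(maxit = 60L, reltol = 1e-14,
                           ndeps = rep(1e-5, npar))),
      error = function(e) NULL)
    if (!is.null(ob) && is.finite(ob$value) && ob$value < cur$val - 1e-9) {
      tt <- t_clamp(ob$par)
      th <- theta_of_t(tt)
      cur <- evaluate(th, want_sol = TRUE)
      if (verbose)
        cat(sprintf("it %3d  quasi-Newton fallback  -2logRL %.6f\n",
                    it, cur$val))
      stalled <- FALSE                       # improved: keep iterating
      next
    }
    converged <- TRUE
    break
  }

  AI <- ai_matrix(th, cur$ch, cur$sol)
  se <- sqrt(pmax(diag(tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, npar, npar))), 0))
  names(se) <- c("var_w", "cov_wq", "var_q", "var_e",
                 if (has_g) "var_g")
  est <- th
  names(est) <- names(se)
  sol <- cur$sol
  r_wq <- est[["cov_wq"]] / sqrt(max(est[["var_w"]] * est[["var_q"]], 1e-12))
  structure(list(estimates = est, G0 = G0_of(th),
                 r_wq = min(max(r_wq, -1), 1),
                 se_pred = se, converged = converged, n_iter = it,
                 neg2logRL = cur$val,
                 fixed = sol[seq_len(p)],
                 ebv_w = sol[p + seq_len(m)],
                 ebv_q = sol[p + m + seq_len(m)],
                 group = if (qg > 0L) sol[p + 2L * m + seq_len(qg)] else NULL,
                 trace = trace_log),
            class = "bee_reml")
}

#' @export
print.bee_reml <- function(x, ...) {
  cat("AI-REML fit (", if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  est <- rbind(estimate = x$estimates, pred_se = x$se_pred)
  print(round(est, 4))
  cat("r_wq =", round(x$r_wq, 4), "  -2logRL =", round(x$neg2logRL, 4), "\n")
  invisible(x)
}

#' Restricted likelihood of the residual-only reduction
#'
#' With the genetic covariance constrained to zero the model collapses to
#' `y = X b + e`, whose REML variance estimate is the ordinary
#' least-squares residual variance `RSS / (n - p)`.
#'
#' @param y Response vector.
#' @param X Fixed-effect incidence matrix.
#' @return The REML estimate of `var_e`.
#' @export
reml_residual_only <- function(y, X) {
  X <- as.matrix(X)
  fit <- lm.fit(X, y)
  sum(fit$residuals^2) / (length(y) - fit$rank)
}

#' Breeding-value table for queens
#'
#' Joins the BLUP solutions of a fit to the queen entities of the
#' pedigree, giving worker- and queen-trait estimated breeding values per
#' queen with her birth year. Dummy DPQs and group entities are excluded.
#'
#' @param fit A [reml_fit()] result.
#' @param factor The [build_factor()] used in the fit.
#' @param ped The estimation pedigree.
#' @return A data frame `ped_id, birth_year, ebv_w, ebv_q`.
#' @export
ebv_table <- function(fit, factor, ped) {
  e <- factor$entity
  qids <- ped$id[ped$kind == "QUEEN"]
  rows <- which(!is.na(e$ped_id) & e$ped_id %in% qids)
  data.frame(ped_id = e$ped_id[rows], birth_year = e$birth_year[rows],
             ebv_w = fit$ebv_w[rows], ebv_q = fit$ebv_q[rows])
}
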