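## Average-information REML engine on the mixed-model-equations form.
##
## Model: y = X b + sum_t Z_t u_t + e, u_t ~ N(0, S_t (x) K_t), e ~ N(0, R),
## where K_t is a known q_t x q_t covariance (NULL = identity), S_t is a
## scalar variance (nt = 1) or an unstructured 2x2 trait covariance (nt = 2),
## and R is sigma_e^2 I (nt = 1) or a 2x2-blocked residual over paired plot
## records (nt = 2).
##
## Everything is computed from the coefficient matrix
##   C = W' R^-1 W + blockdiag(0, S_1^-1 (x) K_1^-1, ...),  W = [X, Z_1, ...]
## using the identities  log|V| + log|X'V^-1 X| = log|C| + log|G| + log|R|
## and  tr(P Z_t B Z_t') = tr((G_t^-1 - G_t^-1 C^{tt} G_t^-1) B), where C^{tt}
## is the t-block of C^-1. AI updates use the quadratic forms
## AI_kl = v_k' P v_l / 2 with v_k = (dV/dtheta_k) P y. EM-REML steps replace
## an AI update that leaves the parameter space (univariate terms); bivariate
## covariance blocks are step-halved and PSD-projected instead.

## A term: list(label, Z (n x nt*q sparse), q, nt, K/Kinv (or NULL =
## identity), ldetK = log|K|)
.reml_term <- function(label, Z, q, nt = 1, K = NULL, Kinv = NULL, ldetK = 0) {
  list(label = label, Z = Z, q = q, nt = nt, K = K, Kinv = Kinv, ldetK = ldetK)
}

## number of parameters for a term / residual
.npar <- function(nt) if (nt == 1) 1L else 3L

## expand theta into per-structure parameter list
.split_theta <- function(theta, terms, nt_resid) {
  out <- list()
  pos <- 1L
  for (t in seq_along(terms)) {
    np <- .npar(terms[[t]]$nt)
    out[[t]] <- theta[pos:(pos + np - 1L)]
    pos <- pos + np
  }
  out$resid <- theta[pos:(pos + .npar(nt_resid) - 1L)]
  out
}

.cov2x2 <- function(p) matrix(c(p[1], p[2], p[2], p[3]), 2, 2)

## validity of a parameter vector
.theta_valid <- function(theta, terms, nt_resid, floor) {
  sp <- .split_theta(theta, terms, nt_resid)
  ok <- TRUE
  for (t in seq_along(terms)) {
    p <- sp[[t]]
    if (terms[[t]]$nt == 1) ok <- ok && p[1] >= floor
    else ok <- ok && p[1] >= floor && p[3] >= floor &&
        (p[1] * p[3] - p[2]^2) > 0
  }
  p <- sp$resid
  if (nt_resid == 1) ok <- ok && p[1] >= floor
  else ok <- ok && p[1] >= floor && p[3] >= floor &&
      (p[1] * p[3] - p[2]^2) > 0
  ok
}

## residual description for nt = 2: trait (1/2 per obs), pair (partner row or NA)
.resid_rinv <- function(rp, resid, n) {
  if (resid$nt == 1) return(list(scalar = 1 / rp[1], ldet = n * log(rp[1])))
  if (isFALSE(resid$est_cov)) rp[2] <- 0
  e1 <- rp[1]; e12 <- rp[2]; e2 <- rp[3]
  tr <- resid$trait
  pair <- resid$pair
  di <- ifelse(tr == 1, e1, e2)
  i <- which(tr == 1 & !is.na(pair))   # trait-1 member of each pair
  j <- pair[i]                         # its trait-2 partner
  det2 <- e1 * e2 - e12^2
  dvals <- 1 / di
  ovals <- numeric(0)
  if (length(i)) {
    dvals[i] <- e2 / det2
    dvals[j] <- e1 / det2
    ovals <- rep(-e12 / det2, length(i))
  }
  Rinv <- Matrix::sparseMatrix(
    i = c(seq_len(n), i, j), j = c(seq_len(n), j, i),
    x = c(dvals, ovals, ovals), dims = c(n, n))
  ldet <- sum(log(di[is.na(pair)])) + length(i) * log(det2)
  list(Rinv = Rinv, ldet = ldet, det2 = det2, ipair = i, jpair = j)
}

## core evaluation at theta; returns likelihood pieces, solutions and
## (optionally) scores + AI matrix
.reml_eval <- function(theta, env, derivs = TRUE, need_cinv = TRUE) {
  terms <- env$terms; resid <- env$resid
  y <- env$y; W <- env$W; n <- env$n; p <- env$p
  sp <- .split_theta(theta, terms, resid$nt)

  ## G^-1 blocks and log|G|
  Ginv_blocks <- vector("list", length(terms))
  ldetG <- 0
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    if (tm$nt == 1) {
      s2 <- sp[[t]][1]
      Ginv_blocks[[t]] <- if (is.null(tm$Kinv)) diag(1 / s2, tm$q) else tm$Kinv / s2
      ldetG <- ldetG + tm$q * log(s2) + tm$ldetK
    } else {
      S <- .cov2x2(sp[[t]])
      Si <- solve(S)
      Ki <- if (is.null(tm$Kinv)) diag(tm$q) else tm$Kinv
      Ginv_blocks[[t]] <- kronecker(Si, Ki)
      ldetG <- ldetG + tm$q * determinant(S)$modulus[1] + 2 * tm$ldetK
    }
  }

  ## R^-1 and weighted cross-products
  rr <- .resid_rinv(sp$resid, resid, n)
  if (resid$nt == 1) {
    se2 <- sp$resid[1]
    CtWW <- as.matrix(env$WtW) / se2
    rhs <- env$Wty / se2
    ldetR <- rr$ldet
  } else {
    WtRi <- Matrix::crossprod(W, rr$Rinv)       # dimC x n sparse
    CtWW <- as.matrix(WtRi %*% W)
    rhs <- as.numeric(WtRi %*% y)
    ldetR <- rr$ldet
  }
  dimC <- ncol(CtWW)
  C <- CtWW
  for (t in seq_along(terms)) {
    J <- env$idx[[t]]
    C[J, J] <- C[J, J] + Ginv_blocks[[t]]
  }
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  s <- backsolve(L, backsolve(L, rhs, transpose = TRUE))
  e <- as.numeric(y - W %*% s)
  Py <- if (resid$nt == 1) e / sp$resid[1] else as.numeric(rr$Rinv %*% e)
  yPy <- sum(y * Py)
  ldetC <- 2 * sum(log(diag(L)))
  m2ll <- ldetC + ldetG + ldetR + yPy + (n - p) * log(2 * pi)

  out <- list(theta = theta, m2ll = m2ll, s = s, e = e, Py = Py, L = L,
              sp = sp, Ginv_blocks = Ginv_blocks, rr = rr)
  if (!derivs) {
    if (need_cinv) out$Cinv <- chol2inv(L)
    return(out)
  }

  Cinv <- chol2inv(L)
  out$Cinv <- Cinv

  npar <- env$npar
  trP <- numeric(npar)     # tr(P dV_k)
  quad <- numeric(npar)    # Py' dV_k Py
  vlist <- vector("list", npar)
  k <- 0L
  trCG <- 0                # tr(C^-1 blockdiag(0, Ginv))
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    J <- env$idx[[t]]
    CJJ <- Cinv[J, J, drop = FALSE]
    u <- as.numeric(Matrix::crossprod(tm$Z, Py))
    if (tm$nt == 1) {
      s2 <- sp[[t]][1]
      trKiC <- if (is.null(tm$Kinv)) sum(diag(CJJ)) else sum(tm$Kinv * CJJ)
      trCG <- trCG + trKiC / s2
      k <- k + 1L
      trP[k] <- tm$q / s2 - trKiC / s2^2
      Ku <- if (is.null(tm$K)) u else as.numeric(tm$K %*% u)
      quad[k] <- sum(u * Ku)
      vlist[[k]] <- as.numeric(tm$Z %*% Ku)
    } else {
      Gi <- Ginv_blocks[[t]]
      trCG <- trCG + sum(CJJ * Gi)
      D <- Gi - Gi %*% CJJ %*% Gi   # tr(P Z B Z') = tr(D B)
      q <- tm$q
      i1 <- seq_len(q); i2 <- q + i1
      Kd <- tm$K  # NULL means identity
      u1 <- u[i1]; u2 <- u[i2]
      Ku1 <- if (is.null(Kd)) u1 else as.numeric(Kd %*% u1)
      Ku2 <- if (is.null(Kd)) u2 else as.numeric(Kd %*% u2)
      trblk <- function(Dij) if (is.null(Kd)) sum(diag(Dij)) else sum(Dij * Kd)
      ## basis E11, E12 (symmetric), E22
      k <- k + 1L
      trP[k] <- trblk(D[i1, i1, drop = FALSE])
      quad[k] <- sum(u1 * Ku1)
      vlist[[k]] <- as.numeric(tm$Z %*% c(Ku1, numeric(q)))
      k <- k + 1L
      trP[k] <- 2 * trblk(D[i1, i2, drop = FALSE])
      quad[k] <- 2 * sum(u1 * Ku2)
      vlist[[k]] <- as.numeric(tm$Z %*% c(Ku2, Ku1))
      k <- k + 1L
      trP[k] <- trblk(D[i2, i2, drop = FALSE])
      quad[k] <- sum(u2 * Ku2)
      vlist[[k]] <- as.numeric(tm$Z %*% c(numeric(q), Ku2))
    }
  }
  ## residual parameters
  if (resid$nt == 1) {
    se2 <- sp$resid[1]
    k <- k + 1L
    trP[k] <- (n - dimC + trCG) / se2
    quad[k] <- sum(Py * Py)
    vlist[[k]] <- Py
  } else {
    ## entries of N = (W'R^-1)' C^-1 (W'R^-1) at the sparsity of dR
    WtRi <- Matrix::crossprod(W, rr$Rinv)
    Mhat <- backsolve(L, as.matrix(WtRi), transpose = TRUE)
    ndiag <- colSums(Mhat^2)
    tr1 <- resid$trait == 1
    Rinv_diag <- Matrix::diag(rr$Rinv)
    i <- rr$ipair; j <- rr$jpair
    npair_od <- if (length(i)) colSums(Mhat[, i, drop = FALSE] *
                                       Mhat[, j, drop = FALSE]) else numeric(0)
    Rinv_od <- -sp$resid[2] / rr$det2
    k <- k + 1L  # e11
    trP[k] <- sum(Rinv_diag[tr1]) - sum(ndiag[tr1])
    quad[k] <- sum(Py[tr1]^2)
    v <- numeric(n); v[tr1] <- Py[tr1]; vlist[[k]] <- v
    k <- k + 1L  # e12 (paired coupling)
    trP[k] <- if (length(i)) 2 * (length(i) * Rinv_od - sum(npair_od)) else 0
    quad[k] <- 2 * sum(Py[i] * Py[j])
    v <- numeric(n)
    if (length(i)) { v[i] <- Py[j]; v[j] <- Py[i] }
    vlist[[k]] <- v
    k <- k + 1L  # e22
    trP[k] <- sum(Rinv_diag[!tr1]) - sum(ndiag[!tr1])
    quad[k] <- sum(Py[!tr1]^2)
    v <- numeric(n); v[!tr1] <- Py[!tr1]; vlist[[k]] <- v
  }

  ## P v_k via one MME solve each, then AI = V' P V / 2
  PV <- matrix(0, n, npar)
  for (kk in seq_len(npar)) {
    v <- vlist[[kk]]
    if (resid$nt == 1) {
      wv <- as.numeric(Matrix::crossprod(W, v)) / sp$resid[1]
      cv <- backsolve(L, backsolve(L, wv, transpose = TRUE))
      PV[, kk] <- (v - as.numeric(W %*% cv)) / sp$resid[1]
    } else {
      rv <- as.numeric(rr$Rinv %*% v)
      wv <- as.numeric(Matrix::crossprod(W, rv))
      cv <- backsolve(L, backsolve(L, wv, transpose = TRUE))
      PV[, kk] <- rv - as.numeric(rr$Rinv %*% (W %*% cv))
    }
  }
  Vmat <- do.call(cbind, vlist)
  AI <- crossprod(Vmat, PV) / 2
  AI <- (AI + t(AI)) / 2
  score <- -0.5 * (trP - quad)
  out$score <- score
  out$AI <- AI
  out$trP <- trP
  out
}

## EM-REML step (univariate structures only; bivariate blocks get the
## multivariate EM analogue using C^{tt} blocks)
.reml_em <- function(ev, env) {
  terms <- env$terms; resid <- env$resid
  theta <- ev$theta
  sp <- .split_theta(theta, terms, resid$nt)
  pos <- 1L
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    J <- env$idx[[t]]
    u <- ev$s[J]
    CJJ <- ev$Cinv[J, J, drop = FALSE]
    if (tm$nt == 1) {
      if (is.null(tm$Kinv)) {
        theta[pos] <- (sum(u^2) + sum(diag(CJJ))) / tm$q
      } else {
        theta[pos] <- (sum(u * (tm$Kinv %*% u)) + sum(CJJ * tm$Kinv)) / tm$q
      }
      pos <- pos + 1L
    } else {
      q <- tm$q; i1 <- seq_len(q); i2 <- q + i1
      Ki <- if (is.null(tm$Kinv)) diag(q) else tm$Kinv
      uu <- cbind(u[i1], u[i2])
      Snew <- (crossprod(uu, Ki %*% uu) +
                 rbind(c(sum(CJJ[i1, i1] * Ki), sum(CJJ[i1, i2] * Ki)),
                       c(sum(CJJ[i2, i1] * Ki), sum(CJJ[i2, i2] * Ki)))) / q
      theta[pos:(pos + 2L)] <- c(Snew[1, 1], (Snew[1, 2] + Snew[2, 1]) / 2,
                                 Snew[2, 2])
      pos <- pos + 3L
    }
  }
  if (resid$nt == 1) {
    theta[pos] <- sum(env$y * ev$e) / (env$n - env$p)
  }
  ## bivariate residual: keep current values (AI handles them; EM fallback
  ## only replaces the genetic blocks)
  theta
}

#' @keywords internal
.reml_ai_fit <- function(y, X, terms, resid = list(nt = 1),
                         start = NULL, maxit = 100, tol = 1e-8,
                         floor_frac = 1e-6, fixed_mask = NULL,
                         verbose = FALSE) {
  n <- length(y)
  X <- as.matrix(X)
  ## drop aliased fixed-effect columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE),
             do.call(cbind, lapply(terms, `[[`, "Z")))
  idx <- list()
  pos <- p
  K <- list()
  for (t in seq_along(terms)) {
    nt <- terms[[t]]$nt; q <- terms[[t]]$q
    idx[[t]] <- pos + seq_len(nt * q)
    pos <- pos + nt * q
    K[[t]] <- terms[[t]]$K      # dense covariance or NULL (identity)
  }
  npar <- sum(vapply(terms, function(tm) .npar(tm$nt), 1L)) + .npar(resid$nt)
  env <- list(y = y, X = X, W = W, n = n, p = p, terms = terms, resid = resid,
              idx = idx, npar = npar, K = K,
              WtW = Matrix::crossprod(W),
              Wty = as.numeric(Matrix::crossprod(W, y)))

  ## per-trait phenotypic variances drive starting values and the parameter
  ## floor, so traits on very different scales start in the right region
  if (resid$nt == 2) {
    vy1 <- stats::var(y[resid$trait == 1])
    vy2 <- stats::var(y[resid$trait == 2])
    vy <- min(vy1, vy2)
  } else vy1 <- vy2 <- vy <- stats::var(y)
  floor <- floor_frac * vy
  if (is.null(start)) {
    nstr <- length(terms) + 1L
    start <- numeric(0)
    for (t in seq_along(terms)) {
      if (terms[[t]]$nt == 1) start <- c(start, vy1 / nstr)
      else start <- c(start, c(vy1 / nstr, 0, vy2 / nstr))
    }
    start <- c(start, if (resid$nt == 1) vy1 / nstr else
      c(vy1 / nstr, 0, vy2 / nstr))
  }
  theta <- pmax(start, ifelse(seq_along(start) %in% .offdiag_pos(terms, resid),
                              -Inf, floor))

  if (is.null(fixed_mask)) fixed_mask <- rep(FALSE, npar)
  mask_ai <- function(ev) {
    if (any(fixed_mask)) {
      ev$score[fixed_mask] <- 0
      ev$AI[fixed_mask, ] <- 0
      ev$AI[, fixed_mask] <- 0
      diag(ev$AI)[fixed_mask] <- 1
    }
    ev
  }
  ev <- .reml_eval(theta, env)
  if (is.null(ev)) stop("REML: coefficient matrix not positive definite at start",
                        call. = FALSE)
  ev <- mask_ai(ev)
  trace <- data.frame(iter = 0L, m2ll = ev$m2ll, step = "start")
  converged <- FALSE
  stall <- 0L
  bound_cnt <- integer(npar)
  frozen <- FALSE
  any_clamped <- FALSE
  offd <- .offdiag_pos(terms, resid)
  proj <- function(th) {
    out <- .project_valid(th, terms, resid$nt, floor)
    if (isTRUE(attr(out, "clamped"))) any_clamped <<- TRUE
    as.numeric(out)
  }
  for (it in seq_len(maxit)) {
    step_kind <- "AI"
    delta <- tryCatch(solve(ev$AI + diag(1e-10, nrow(ev$AI)), ev$score),
                      error = function(e) NULL)
    cand <- NULL
    if (!is.null(delta)) {
      ## AI proposal, projected onto the parameter space (variances floored,
      ## covariance blocks PSD); step-halve if projection still invalid or
      ## the likelihood degrades
      for (h in 0:3) {
        prop <- ev$theta + delta / 2^h
        prop[fixed_mask] <- ev$theta[fixed_mask]
        prop <- proj(prop)
        if (!.theta_valid(prop, terms, resid$nt, floor)) next
        chk <- .reml_eval(prop, env, derivs = FALSE, need_cinv = FALSE)
        if (!is.null(chk) && chk$m2ll <= ev$m2ll + 1e-7) {
          cand <- .reml_eval(prop, env)
          break
        }
      }
      if (!is.null(cand)) cand <- mask_ai(cand)
    }
    if (is.null(cand) && !is.null(delta)) {
      ## pin boundary parameters and take the AI step on the rest:
      ## variances sitting at the floor with the score pushing further down,
      ## and covariances at the PSD correlation bound pushing outward
      sp_cur <- .split_theta(ev$theta, terms, resid$nt)
      pin <- which(!fixed_mask & !seq_along(ev$theta) %in% offd &
                     ev$theta <= floor * 1.01 & ev$score < 0)
      ## covariance parameters at the PSD bound, score pushing outward
      pos <- 1L
      pinned_vals <- ev$theta
      blocks <- c(lapply(seq_along(terms), function(t) sp_cur[[t]]),
                  list(sp_cur$resid))
      for (b in blocks) {
        if (length(b) == 3) {
          kk <- pos + 1L
          lim <- 0.999 * sqrt(b[1] * b[3])
          if (!fixed_mask[kk] && abs(b[2]) >= lim * (1 - 1e-6) &&
              sign(ev$score[kk]) == sign(b[2]))
            pin <- c(pin, kk)
          pos <- pos + 3L
        } else pos <- pos + 1L
      }
      pin <- sort(unique(c(pin)))
      free <- setdiff(which(!fixed_mask), pin)
      if (length(pin) > 0 && length(free) > 0) {
        dsub <- tryCatch(solve(ev$AI[free, free, drop = FALSE] +
                                 diag(1e-10, length(free)), ev$score[free]),
                         error = function(e) NULL)
        if (!is.null(dsub)) {
          for (h in 0:3) {
            prop <- ev$theta
            prop[free] <- prop[free] + dsub / 2^h
            prop[pin] <- ifelse(pin %in% offd, ev$theta[pin], floor)
            prop <- proj(prop)
            if (!.theta_valid(prop, terms, resid$nt, floor)) next
            chk <- .reml_eval(prop, env, derivs = FALSE, need_cinv = FALSE)
            if (!is.null(chk) && chk$m2ll <= ev$m2ll + 1e-7) {
              cand <- .reml_eval(prop, env)
              break
            }
          }
          if (!is.null(cand)) { cand <- mask_ai(cand); step_kind <- "AI-pin" }
        }
      }
    }
    if (is.null(cand)) {
      step_kind <- "EM"
      em <- .reml_em(ev, env)
      em[fixed_mask] <- ev$theta[fixed_mask]
      ## EM with step extrapolation: plain EM creeps along boundary ridges,
      ## so try amplified versions of the EM direction first
      for (alpha in c(16, 8, 4, 2, 1)) {
        prop <- proj(ev$theta + alpha * (em - ev$theta))
        if (!.theta_valid(prop, terms, resid$nt, floor)) next
        if (alpha > 1) {
          chk <- .reml_eval(prop, env, derivs = FALSE, need_cinv = FALSE)
          if (is.null(chk) || chk$m2ll > ev$m2ll + 1e-9) next
        }
        ## the plain (alpha = 1) EM step is accepted whenever it evaluates:
        ## EM never increases -2logL beyond numerical noise
        cand <- .reml_eval(prop, env)
        if (!is.null(cand)) {
          if (alpha > 1) step_kind <- "EM-acc"
          break
        }
      }
      if (is.null(cand)) stop("REML failed: singular system in EM step",
                              call. = FALSE)
      cand <- mask_ai(cand)
    }
    rel <- abs(cand$m2ll - ev$m2ll) / (abs(ev$m2ll) + 1e-10)
    drel <- max(abs(cand$theta - ev$theta) / (abs(ev$theta) + 1e-8))
    ev <- cand
    trace <- rbind(trace, data.frame(iter = it, m2ll = ev$m2ll, step = step_kind))
    if (verbose) message(sprintf("it %d [%s] -2logL = %.8f", it, step_kind, ev$m2ll))
    if (rel < tol) { converged <- TRUE; break }
    ## boundary stall: accepted steps that barely move the parameters while
    ## the likelihood creeps along a constraint count as converged
    stall <- if (drel < 1e-5) stall + 1L else 0L
    if (stall >= 3L) { converged <- TRUE; break }
    ## parameters glued to a constraint for several consecutive iterations
    ## are frozen there so the free parameters can converge (boundary fix,
    ## as variance-component solvers conventionally do)
    sp_b <- .split_theta(ev$theta, terms, resid$nt)
    at_b <- rep(FALSE, length(ev$theta))
    pos <- 1L
    for (b in c(sp_b[seq_along(terms)], list(sp_b$resid))) {
      if (length(b) == 3) {
        lim <- 0.999 * sqrt(b[1] * b[3])
        if (abs(b[2]) >= lim * (1 - 1e-6)) at_b[pos:(pos + 2L)] <- TRUE
        if (b[1] <= floor * 1.01) at_b[pos] <- TRUE
        if (b[3] <= floor * 1.01) at_b[pos + 2L] <- TRUE
        pos <- pos + 3L
      } else {
        if (b[1] <= floor * 1.01) at_b[pos] <- TRUE
        pos <- pos + 1L
      }
    }
    bound_cnt <- ifelse(at_b, bound_cnt + 1L, 0L)
    newly <- bound_cnt >= 4L & !fixed_mask
    if (any(newly)) {
      fixed_mask[newly] <- TRUE
      frozen <- TRUE
      ev <- mask_ai(ev)
    }
  }
  if (any_clamped)
    warning("covariance update(s) projected to nearest PSD during REML")
  if (frozen)
    warning("boundary parameter(s) frozen at their constraint during REML")
  if (!converged)
    warning("REML did not converge in ", maxit,
            " iterations (relative -2logL change above tolerance)")

  se <- tryCatch(sqrt(pmax(diag(solve(ev$AI)), 0)), error = function(e)
    rep(NA_real_, length(ev$theta)))
  se[fixed_mask] <- NA_real_
  boundary <- ev$theta <= floor * (1 + 1e-6)
  boundary[.offdiag_pos(terms, resid)] <- FALSE
  list(theta = ev$theta, se = se, AI = ev$AI, m2ll = ev$m2ll,
       converged = converged, iterations = trace, boundary = boundary,
       s = ev$s, e = ev$e, Cinv = ev$Cinv, idx = idx, p = p, X = X,
       floor = floor)
}

## positions of off-diagonal (covariance) parameters in theta
.offdiag_pos <- function(terms, resid) {
  pos <- integer(0)
  k <- 0L
  for (t in seq_along(terms)) {
    if (terms[[t]]$nt == 1) k <- k + 1L
    else { pos <- c(pos, k + 2L); k <- k + 3L }
  }
  if (resid$nt == 2) pos <- c(pos, k + 2L)
  pos
}

## project parameters back to the valid region (floors + PSD 2x2 blocks);
## attribute "clamped" records whether a covariance was PSD-projected
.project_valid <- function(theta, terms, nt_resid, floor) {
  clamped <- FALSE
  sp <- .split_theta(theta, terms, nt_resid)
  fix2 <- function(p) {
    p[1] <- max(p[1], floor); p[3] <- max(p[3], floor)
    lim <- 0.999 * sqrt(p[1] * p[3])
    if (abs(p[2]) > lim) {
      clamped <<- TRUE
      p[2] <- sign(p[2]) * lim
    }
    p
  }
  out <- numeric(0)
  for (t in seq_along(terms)) {
    p <- sp[[t]]
    out <- c(out, if (terms[[t]]$nt == 1) max(p[1], floor) else fix2(p))
  }
  p <- sp$resid
  out <- c(out, if (nt_resid == 1) max(p[1], floor) else fix2(p))
  attr(out, "clamped") <- clamped
  out
}

## BLUP solve at fixed variance components (no iteration); returns solutions,
## the fixed-effect covariance and per-term C^{tt} diagonals (PEVs)
.mme_solve <- function(y, X, terms, resid = list(nt = 1), theta,
                       need_cinv = TRUE) {
  n <- length(y)
  X <- as.matrix(X)
  qrX <- qr(X)
  kept <- qrX$pivot[seq_len(qrX$rank)]
  if (qrX$rank < ncol(X)) X <- X[, kept, drop = FALSE]
  p <- ncol(X)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE),
             do.call(cbind, lapply(terms, `[[`, "Z")))
  idx <- list()
  pos <- p
  for (t in seq_along(terms)) {
    nt <- terms[[t]]$nt; q <- terms[[t]]$q
    idx[[t]] <- pos + seq_len(nt * q)
    pos <- pos + nt * q
  }
  env <- list(y = y, X = X, W = W, n = n, p = p, terms = terms, resid = resid,
              idx = idx, npar = NA, K = lapply(terms, `[[`, "K"),
              WtW = Matrix::crossprod(W),
              Wty = as.numeric(Matrix::crossprod(W, y)))
  ev <- .reml_eval(theta, env, derivs = FALSE, need_cinv = need_cinv)
  if (is.null(ev))
    stop("singular coefficient matrix in BLUP solve", call. = FALSE)
  list(s = ev$s, e = ev$e, Cinv = ev$Cinv, idx = idx, p = p, X = X,
       kept = kept, m2ll = ev$m2ll)
}
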