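#' Multi-GRM REML variance component estimation
#'
#' Fits \eqn{y = 1\mu + \sum_f g_f + \epsilon} with \eqn{Var(g_f) = G_f
#' \sigma^2_f} and \eqn{Var(\epsilon) = I\sigma^2_\epsilon} by restricted
#' maximum likelihood, using average-information (AI) updates with an
#' expectation-maximisation first step and EM fallback whenever an AI
#' step would leave the feasible region.  Components that an update
#' drives negative are pinned at (effectively) zero.  With a single GRM
#' the problem is rotated once into the GRM's eigenbasis, making every
#' iteration O(n); with several GRMs dense O(n^3) algebra is used.
#'
#' @param y phenotypes: a named numeric vector, or a data.frame with
#'   columns \code{animal_id} and \code{dpta} (deregressed PTA).
#' @param grms a \linkS4class{GRM} or (optionally named) list of GRMs
#'   sharing a common sample set.
#' @param maxIter maximum iterations (default 200).
#' @param tol convergence tolerance on the relative parameter change and
#'   log-likelihood increase (default 1e-6).
#' @param verbose print the iteration trajectory.
#' @return a \linkS4class{VarCompFit}.
#' @examples
#' gm <- simGenotypes(300, 400, seed = 1)
#' sim <- simEffectsAndPhenotypes(gm, h2Target = 0.5, seed = 2)
#' fit <- fitREML(sim$phenotypes, computeGRM(gm))
#' h2All(fit)
#' @export
fitREML <- function(y, grms, maxIter = 200L, tol = 1e-6, verbose = FALSE) {
  if (is(grms, "GRM")) grms <- list(grms)
  stopifnot2(length(grms) >= 1, "need at least one GRM")
  if (is.null(names(grms)))
    names(grms) <- if (length(grms) == 1) "genetic"
                   else paste0("component", seq_along(grms))

  ids <- sampleIds(grms[[1]])
  for (g in grms)
    stopifnot2(setequal(sampleIds(g), ids), "GRMs must share the sample set")
  yv <- phenoVector(y)
  stopifnot2(all(ids %in% names(yv)),
             "phenotypes missing for some GRM samples")
  yv <- yv[ids]
  n <- length(yv)
  stopifnot2(stats::var(yv) > 0, "phenotype variance is zero")

  Gs <- lapply(grms, function(g) grmMatrix(g)[ids, ids])

  if (length(Gs) == 1L) {
    eg <- eigen(Gs[[1]], symmetric = TRUE)
    state <- list(kind = "diag", d = eg$values,
                  w = drop(crossprod(eg$vectors, yv)),
                  x = drop(crossprod(eg$vectors, rep(1, n))))
  } else {
    state <- list(kind = "dense", Gs = Gs, y = yv, X = matrix(1, n, 1))
  }
  res <- remlIterate(state, n, k = length(Gs), vy = stats::var(yv),
                     maxIter = as.integer(maxIter), tol = tol,
                     verbose = verbose)

  sg <- res$theta[seq_along(Gs)]
  names(sg) <- names(grms)
  se <- res$se
  names(se) <- c(names(grms), "residual")
  seProp <- res$seProp
  names(seProp) <- names(grms)
  new("VarCompFit", sigma2 = sg, sigma2e = res$theta[length(res$theta)],
      se = se, seProp = seProp, loglik = res$loglik,
      converged = res$converged, nIter = res$nIter, n = as.integer(n))
}

phenoVector <- function(y) {
  if (is.data.frame(y)) {
    stopifnot2(all(c("animal_id", "dpta") %in% names(y)),
               "phenotype data.frame needs animal_id and dpta columns")
    stopifnot2(!anyDuplicated(y$animal_id), "duplicate animal IDs")
    stats::setNames(y$dpta, y$animal_id)
  } else {
    stopifnot2(!is.null(names(y)), "phenotype vector must be named")
    y
  }
}

# One REML evaluation: gradient, AI matrix, log-likelihood.
# theta = (sigma2_1..k, sigma2_e).
remlEval <- function(state, theta, n, k) {
  if (state$kind == "diag") {
    v <- theta[1] * state$d + theta[2]
    w <- state$w; x <- state$x
    iv <- 1 / v
    xtvx <- sum(x^2 * iv)
    Pvec <- function(u) u * iv - x * iv * (sum(x * u * iv) / xtvx)
    Pw <- Pvec(w)
    Pdiag <- iv - (x * iv)^2 / xtvx
    q <- list(state$d * Pw, Pw)
    trPG <- c(sum(state$d * Pdiag), sum(Pdiag))
    yPGPy <- c(sum(Pw * q[[1]]), sum(Pw * q[[2]]))
    AI <- matrix(0, 2, 2)
    Pq <- lapply(q, Pvec)
    for (i in 1:2) for (j in i:2)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(q[[i]] * Pq[[j]])
    yPy <- sum(w * Pw)
    logdetV <- sum(log(v))
    logdetX <- log(xtvx)
  } else {
    Gs <- state$Gs
    V <- diag(theta[k + 1], n)
    for (i in seq_len(k)) V <- V + theta[i] * Gs[[i]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vinv <- chol2inv(R)
    VinvX <- rowSums(Vinv)               # X = 1
    xtvx <- sum(VinvX)
    P <- Vinv - tcrossprod(VinvX) / xtvx
    Pw <- drop(P %*% state$y)
    q <- vector("list", k + 1)
    trPG <- numeric(k + 1)
    for (i in seq_len(k)) {
      q[[i]] <- drop(Gs[[i]] %*% Pw)
      trPG[i] <- sum(P * Gs[[i]])
    }
    q[[k + 1]] <- Pw
    trPG[k + 1] <- sum(diag(P))
    yPGPy <- vapply(q, function(u) sum(Pw * u), 0)
    AI <- matrix(0, k + 1, k + 1)
    Pq <- lapply(q, function(u) drop(P %*% u))
    for (i in seq_len(k + 1)) for (j in i:(k + 1))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(q[[i]] * Pq[[j]])
    yPy <- sum(state$y * Pw)
    logdetV <- 2 * sum(log(diag(R)))
    logdetX <- log(xtvx)
  }
  grad <- -0.5 * (trPG - yPGPy)
  loglik <- -0.5 * (logdetV + logdetX + yPy + (n - 1) * log(2 * pi))
  list(grad = grad, AI = AI, loglik = loglik, trPG = trPG, yPGPy = yPGPy)
}

remlIterate <- function(state, n, k, vy, maxIter, tol, verbose) {
  np <- k + 1L
  theta <- rep(vy / np, np)
  floorv <- 1e-8 * vy
  ev <- remlEval(state, theta, n, k)
  stopifnot2(!is.null(ev), "singular phenotype covariance at start")
  loglik <- ev$loglik
  converged <- FALSE
  iter <- 0L

  emStep <- function(theta, ev)
    (theta^2 * ev$yPGPy + n * theta - theta^2 * ev$trPG) / n

  for (iter in seq_len(maxIter)) {
    if (iter == 1L) {
      cand <- emStep(theta, ev)
    } else {
      step <- tryCatch(solve(ev$AI, ev$grad), error = function(e) NULL)
      if (is.null(step)) {
        cand <- emStep(theta, ev)            # EM fallback: AI singular
      } else {
        cand <- theta + step
        if (any(cand < 0)) {
          # project onto the feasible region: pin offending components
          # at the floor and re-solve the AI system for the rest
          pin <- cand < floorv
          for (rep_ in seq_len(np)) {
            freeI <- which(!pin)
            if (!length(freeI)) break
            adj <- ev$grad[freeI] -
              ev$AI[freeI, pin, drop = FALSE] %*% (floorv - theta[pin])
            st2 <- tryCatch(solve(ev$AI[freeI, freeI, drop = FALSE], adj),
                            error = function(e) NULL)
            if (is.null(st2)) { cand <- emStep(theta, ev); break }
            cand <- theta
            cand[pin] <- floorv
            cand[freeI] <- theta[freeI] + st2
            if (!any(cand[freeI] < 0)) break
            pin <- pin | (cand < floorv)
          }
        }
      }
    }
    cand[cand < floorv] <- floorv
    evNew <- remlEval(state, cand, n, k)
    if (is.null(evNew)) { # numerically singular: shrink toward current
      cand <- (theta + cand) / 2
      evNew <- remlEval(state, cand, n, k)
      if (is.null(evNew)) break
    }
    # simple step-halving if the likelihood dropped noticeably
    h <- 0
    while (evNew$loglik < loglik - 1e-8 && h < 8) {
      cand <- (theta + cand) / 2
      evNew <- remlEval(state, cand, n, k)
      h <- h + 1
    }
    delta <- sqrt(sum((cand - theta)^2) / max(sum(cand^2), 1e-30))
    dll <- evNew$loglik - loglik
    theta <- cand; ev <- evNew; loglik <- evNew$loglik
    if (verbose)
      message(sprintf("iter %3d  logLik %.6f  theta: %s", iter, loglik,
                      paste(signif(theta, 5), collapse = " ")))
    if (iter > 1L && delta < tol && abs(dll) < max(tol, 1e-6)) {
      converged <- TRUE
      break
    }
  }

  C <- tryCatch(solve(ev$AI), error = function(e)
    matrix(NA_real_, np, np))
  se <- sqrt(pmax(diag(C), 0))
  # delta method for proportions h_i = theta_i / sum(theta)
  S <- sum(theta)
  seProp <- vapply(seq_len(k), function(i) {
    dd <- -theta[i] / S^2 * rep(1, np)
    dd[i] <- dd[i] + 1 / S
    sqrt(max(drop(t(dd) %*% C %*% dd), 0))
  }, 0)
  theta[theta <= 1.5 * floorv] <- 0
  list(theta = theta, se = se, seProp = seProp, loglik = loglik,
       converged = converged, nIter = iter)
}
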