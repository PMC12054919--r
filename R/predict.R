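#' Deregress predicted transmitting abilities
#'
#' \code{dpta = pta / reliability^2}, removing parental information so
#' records behave as quasi-independent phenotypes.
#'
#' @param pta numeric PTA values.
#' @param reliability per-animal reliability in (0, 1].
#' @return deregressed PTA values.
#' @examples
#' deregress(1, 0.8)  # 1.5625
#' @export
deregress <- function(pta, reliability) {
  stopifnot2(all(reliability > 0 & reliability <= 1),
             "reliability must lie in (0, 1]")
  pta / reliability^2
}

#' Split animals into reference and validation by birth year
#'
#' Reference animals are born strictly before the cutoff; validation
#' animals at or after it.
#'
#' @param animals character vector of animal IDs.
#' @param birthYears numeric vector aligned with \code{animals}.
#' @param cutoff birth-year cutoff.
#' @return list: reference, validation (character vectors).
#' @export
splitReferenceValidation <- function(animals, birthYears, cutoff) {
  stopifnot2(length(animals) == length(birthYears),
             "every animal needs a birth year")
  ref <- animals[birthYears < cutoff]
  val <- animals[birthYears >= cutoff]
  stopifnot2(length(ref) > 0, "reference population is empty")
  stopifnot2(length(val) > 0, "validation population is empty")
  list(reference = ref, validation = val)
}

#' GBLUP genomic prediction
#'
#' BLUP of genomic values from the mixed model \eqn{y = 1\mu + Zg + e},
#' \eqn{g \sim N(0, G\sigma^2_g)}.  Only reference animals' phenotypes
#' enter the equations; validation animals receive GEBVs through their
#' genomic relationships with the reference block.
#'
#' @param y phenotypes of the reference animals (named vector or
#'   data.frame; see \code{\link{fitREML}}).  Animals in the GRM but
#'   absent from \code{y} are treated as validation.
#' @param grm a \linkS4class{GRM} over all animals.
#' @param sigma2g,sigma2e variance components; estimated by
#'   \code{\link{fitREML}} on the reference block when NULL.
#' @return a \linkS4class{PredictionFit} with GEBVs for every animal in
#'   the GRM.
#' @export
solveGBLUP <- function(y, grm, sigma2g = NULL, sigma2e = NULL) {
  yv <- phenoVector(y)
  all <- sampleIds(grm)
  ref <- intersect(all, names(yv))
  stopifnot2(length(ref) >= 2, "need >= 2 reference animals")
  G <- grmMatrix(grm)

  if (is.null(sigma2g) || is.null(sigma2e)) {
    sub <- new("GRM", mat = G[ref, ref], nVariantsUsed = nVariantsUsed(grm))
    fit <- fitREML(yv[ref], sub)
    sigma2g <- unname(fit@sigma2[1])
    sigma2e <- fit@sigma2e
  }

  n <- length(ref)
  V <- sigma2g * G[ref, ref] + diag(sigma2e, n)
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) {
    message("singular coefficient matrix; ridge of 1e-8 added")
    chol2inv(chol(V + diag(1e-8 * mean(diag(V)), n)))
  })
  one <- rep(1, n)
  mu <- sum(Vi %*% yv[ref]) / sum(Vi)
  r <- drop(Vi %*% (yv[ref] - mu))
  g <- sigma2g * drop(G[, ref] %*% r)
  names(g) <- all
  new("PredictionFit", model = "GBLUP", gebv = g,
      hyper = list(sigma2g = sigma2g, sigma2e = sigma2e, mu = mu),
      mcmc = list(), piPosterior = NULL)
}

#' MultiBLUP genomic prediction with two genomic components
#'
#' \eqn{y = 1\mu + Zg_f + Zg_r + e} with independent genomic values for
#' the functional-class markers (\eqn{G_f}) and the remaining markers
#' (\eqn{G_r}).  Total GEBV is \eqn{\hat g_f + \hat g_r}.
#'
#' @param y reference phenotypes (see \code{\link{solveGBLUP}}).
#' @param grmFunctional,grmRest \linkS4class{GRM}s over all animals.
#' @param sigma2f,sigma2r,sigma2e variance components; estimated jointly
#'   by \code{\link{fitREML}} on the reference block when NULL.
#' @return a \linkS4class{PredictionFit}.
#' @export
solveMultiBLUP <- function(y, grmFunctional, grmRest, sigma2f = NULL,
                           sigma2r = NULL, sigma2e = NULL) {
  yv <- phenoVector(y)
  all <- sampleIds(grmFunctional)
  stopifnot2(setequal(all, sampleIds(grmRest)),
             "GRMs must cover the same animals")
  ref <- intersect(all, names(yv))
  Gf <- grmMatrix(grmFunctional)[all, all]
  Gr <- grmMatrix(grmRest)[all, all]

  if (is.null(sigma2f) || is.null(sigma2r) || is.null(sigma2e)) {
    grms <- list(
      functional = new("GRM", mat = Gf[ref, ref],
                       nVariantsUsed = nVariantsUsed(grmFunctional)),
      rest = new("GRM", mat = Gr[ref, ref],
                 nVariantsUsed = nVariantsUsed(grmRest)))
    fit <- fitREML(yv[ref], grms)
    sigma2f <- unname(fit@sigma2["functional"])
    sigma2r <- unname(fit@sigma2["rest"])
    sigma2e <- fit@sigma2e
  }

  n <- length(ref)
  V <- sigma2f * Gf[ref, ref] + sigma2r * Gr[ref, ref] + diag(sigma2e, n)
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) {
    message("singular coefficient matrix; ridge of 1e-8 added")
    chol2inv(chol(V + diag(1e-8 * mean(diag(V)), n)))
  })
  mu <- sum(Vi %*% yv[ref]) / sum(Vi)
  r <- drop(Vi %*% (yv[ref] - mu))
  gf <- sigma2f * drop(Gf[, ref] %*% r)
  gr <- sigma2r * drop(Gr[, ref] %*% r)
  g <- gf + gr
  names(g) <- all
  new("PredictionFit", model = "MultiBLUP", gebv = g,
      hyper = list(sigma2f = sigma2f, sigma2r = sigma2r,
                   sigma2e = sigma2e, mu = mu,
                   gebvFunctional = gf, gebvRest = gr),
      mcmc = list(), piPosterior = NULL)
}

#' BayesR genomic prediction
#'
#' Single-site Gibbs sampling of \eqn{y = 1\mu + Ws + e} with SNP
#' effects from a four-component normal mixture
#' \eqn{N(0, \gamma_k\sigma^2_\beta)}, \eqn{\gamma = (0, 0.01, 0.1, 1)}.
#' Mixing proportions get a Dirichlet update unless \code{fixPi}.
#' Variances follow scaled-inverse-chi-square priors with \eqn{\nu = 4}.
#' GEBVs are the centred-genotype product with the posterior-mean
#' effects.
#'
#' @param y reference phenotypes (named vector or data.frame); animals
#'   in \code{geno} but not in \code{y} are validation animals.
#' @param geno a \linkS4class{GenotypeMatrix} over all animals.
#' @param pi starting (or fixed) mixing proportions, length 4 summing to
#'   1.
#' @param fixPi keep \code{pi} fixed instead of sampling it.
#' @param nIter,burnIn chain length and burn-in (defaults 25000 / 5000;
#'   scale down for desk-sized problems).
#' @param seed integer seed (drives R's RNG).
#' @param dirichletAlpha Dirichlet prior count per component (default 1).
#' @return a \linkS4class{PredictionFit}; \code{hyper} carries posterior
#'   means and the \code{sigma2e} trace, \code{piPosterior} the
#'   posterior-mean proportions.
#' @export
gibbsBayesR <- function(y, geno, pi = c(0.25, 0.25, 0.25, 0.25),
                        fixPi = FALSE, nIter = 25000, burnIn = 5000,
                        seed = 1, dirichletAlpha = 1) {
  res <- bayesMixtureFit(y, geno, classOf = NULL, pi = pi, fixPi = fixPi,
                         nIter = nIter, burnIn = burnIn, seed = seed,
                         dirichletAlpha = dirichletAlpha)
  new("PredictionFit", model = "BayesR", gebv = res$gebv,
      hyper = res$hyper,
      mcmc = list(nIter = nIter, burnIn = burnIn, seed = seed),
      piPosterior = res$pi)
}

#' BayesRC genomic prediction with annotation classes
#'
#' As \code{\link{gibbsBayesR}}, but every SNP belongs to exactly one
#' annotation class and each class keeps its own mixture proportions
#' (\eqn{\pi_f} vs \eqn{\pi_r} in the two-class case), each with its own
#' Dirichlet update.  An empty functional class reduces the model to
#' BayesR (warning).
#'
#' @inheritParams gibbsBayesR
#' @param classAssign character/factor per variant (length
#'   \code{nVariants(geno)}): the annotation class of each SNP.
#' @return a \linkS4class{PredictionFit}; \code{piPosterior} has one row
#'   per class.
#' @export
gibbsBayesRC <- function(y, geno, classAssign,
                         pi = c(0.25, 0.25, 0.25, 0.25), fixPi = FALSE,
                         nIter = 25000, burnIn = 5000, seed = 1,
                         dirichletAlpha = 1) {
  classAssign <- as.factor(classAssign)
  stopifnot2(length(classAssign) == nVariants(geno),
             "classAssign must cover every variant")
  used <- table(classAssign)
  if (any(used == 0) || nlevels(classAssign) < 2) {
    warning("empty annotation class; falling back to BayesR")
    classAssign <- NULL
  }
  res <- bayesMixtureFit(y, geno, classOf = classAssign, pi = pi,
                         fixPi = fixPi, nIter = nIter, burnIn = burnIn,
                         seed = seed, dirichletAlpha = dirichletAlpha)
  new("PredictionFit", model = "BayesRC", gebv = res$gebv,
      hyper = res$hyper,
      mcmc = list(nIter = nIter, burnIn = burnIn, seed = seed),
      piPosterior = res$pi)
}

# shared driver for the mixture models
bayesMixtureFit <- function(y, geno, classOf, pi, fixPi, nIter, burnIn,
                            seed, dirichletAlpha) {
  stopifnot2(nIter > burnIn, "nIter must exceed burnIn")
  stopifnot2(abs(sum(pi) - 1) < 1e-8 && all(pi >= 0),
             "pi must be nonnegative and sum to 1")
  yv <- phenoVector(y)
  all <- sampleIds(geno)
  ref <- intersect(all, names(yv))
  stopifnot2(length(ref) >= 2, "need >= 2 reference animals")

  gamma <- c(0, 0.01, 0.1, 1)
  D <- dosages(geno)
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  W <- scale(D, center = TRUE, scale = FALSE)
  Wref <- W[ref, , drop = FALSE]

  if (is.null(classOf)) {
    cls <- integer(ncol(W))
    piInit <- matrix(pi, nrow = 1)
    classLevels <- "all"
  } else {
    cls <- as.integer(as.factor(classOf)) - 1L
    classLevels <- levels(as.factor(classOf))
    piInit <- matrix(rep(pi, each = length(classLevels)),
                     nrow = length(classLevels))
  }

  vary <- stats::var(yv[ref])
  sumWtw <- sum(colSums(Wref^2)) / length(ref)
  meanGamma <- sum(pi * gamma)
  s0b <- 0.5 * vary / max(meanGamma * sumWtw, .Machine$double.eps)

  res <- withSeed(seed,
    .bayesrGibbs(yv[ref], Wref, cls, gamma, piInit, fixPi,
                 as.integer(nIter), as.integer(burnIn), nu0 = 4,
                 s0e = vary / 2, s0b = s0b,
                 dirichletAlpha = dirichletAlpha))
  if (!all(is.finite(res$effects)))
    stop("non-finite likelihood in the Gibbs chain; check inputs")

  gebvAll <- drop(W %*% res$effects)
  names(gebvAll) <- all
  piOut <- res$pi
  dimnames(piOut) <- list(classLevels, paste0("pi", 1:4))
  list(gebv = gebvAll,
       hyper = list(mu = res$mu, sigma2e = res$sigma2e,
                    sigma2beta = res$sigma2beta,
                    effects = stats::setNames(drop(res$effects),
                                              variantIds(geno)),
                    inclusion = stats::setNames(drop(res$inclusion),
                                                variantIds(geno)),
                    sigma2eTrace = drop(res$sigma2eTrace)),
       pi = piOut)
}

#' Validation reliability of genomic predictions
#'
#' Squared Pearson correlation between GEBV and deregressed PTA over the
#' validation animals, times 100 (percent).
#'
#' @param gebv named numeric GEBVs (must cover the validation animals).
#' @param dptaValidation named numeric deregressed PTAs of >= 10
#'   validation animals.
#' @return reliability in percent.
#' @export
predictionReliability <- function(gebv, dptaValidation) {
  ids <- names(dptaValidation)
  stopifnot2(length(ids) >= 10, "need >= 10 validation animals")
  stopifnot2(all(ids %in% names(gebv)), "GEBVs missing for some animals")
  g <- gebv[ids]
  if (stats::sd(g) == 0) {
    warning("zero-variance GEBV; reliability set to 0")
    return(0)
  }
  100 * stats::cor(g, dptaValidation)^2
}

#' Model-comparison arithmetic for reliability tables
#'
#' Per-trait reliability increase of each model over a baseline, plus
#' the grand average across traits.  Increases are computed before any
#' rounding; \code{digits} only affects the rendered copy.
#'
#' @param reports named list: model/panel name -> named numeric vector
#'   of per-trait reliabilities (percent), all sharing the same traits.
#' @param baseline name of the baseline entry in \code{reports}.
#' @param digits decimals for the rendered table (default 2).
#' @return list: \code{increase} (matrix models x traits),
#'   \code{average} (named numeric per model), \code{rendered}
#'   (character matrix at \code{digits} decimals).
#' @examples
#' compareModels(list(`671K` = c(MY = 75.13), `625K` = c(MY = 75.48)),
#'               baseline = "671K")$increase
#' @export
compareModels <- function(reports, baseline, digits = 2) {
  stopifnot2(baseline %in% names(reports), "unknown baseline")
  traits <- names(reports[[baseline]])
  for (nm in names(reports))
    stopifnot2(setequal(names(reports[[nm]]), traits),
               paste0("trait mismatch in '", nm, "'"))
  others <- setdiff(names(reports), baseline)
  inc <- t(vapply(others, function(nm)
    reports[[nm]][traits] - reports[[baseline]][traits],
    numeric(length(traits))))
  dimnames(inc) <- list(others, traits)
  avg <- rowMeans(inc)
  list(increase = inc, average = avg,
       rendered = matrix(sprintf(paste0("%.", digits, "f"), inc),
                         nrow = nrow(inc), dimnames = dimnames(inc)))
}
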