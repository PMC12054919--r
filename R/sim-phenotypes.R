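#' Simulate SNP effects and PTA-like phenotypes under a mixture prior
#'
#' Each variant's effect is drawn from a four-component normal mixture
#' \eqn{N(0, \gamma_k \sigma^2_\beta)} with \eqn{\gamma = (0, 0.01, 0.1,
#' 1)}; the mixing proportions are class-specific, so functional classes
#' can be enriched (or depleted) for non-null effects.  The genetic value
#' is the centred-dosage inner product with the effects, rescaled post hoc
#' so that \eqn{var(g)/var(y)} hits \code{h2Target} exactly in the
#' simulated sample.  The phenotype is reported as a deregressed-PTA-like
#' value: \eqn{y_i = g_i + e_i} with \eqn{e_i \sim N(0,
#' \sigma^2_e/r_i)} and per-animal reliability \eqn{r_i} drawn uniformly
#' in \code{reliabilityRange}, so lower reliability means a noisier
#' record.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param classMap a \linkS4class{FunctionalClassMap}; variants outside
#'   every listed class use the \code{"other"} mixture.
#' @param classPi named list: class name (including \code{"other"}) ->
#'   length-4 mixing proportions summing to 1.  Classes not listed default
#'   to all-null \code{c(1, 0, 0, 0)}.
#' @param h2Target target heritability in (0, 1).
#' @param reliabilityRange length-2 vector in (0, 1]: uniform bounds for
#'   per-animal reliability.
#' @param seed integer seed.
#' @return list with elements \code{truth} (list: \code{effects},
#'   \code{componentOf}, \code{classOfEffect}, \code{geneticValues},
#'   \code{h2Realized}) and \code{phenotypes} (data.frame:
#'   \code{animal_id}, \code{dpta}, \code{reliability}).
#' @examples
#' gm <- simGenotypes(50, 100, seed = 1)
#' cm <- emptyClassMap(gm)
#' sim <- simEffectsAndPhenotypes(gm, cm,
#'          classPi = list(other = c(0.9, 0, 0, 0.1)),
#'          h2Target = 0.5, seed = 2)
#' sim$truth$h2Realized
#' @export
simEffectsAndPhenotypes <- function(geno, classMap = emptyClassMap(geno),
                                    classPi = list(other = c(0.95, 0, 0, 0.05)),
                                    h2Target = 0.6,
                                    reliabilityRange = c(0.7, 0.99),
                                    seed = 1) {
  stopifnot2(h2Target > 0 && h2Target < 1, "h2Target must lie in (0, 1)")
  stopifnot2(all(vapply(classPi, length, 1L) == 4L),
             "each mixture must have four proportions")
  for (pi in classPi)
    stopifnot2(abs(sum(pi) - 1) < 1e-8 && all(pi >= 0),
               "mixture proportions must be nonnegative and sum to 1")
  members <- classMembers(classMap)
  stopifnot2(all(names(classPi) %in% names(members)),
             "classPi refers to classes absent from classMap")

  gamma <- c(0, 0.01, 0.1, 1)
  ids <- variantIds(geno)
  m <- length(ids)
  n <- nSamples(geno)

  withSeed(seed, {
    # highest-priority listed class wins for variants in several classes
    classOf <- rep("other", m)
    names(classOf) <- ids
    for (nm in rev(setdiff(names(members), "other")))
      classOf[members[[nm]]] <- nm

    comp <- integer(m)
    for (nm in unique(classOf)) {
      pi <- classPi[[nm]]
      if (is.null(pi)) pi <- c(1, 0, 0, 0)
      idx <- which(classOf == nm)
      comp[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = pi)
    }
    beta <- rnorm(m, 0, sqrt(gamma[comp]))  # sigma2_beta = 1; rescaled below

    Z <- scale(dosages(geno), center = TRUE, scale = FALSE)
    g <- drop(Z %*% beta)

    rel <- runif(n, reliabilityRange[1], reliabilityRange[2])
    if (stats::var(g) > 0) {
      # rescale g so that var(g) / var(y) = h2Target exactly in-sample:
      # noise is made empirically orthogonal to g and unit-variance first
      e <- rnorm(n, 0, 1) / sqrt(rel)
      e <- e - g * stats::cov(e, g) / stats::var(g)
      e <- e / stats::sd(e)
      s <- sqrt(h2Target / (1 - h2Target)) / stats::sd(g)
      g <- g * s
      beta <- beta * s
      y <- g + e
    } else {
      e <- rnorm(n, 0, 1) / sqrt(rel)
      y <- g + e
    }

    h2r <- stats::var(g) / stats::var(y)
    ph <- data.frame(animal_id = sampleIds(geno), dpta = y,
                     reliability = rel, stringsAsFactors = FALSE)
    list(truth = list(effects = stats::setNames(beta, ids),
                      componentOf = stats::setNames(comp, ids),
                      classOfEffect = classOf,
                      geneticValues = stats::setNames(g, sampleIds(geno)),
                      h2Realized = h2r),
         phenotypes = ph)
  })
}

#' An empty functional-class map
#'
#' Every variant falls in the designated \code{"other"} complement class.
#' @param geno a \linkS4class{GenotypeMatrix}
#' @return a \linkS4class{FunctionalClassMap} with no functional classes.
#' @export
emptyClassMap <- function(geno) {
  new("FunctionalClassMap", classes = list(), other = variantIds(geno),
      provenance = list())
}
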