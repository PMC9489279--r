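#' Chain settings for the MCMC sampler
#'
#' Defaults are desk-scale (50 000 iterations, 10 000 burn-in, thinning 20,
#' giving 2000 stored draws); production-scale settings of any size are
#' accepted. The stored sample count is
#' \code{floor((niter - burnin) / thin)}.
#'
#' @param niter total iterations
#' @param burnin iterations discarded before storage
#' @param thin storage interval
#' @param seed RNG seed (R's RNG drives the whole chain)
#' @return validated list of settings
#' @export
chainSettings <- function(niter = 50000, burnin = 10000, thin = 20, seed = 1) {
  stopifnot(burnin < niter, thin >= 1, niter > 0, burnin >= 0)
  list(niter = as.integer(niter), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed))
}

#' Prior specification for the phylogenetic mixed model
#'
#' Fixed effects get independent normal(0, \code{fixedVar}) priors. Each
#' random-effect variance gets the parameter-expanded prior defined by a
#' base inverse-Wishart (scalar inverse-gamma) with \code{(peV, peNu)} on
#' the working variance and a normal(\code{peAlphaMu}, \code{peAlphaV})
#' prior on the redundant working scale, which together induce a scaled-F
#' marginal prior on the effective variance. The residual variance gets a
#' scalar inverse-Wishart with \code{(residV, residNu)}.
#'
#' @param fixedVar prior variance of fixed effects (default 1e8)
#' @param peV,peNu base inverse-Wishart V and nu for expanded terms
#'   (defaults 1, 1)
#' @param peAlphaMu,peAlphaV working-scale prior mean and variance
#'   (defaults 0, 1000)
#' @param residV,residNu residual inverse-Wishart V and nu
#'   (defaults 1, 0.002)
#' @return list of hyperparameters
#' @export
pmmPrior <- function(fixedVar = 1e8, peV = 1, peNu = 1,
                     peAlphaMu = 0, peAlphaV = 1000,
                     residV = 1, residNu = 0.002) {
  vals <- c(fixedVar, peV, peNu, peAlphaV, residV, residNu)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  list(fixedVar = fixedVar, peV = peV, peNu = peNu,
       peAlphaMu = peAlphaMu, peAlphaV = peAlphaV,
       residV = residV, residNu = residNu)
}

#' Build the design bundle for a phylogenetic mixed model
#'
#' Assembles the fixed-effect design matrix (intercept first, then the
#' requested covariate columns), one incidence matrix per random term, and
#' the covariance structure of each term: the MRCA-depth matrix \eqn{A} for
#' the \code{"phylo"} term, identity for \code{"species"} and
#' \code{"strain"}.
#'
#' @param data observation table with columns \code{species}, \code{strain},
#'   the response column(s) and any covariate columns named in \code{fixed}
#' @param fixed character vector of covariate column names (the intercept is
#'   always included and need not be listed)
#' @param random subset of \code{c("phylo", "species", "strain")}
#' @param rel a [RelatednessStructure-class]; required when \code{"phylo"}
#'   or \code{"species"} is in \code{random} or when any check against the
#'   tree is wanted
#' @param family \code{"binomial"} or \code{"gaussian"}
#' @param response for binomial, length-2 character vector naming the count
#'   and trial columns (default \code{c("n_infected", "n_replicates")}); for
#'   gaussian, one column name (default \code{"score"})
#' @return design bundle (list) consumed by [fitPMM()]
#' @export
buildDesign <- function(data, fixed = character(), random = "species", rel,
                        family = c("binomial", "gaussian"),
                        response = NULL) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  stopifnot(all(c("species", "strain") %in% names(data)))
  random <- unique(random)
  bad <- setdiff(random, c("phylo", "species", "strain"))
  if (length(bad)) stop("unknown random term(s): ", paste(bad, collapse = ", "))

  if (!missing(rel) && !is.null(rel)) {
    off_tree <- setdiff(unique(data$species), taxonOrder(rel))
    if (length(off_tree))
      stop("species not on the tree (prune the data first): ",
           paste(off_tree, collapse = ", "))
  } else if (any(c("phylo") %in% random)) {
    stop("a RelatednessStructure is required for the phylo term")
  }

  if (is.null(response))
    response <- if (family == "binomial") c("n_infected", "n_replicates")
                else "score"
  miss <- setdiff(c(fixed, response), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  n <- nrow(data)
  X <- cbind(intercept = rep(1, n))
  for (f in fixed) {
    v <- as.numeric(data[[f]])
    if (anyNA(v) || any(!is.finite(v)))
      stop("covariate '", f, "' has missing or non-finite values")
    if (stats::var(v) == 0)
      warning("covariate '", f, "' has zero variance")
    X <- cbind(X, v)
  }
  colnames(X) <- c("intercept", fixed)

  incidence <- function(fac, levels) {
    Zi <- matrix(0, n, length(levels),
                 dimnames = list(NULL, levels))
    Zi[cbind(seq_len(n), match(fac, levels))] <- 1
    Zi
  }
  Zs <- list(); Ginv <- list()
  for (term in random) {
    if (term == "phylo") {
      lev <- taxonOrder(rel)
      Zs[[term]] <- incidence(data$species, lev)
      Ginv[[term]] <- relInverse(rel)
    } else if (term == "species") {
      lev <- unique(data$species)
      Zs[[term]] <- incidence(data$species, lev)
      Ginv[[term]] <- diag(length(lev))
    } else {
      lev <- unique(data$strain)
      Zs[[term]] <- incidence(data$strain, lev)
      Ginv[[term]] <- diag(length(lev))
    }
  }

  if (family == "binomial") {
    k <- as.numeric(data[[response[1]]])
    ntr <- as.numeric(data[[response[2]]])
    if (any(ntr < 1)) stop("binomial trials must be >= 1")
    if (any(k < 0 | k > ntr)) stop("counts must lie in [0, trials]")
    y <- k
  } else {
    y <- as.numeric(data[[response[1]]])
    if (anyNA(y)) stop("gaussian response has missing values")
    ntr <- numeric(0)
  }

  list(X = X, Z = if (length(Zs)) do.call(cbind, Zs) else matrix(0, n, 0),
       term_sizes = vapply(Zs, ncol, integer(1)),
       term_names = names(Zs), Ginv = Ginv,
       y = y, ntrials = ntr, family = family,
       fixed = c("intercept", fixed), random = random, data = data)
}

#' Fit a Bayesian phylogenetic mixed model by MCMC
#'
#' Liability model \eqn{\ell = X\beta + \sum_t Z_t u_t + e} with
#' \eqn{u_{phylo} \sim N(0, \sigma^2_p A)}, identity-covariance species and
#' strain effects, and \eqn{e \sim N(0, \sigma^2_e I)}. For a Gaussian
#' response the liability is observed; for a binomial response
#' \eqn{y_i \sim \mathrm{Binom}(n_i, \mathrm{logit}^{-1}(\ell_i))} and the
#' liabilities are latent, updated by per-observation Metropolis steps with
#' adaptive proposals targeting 0.44 acceptance. Location effects are drawn
#' jointly by conjugate Gibbs using the dense inverse of \eqn{A}; variance
#' components use the redundant multiplicative parameter expansion of
#' [pmmPrior()].
#'
#' @inheritParams buildDesign
#' @param prior a [pmmPrior()] list
#' @param chain a [chainSettings()] list
#' @param fixResidual if a positive number, the residual variance is held
#'   fixed at that value instead of being sampled (used e.g. to compare the
#'   Gaussian sampler against the closed-form conjugate posterior)
#' @param design optionally, a pre-built bundle from [buildDesign()]
#'   (then \code{data}, \code{fixed}, \code{random}, \code{rel},
#'   \code{family}, \code{response} are ignored)
#' @return a [PmmFit-class] object
#' @export
fitPMM <- function(data, fixed = character(), random = "species", rel = NULL,
                   family = c("binomial", "gaussian"), response = NULL,
                   prior = pmmPrior(), chain = chainSettings(),
                   fixResidual = NA, design = NULL) {
  if (is.null(design))
    design <- buildDesign(data, fixed = fixed, random = random, rel = rel,
                          family = family, response = response)
  fam_code <- if (design$family == "binomial") 1L else 0L
  set.seed(chain$seed)
  raw <- .pmm_sampler_cpp(
    y = design$y, ntrials = design$ntrials, family = fam_code,
    X = design$X, Z = design$Z,
    term_sizes = as.integer(design$term_sizes),
    Ginv_list = unname(design$Ginv),
    fixed_var = prior$fixedVar,
    pe_nu = prior$peNu, pe_V = prior$peV,
    pe_alpha_mu = prior$peAlphaMu, pe_alpha_V = prior$peAlphaV,
    resid_nu = prior$residNu, resid_V = prior$residV,
    fix_resid = if (is.na(fixResidual)) -1 else fixResidual,
    niter = chain$niter, burnin = chain$burnin, thin = chain$thin,
    step_init = 1)

  colnames(raw$beta) <- design$fixed
  if (ncol(raw$sigma2)) colnames(raw$sigma2) <- design$term_names
  samples <- list(beta = raw$beta, sigma2 = raw$sigma2,
                  sigma2_e = as.numeric(raw$sigma2_e),
                  deviance = as.numeric(raw$deviance),
                  liability = raw$liability, fitted = raw$fitted,
                  accept_rate = raw$accept_rate)

  summ <- .pmm_summary(samples, design)
  dic <- .pmm_dic(samples, design)
  diagnostics <- .pmm_diagnostics(samples)
  new("PmmFit", samples = samples, design = design, summary = summ,
      dic = dic, settings = chain, diagnostics = diagnostics)
}

#' Highest-posterior-density interval of a set of draws
#'
#' Shortest interval containing a fraction \code{prob} of the sorted draws.
#'
#' @param draws numeric vector of posterior draws
#' @param prob coverage (default 0.95)
#' @return c(lower, upper)
#' @export
hpdInterval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  S <- length(x)
  m <- max(1, min(S, round(prob * S)))
  if (m == S) return(c(lower = x[1], upper = x[S]))
  widths <- x[m:S] - x[1:(S - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' MCMC two-sided tail probability for a fixed effect
#'
#' \code{2 * max(1, min(#draws > 0, #draws < 0)) / S}, capped at 1; by
#' convention never exactly zero.
#'
#' @param draws numeric vector of posterior draws
#' @return pMCMC in (0, 1]
#' @export
pMCMC <- function(draws) {
  S <- length(draws)
  if (!S) stop("no draws")
  min(1, 2 * max(1, min(sum(draws > 0), sum(draws < 0))) / S)
}

.pmm_summary <- function(samples, design, level = 0.95) {
  S <- nrow(samples$beta)
  if (S < 100) stop("need at least 100 stored draws to summarize")
  rows <- list()
  for (j in seq_len(ncol(samples$beta))) {
    d <- samples$beta[, j]
    h <- hpdInterval(d, level)
    rows[[length(rows) + 1]] <- data.frame(
      term = colnames(samples$beta)[j], kind = "fixed",
      post_mean = mean(d), ci_low = h[1], ci_high = h[2], pMCMC = pMCMC(d))
  }
  vc <- cbind(samples$sigma2, residual = samples$sigma2_e)
  for (j in seq_len(ncol(vc))) {
    d <- vc[, j]
    h <- hpdInterval(d, level)
    rows[[length(rows) + 1]] <- data.frame(
      term = colnames(vc)[j], kind = "variance",
      post_mean = mean(d), ci_low = h[1], ci_high = h[2], pMCMC = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of a fitted model
#'
#' Posterior mean, 95% highest-posterior-density interval and (for fixed
#' effects) pMCMC per parameter.
#'
#' @param fit a [PmmFit-class]
#' @param level credible level (default 0.95)
#' @return data.frame with one row per parameter
#' @export
summarizeFit <- function(fit, level = 0.95) {
  .pmm_summary(posteriorSamples(fit), fit@design, level)
}

.softplus <- function(x) ifelse(x > 35, x, log1p(exp(pmax(x, -700))))

.pmm_dic <- function(samples, design) {
  S <- length(samples$deviance)
  if (S < 2) stop("need at least 2 stored draws for DIC")
  Dbar <- mean(samples$deviance)
  if (design$family == "binomial") {
    lbar <- colMeans(samples$liability)
    k <- design$y; ntr <- design$ntrials
    Dhat <- -2 * sum(lchoose(ntr, k) + k * lbar - ntr * .softplus(lbar))
  } else {
    fbar <- colMeans(samples$fitted)
    s2bar <- mean(samples$sigma2_e)
    Dhat <- -2 * sum(stats::dnorm(design$y, fbar, sqrt(s2bar), log = TRUE))
  }
  2 * Dbar - Dhat
}

#' Deviance information criterion of a fitted model
#'
#' Conditional-deviance DIC: \code{DIC = mean(D) + pD} with
#' \code{pD = mean(D) - D(theta_bar)}, where the plug-in point is the
#' posterior mean of the latent liabilities (binomial) or of the fitted
#' values and residual variance (Gaussian).
#'
#' @param fit a [PmmFit-class]
#' @return the DIC (a scalar)
#' @export
computeDic <- function(fit) .pmm_dic(posteriorSamples(fit), fit@design)

#' Write posterior draws as tidy TSV
#'
#' One row per stored draw, one column per parameter (fixed effects, then
#' variance components with the residual last, then the deviance).
#'
#' @param fit a [PmmFit-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writePosteriorDraws <- function(fit, path) {
  s <- posteriorSamples(fit)
  vc <- s$sigma2
  if (ncol(vc)) colnames(vc) <- paste0("sigma2_", colnames(vc))
  df <- data.frame(draw = seq_len(nrow(s$beta)), s$beta, vc,
                   sigma2_residual = s$sigma2_e, deviance = s$deviance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pmm_diagnostics <- function(samples) {
  pars <- cbind(samples$beta, samples$sigma2, residual = samples$sigma2_e)
  out <- do.call(rbind, lapply(seq_len(ncol(pars)), function(j) {
    hw <- heidelbergerWelch(pars[, j])
    data.frame(term = colnames(pars)[j], passed = hw$passed,
               retained_fraction = hw$retainedFraction, p_value = hw$pvalue)
  }))
  rownames(out) <- NULL
  out
}
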