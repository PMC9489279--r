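#' @import methods
NULL

#' Phylogenetic relatedness structure
#'
#' Holds the species-level relatedness matrix \eqn{A} derived from an
#' ultrametric phylogeny, where \eqn{A[i,j]} is the depth (distance from the
#' root) of the most recent common ancestor of tips \eqn{i} and \eqn{j} —
#' the trait covariance structure implied by Brownian motion on the tree —
#' together with its dense inverse and the tree height \eqn{H}.
#'
#' On an ultrametric tree the diagonal of \eqn{A} equals \eqn{H} and the
#' cophenetic distance between tips obeys \eqn{d(i,j) = 2(H - A[i,j])}.
#'
#' @slot taxa ordered tip labels (rows/columns of \code{A})
#' @slot A symmetric positive-definite MRCA-depth matrix
#' @slot Ainv dense inverse of \code{A}
#' @slot height tree height \eqn{H} (branch-length units)
#'
#' @seealso [relatednessMatrix()] which constructs the object from a tree.
#' @export
setClass("RelatednessStructure",
  representation(
    taxa = "character",
    A = "matrix",
    Ainv = "matrix",
    height = "numeric"
  )
)

setValidity("RelatednessStructure", function(object) {
  msg <- character()
  n <- length(object@taxa)
  if (anyDuplicated(object@taxa)) msg <- c(msg, "taxa must be unique")
  if (!all(dim(object@A) == n) || !all(dim(object@Ainv) == n))
    msg <- c(msg, "A and Ainv must be square with one row per taxon")
  if (n > 0) {
    if (max(abs(object@A - t(object@A))) > 1e-8 * max(1, object@height))
      msg <- c(msg, "A must be symmetric")
    if (max(abs(diag(object@A) - object@height)) > 1e-6 * max(1, object@height))
      msg <- c(msg, "diagonal of A must equal the tree height (ultrametric)")
    resid <- max(abs(object@A %*% object@Ainv - diag(n)))
    if (resid > 1e-6) msg <- c(msg, sprintf(
      "A %%*%% Ainv deviates from identity (max residual %.2e)", resid))
  }
  if (length(msg)) msg else TRUE
})

#' Long-format qPCR Ct table
#'
#' One row per qPCR measurement, carrying the strain, species, experimental
#' block, replicate index, sample role and Ct value. Non-detections are kept
#' as \code{NA} and only imputed (to \code{undetectedCt}, by default 40
#' cycles) inside operations that need a numeric value. Roles follow the
#' plate design of the susceptibility assays: experimental samples, a
#' water-exposed negative control, two positive controls of known-susceptible
#' \emph{C. elegans} strains, and two virus-only benchmarks used for
#' thresholding.
#'
#' @slot records data.frame with columns strain, species, block, replicate,
#'   role, ct (NA = undetected)
#' @slot undetectedCt Ct value imputed for non-detections where an operation
#'   requires a number (default 40)
#'
#' @seealso [readCtTable()], [deriveThreshold()], [callSusceptibility()]
#' @export
setClass("CtTable",
  representation(records = "data.frame", undetectedCt = "numeric")
)

.ct_roles <- c("experimental", "control1_neg", "control2_N2",
               "control3_JU1580", "benchmark4", "benchmark5")

setValidity("CtTable", function(object) {
  rec <- object@records
  msg <- character()
  need <- c("strain", "species", "block", "replicate", "role", "ct")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(rec$role), .ct_roles)
  if (length(bad))
    msg <- c(msg, paste("unknown role(s):", paste(bad, collapse = ", ")))
  ct <- rec$ct[!is.na(rec$ct)]
  if (length(ct) && (any(ct <= 0) || any(ct > 40)))
    msg <- c(msg, "detected ct values must lie in (0, 40]")
  key <- paste(rec$strain, rec$block, rec$replicate, rec$role)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (strain, block, replicate, role) records")
  if (length(object@undetectedCt) != 1 || object@undetectedCt <= 0)
    msg <- c(msg, "undetectedCt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Fitted phylogenetic mixed model
#'
#' Container for one MCMC fit: stored posterior draws, the design it was fit
#' to, per-term posterior summaries, DIC and convergence diagnostics.
#'
#' @slot samples list of draw matrices: \code{beta} (stored draws x fixed
#'   terms), \code{sigma2} (draws x variance components, residual last),
#'   \code{deviance} (vector), \code{liability} (draws x observations;
#'   binomial fits only)
#' @slot design the design bundle from [buildDesign()]
#' @slot summary data.frame of per-parameter posterior mean, 95\% HPD
#'   interval and pMCMC (fixed effects only)
#' @slot dic deviance information criterion (conditional deviance)
#' @slot settings chain settings used (iterations, burn-in, thin, seed)
#' @slot diagnostics per-parameter stationarity verdicts
#' @export
setClass("PmmFit",
  representation(
    samples = "list",
    design = "list",
    summary = "data.frame",
    dic = "numeric",
    settings = "list",
    diagnostics = "data.frame"
  )
)

#' DIC model-weight table
#'
#' Per-model \eqn{\Delta}DIC and normalized evidence weights
#' \eqn{w_m = e^{-\Delta_m/2} / \sum_j e^{-\Delta_j/2}}, with the term sets
#' defining each model retained so component weights can be computed by
#' formula membership rather than name matching on fitted parameters.
#'
#' @slot table data.frame with columns model_id, delta, weight (and dic when
#'   absolute DICs were supplied)
#' @slot formulas named list: per model, a list with character vectors
#'   \code{fixed} and \code{random}
#' @export
setClass("DicWeightTable",
  representation(table = "data.frame", formulas = "list")
)

setValidity("DicWeightTable", function(object) {
  tab <- object@table
  msg <- character()
  if (!all(c("model_id", "delta", "weight") %in% names(tab)))
    return("table needs columns model_id, delta, weight")
  if (anyDuplicated(tab$model_id)) msg <- c(msg, "model ids must be unique")
  if (nrow(tab)) {
    if (abs(min(tab$delta)) > 1e-12) msg <- c(msg, "min delta must be 0")
    if (abs(sum(tab$weight) - 1) > 1e-12) msg <- c(msg, "weights must sum to 1")
    if (any(tab$weight <= 0 | tab$weight > 1))
      msg <- c(msg, "weights must lie in (0, 1]")
  }
  if (!setequal(names(object@formulas), tab$model_id))
    msg <- c(msg, "formulas must be named by model_id")
  if (length(msg)) msg else TRUE
})
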