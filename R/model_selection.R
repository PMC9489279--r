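#' DIC evidence weights for a set of models
#'
#' From per-model DIC values (or pre-computed differences
#' \eqn{\Delta_m = \mathrm{DIC}_m - \min \mathrm{DIC}}), computes the
#' normalized weights \eqn{w_m = e^{-\Delta_m/2} / \sum_j e^{-\Delta_j/2}}.
#' Computation is done in log space so very large \eqn{\Delta} values
#' cannot underflow the normalizer. Only differences matter: adding a
#' constant to every DIC leaves the weights unchanged.
#'
#' @param dic numeric vector of absolute DIC values (one per model); supply
#'   either this or \code{delta}
#' @param delta numeric vector of DIC differences from the best model
#' @param formulas optional named list (one entry per model) of lists with
#'   character vectors \code{fixed} and \code{random}; needed for component
#'   weights
#' @param modelIds model identifiers; defaults to the names of
#'   \code{dic}/\code{delta} or \code{model1, model2, ...}
#' @return a [DicWeightTable-class]
#' @examples
#' wt <- dicWeights(delta = c(0, 1.731, 2.370, 4.368))
#' round(weightTable(wt)$weight, 3)  # 0.544 0.229 0.166 0.061
#' @export
dicWeights <- function(dic = NULL, delta = NULL, formulas = NULL,
                       modelIds = NULL) {
  if (is.null(dic) == is.null(delta))
    stop("supply exactly one of `dic` or `delta`")
  vals <- if (is.null(dic)) delta else dic
  if (!length(vals)) stop("empty model set")
  if (any(!is.finite(vals))) stop("DIC values must be finite")
  if (is.null(modelIds))
    modelIds <- if (!is.null(names(vals))) names(vals)
                else paste0("model", seq_along(vals))
  if (anyDuplicated(modelIds)) stop("model ids must be unique")
  d <- vals - min(vals)
  logw <- -d / 2
  w <- exp(logw - (max(logw) + log(sum(exp(logw - max(logw))))))
  if (is.null(formulas)) {
    formulas <- rep(list(list(fixed = character(), random = character())),
                    length(vals))
    names(formulas) <- modelIds
  } else {
    if (length(formulas) != length(vals))
      stop("formulas must have one entry per model")
    names(formulas) <- modelIds
    sig <- vapply(formulas, function(f)
      paste(paste(sort(f$fixed), collapse = "+"),
            paste(sort(f$random), collapse = "+"), sep = "|"),
      character(1))
    if (anyDuplicated(sig)) stop("model formulas must be distinct")
  }
  tab <- data.frame(model_id = modelIds, delta = d, weight = w)
  if (!is.null(dic)) tab$dic <- dic
  new("DicWeightTable", table = tab, formulas = formulas)
}

.component_members <- function(wt, component) {
  forms <- modelFormulas(wt)
  known <- unique(unlist(lapply(forms, function(f) c(f$fixed, f$random))))
  if (!component %in% known)
    stop("unknown component '", component, "'; known terms: ",
         paste(known, collapse = ", "))
  vapply(forms, function(f) component %in% c(f$fixed, f$random), logical(1))
}

#' DIC weight of a model component
#'
#' Sum of the weights of all models whose formula contains the component —
#' the posterior probability that the component belongs in the true model,
#' given that the true model is in the set. Membership is decided from the
#' stored formula descriptors, not by matching fitted parameter names.
#'
#' @param wt a [DicWeightTable-class] built with formulas
#' @param component a term label (fixed or random)
#' @return the summed weight in [0, 1]
#' @export
componentWeight <- function(wt, component) {
  members <- .component_members(wt, component)
  sum(weightTable(wt)$weight[members])
}

#' Combined DIC weight of models containing any of several components
#'
#' Sum of the weights of models whose formula contains at least one of the
#' listed components (e.g. "either phylogenetic effect").
#'
#' @param wt a [DicWeightTable-class] built with formulas
#' @param components non-empty character vector of term labels
#' @return the summed weight in [0, 1]
#' @export
anyComponentWeight <- function(wt, components) {
  if (!length(components)) stop("components must be non-empty")
  members <- Reduce(`|`, lapply(components, .component_members, wt = wt))
  sum(weightTable(wt)$weight[members])
}

#' Posterior variance decomposition (component R-squared) of a fitted model
#'
#' For each stored draw, the variance explained by each model component is
#' computed: for a fixed-effect covariate, the population variance (divisor
#' \eqn{n}) of its contribution \eqn{x_j \beta_j} over the observed design
#' rows; for each random term, its sampled variance component; plus the
#' residual variance. Each component's share of the total is recorded per
#' draw, so shares sum to exactly 1 within every draw and the share of a
#' set of components is the sum of their shares. The intercept contributes
#' no variance and is omitted. Reported are the posterior mean and a 95%
#' HPD interval of each share.
#'
#' @param fit a [PmmFit-class]
#' @param level credible level for the interval (default 0.95)
#' @return list with \code{summary} (data.frame: component, r2_mean,
#'   ci_low, ci_high) and \code{draws} (matrix of per-draw shares, one
#'   column per component including residual)
#' @export
rSquaredComponents <- function(fit, level = 0.95) {
  samples <- posteriorSamples(fit)
  design <- fit@design
  S <- nrow(samples$beta)
  fixed <- setdiff(design$fixed, "intercept")
  comp <- matrix(0, S, 0)
  for (f in fixed) {
    x <- design$X[, f]
    contrib <- outer(samples$beta[, f], x)           # S x n
    v <- apply(contrib, 1, function(r) mean((r - mean(r))^2))
    comp <- cbind(comp, v)
  }
  if (length(design$term_names))
    comp <- cbind(comp, samples$sigma2)
  comp <- cbind(comp, samples$sigma2_e)
  colnames(comp) <- c(fixed, design$term_names, "residual")
  total <- rowSums(comp)
  ok <- total > 0
  if (!all(ok))
    warning(sum(!ok), " draw(s) with zero total variance skipped")
  shares <- comp[ok, , drop = FALSE] / total[ok]
  summ <- do.call(rbind, lapply(colnames(shares), function(cn) {
    h <- hpdInterval(shares[, cn], level)
    data.frame(component = cn, r2_mean = mean(shares[, cn]),
               ci_low = h[1], ci_high = h[2])
  }))
  rownames(summ) <- NULL
  list(summary = summ, draws = shares)
}
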