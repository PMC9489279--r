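#' @rdname RelatednessStructure-class
#' @param object,x a \code{RelatednessStructure}
#' @export
setGeneric("taxonOrder", function(x) standardGeneric("taxonOrder"))

#' @rdname RelatednessStructure-class
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' @rdname RelatednessStructure-class
#' @export
setGeneric("relInverse", function(x) standardGeneric("relInverse"))

#' @rdname RelatednessStructure-class
#' @export
setGeneric("treeHeight", function(x) standardGeneric("treeHeight"))

#' @rdname CtTable-class
#' @export
setGeneric("ctRecords", function(x) standardGeneric("ctRecords"))

#' @rdname CtTable-class
#' @export
setGeneric("undetectedCt", function(x) standardGeneric("undetectedCt"))

#' @rdname PmmFit-class
#' @export
setGeneric("dic", function(x) standardGeneric("dic"))

#' @rdname PmmFit-class
#' @export
setGeneric("posteriorSamples", function(x) standardGeneric("posteriorSamples"))

#' @rdname PmmFit-class
#' @export
setGeneric("fitSummary", function(x) standardGeneric("fitSummary"))

#' @rdname DicWeightTable-class
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))

#' @rdname DicWeightTable-class
#' @export
setGeneric("modelFormulas", function(x) standardGeneric("modelFormulas"))

setMethod("taxonOrder", "RelatednessStructure", function(x) x@taxa)
setMethod("relMatrix", "RelatednessStructure", function(x) x@A)
setMethod("relInverse", "RelatednessStructure", function(x) x@Ainv)
setMethod("treeHeight", "RelatednessStructure", function(x) x@height)

setMethod("show", "RelatednessStructure", function(object) {
  cat(sprintf(
    "RelatednessStructure: %d taxa, tree height %.4g\n",
    length(object@taxa), object@height))
  cat("  taxa:", paste(utils::head(object@taxa, 5), collapse = ", "),
      if (length(object@taxa) > 5) "..." else "", "\n")
})

setMethod("ctRecords", "CtTable", function(x) x@records)
setMethod("undetectedCt", "CtTable", function(x) x@undetectedCt)

setMethod("show", "CtTable", function(object) {
  rec <- object@records
  cat(sprintf("CtTable: %d records, %d strains, %d block(s)\n",
              nrow(rec), length(unique(rec$strain)),
              length(unique(rec$block))))
  cat(sprintf("  undetected: %d record(s), imputed to Ct %.1f on demand\n",
              sum(is.na(rec$ct)), object@undetectedCt))
  tab <- table(rec$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("dic", "PmmFit", function(x) x@dic)
setMethod("posteriorSamples", "PmmFit", function(x) x@samples)
setMethod("fitSummary", "PmmFit", function(x) x@summary)

setMethod("show", "PmmFit", function(object) {
  cat(sprintf("PmmFit (%s response): %d stored draws, DIC = %.3f\n",
              object@design$family,
              nrow(object@samples$beta), object@dic))
  print(object@summary, digits = 4)
})

setMethod("weightTable", "DicWeightTable", function(x) x@table)
setMethod("modelFormulas", "DicWeightTable", function(x) x@formulas)

setMethod("show", "DicWeightTable", function(object) {
  cat(sprintf("DicWeightTable: %d models\n", nrow(object@table)))
  tab <- object@table
  tab$delta <- round(tab$delta, 3)
  tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
})
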