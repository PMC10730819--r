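#' Accessor generics
#'
#' Small accessor family shared by the result classes: `snpIds()` returns the
#' SNP identifiers carried by a container, `estimate()` the point estimate,
#' `stdError()` its standard error, `confInt()` the 95\% interval as a
#' length-2 numeric, `pvalue()` the two-sided p, and `nSNPs()` the number of
#' instruments behind an estimate.
#'
#' @param object an object of one of the package's S4 classes.
#' @return the corresponding slot value (see class documentation).
#' @name accessors
#' @aliases snpIds estimate stdError confInt pvalue nSNPs
#' @examples
#' e <- waldRatio(0.05, 0.01, 0.10)
#' estimate(e); stdError(e); confInt(e)
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("pvalue", function(object) standardGeneric("pvalue"))

#' @rdname accessors
#' @export
setGeneric("nSNPs", function(object) standardGeneric("nSNPs"))

#' @rdname accessors
#' @export
setMethod("snpIds", "SummaryStats", function(object) object@data$SNP)

#' @rdname accessors
#' @export
setMethod("snpIds", "HarmonizedSet", function(object) object@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "LDMatrix", function(object) object@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "MVHarmonizedSet", function(object) object@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "InstrumentSelection", function(object) object@selectedIds)

#' @rdname accessors
#' @export
setMethod("estimate", "MREstimate", function(object) object@beta)

#' @rdname accessors
#' @export
setMethod("stdError", "MREstimate", function(object) object@se)

#' @rdname accessors
#' @export
setMethod("confInt", "MREstimate",
          function(object) c(object@ciLow, object@ciHigh))

#' @rdname accessors
#' @export
setMethod("pvalue", "MREstimate", function(object) object@pval)

#' @rdname accessors
#' @export
setMethod("nSNPs", "MREstimate", function(object) object@nSNPs)

#' @rdname accessors
#' @export
setMethod("nSNPs", "HarmonizedSet", function(object) length(object@snpIds))

#' @rdname accessors
#' @export
setMethod("estimate", "MediationResult", function(object) object@indirectBeta)

#' @rdname accessors
#' @export
setMethod("stdError", "MediationResult", function(object) object@indirectSE)

#' @rdname accessors
#' @export
setMethod("confInt", "MediationResult",
          function(object) c(object@indirectCiLow, object@indirectCiHigh))

#' @rdname accessors
#' @export
setMethod("pvalue", "MediationResult", function(object) object@indirectPval)
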