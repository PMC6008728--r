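#' @rdname accessors
#' @name accessors
#' @title Accessors for confex result objects
#' @description Generic accessors for the exchange-parameter, fit, Markov
#'   model and TPT classes: \code{exchangeRate} (kex, 1/s),
#'   \code{minorPopulation} (pE), \code{shiftDifferences} (ppm),
#'   \code{intrinsicRates} (R2,0), \code{lagTime}, \code{transitionMatrix},
#'   \code{stationaryDistribution}, \code{timescales}, \code{activeStates}
#'   (0-based ids), \code{forwardCommittor}, \code{backwardCommittor},
#'   \code{netFluxMatrix}, \code{totalFlux}, \code{pathways},
#'   \code{macroAssignment}.
#' @param x an object of the respective class.
NULL

#' @rdname accessors
#' @export
setGeneric("exchangeRate", function(x) standardGeneric("exchangeRate"))
#' @rdname accessors
#' @export
setGeneric("minorPopulation", function(x) standardGeneric("minorPopulation"))
#' @rdname accessors
#' @export
setGeneric("shiftDifferences", function(x) standardGeneric("shiftDifferences"))
#' @rdname accessors
#' @export
setGeneric("intrinsicRates", function(x) standardGeneric("intrinsicRates"))

#' @rdname accessors
setMethod("exchangeRate", "ExchangeParams", function(x) x@kex)
#' @rdname accessors
setMethod("exchangeRate", "TwoStateFit", function(x) x@kex)
#' @rdname accessors
setMethod("minorPopulation", "ExchangeParams", function(x) x@pE)
#' @rdname accessors
setMethod("minorPopulation", "TwoStateFit", function(x) x@pE)
#' @rdname accessors
setMethod("shiftDifferences", "ExchangeParams", function(x) x@dwPpm)
#' @rdname accessors
setMethod("shiftDifferences", "TwoStateFit", function(x) x@dwPpm)
#' @rdname accessors
setMethod("intrinsicRates", "ExchangeParams", function(x) x@r20)
#' @rdname accessors
setMethod("intrinsicRates", "TwoStateFit", function(x) x@r20)

#' @rdname accessors
#' @export
setGeneric("lagTime", function(x) standardGeneric("lagTime"))
#' @rdname accessors
setMethod("lagTime", "MarkovModel", function(x) x@lag)
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
setMethod("transitionMatrix", "MarkovModel", function(x) x@transition)
#' @rdname accessors
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))
#' @rdname accessors
setMethod("stationaryDistribution", "MarkovModel", function(x) x@stationary)
#' @rdname accessors
#' @export
setGeneric("timescales", function(x) standardGeneric("timescales"))
#' @rdname accessors
setMethod("timescales", "MarkovModel", function(x) x@timescales)
#' @rdname accessors
#' @export
setGeneric("activeStates", function(x) standardGeneric("activeStates"))
#' @rdname accessors
setMethod("activeStates", "MarkovModel", function(x) x@active)

#' @rdname accessors
#' @export
setGeneric("forwardCommittor", function(x) standardGeneric("forwardCommittor"))
#' @rdname accessors
setMethod("forwardCommittor", "TptResult", function(x) x@qPlus)
#' @rdname accessors
#' @export
setGeneric("backwardCommittor",
           function(x) standardGeneric("backwardCommittor"))
#' @rdname accessors
setMethod("backwardCommittor", "TptResult", function(x) x@qMinus)
#' @rdname accessors
#' @export
setGeneric("netFluxMatrix", function(x) standardGeneric("netFluxMatrix"))
#' @rdname accessors
setMethod("netFluxMatrix", "TptResult", function(x) x@netFlux)
#' @rdname accessors
#' @export
setGeneric("totalFlux", function(x) standardGeneric("totalFlux"))
#' @rdname accessors
setMethod("totalFlux", "TptResult", function(x) x@totalFlux)
#' @rdname accessors
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))
#' @rdname accessors
setMethod("pathways", "TptResult", function(x) x@pathways)

#' @rdname accessors
#' @export
setGeneric("macroAssignment", function(x) standardGeneric("macroAssignment"))
#' @rdname accessors
setMethod("macroAssignment", "Lumping", function(x) x@assignment)

setMethod("show", "ExchangeParams", function(object) {
    cat("ExchangeParams: kex =", format(object@kex), "1/s, pE =",
        format(object@pE), "\n  nucleus", object@nucleus, "at",
        paste(object@fieldT, collapse = "/"), "T,",
        format(object@tempK), "K;", length(object@dwPpm), "residue(s)\n")
})

setMethod("show", "DispersionExperiment", function(object) {
    pts <- object@points
    np <- nrow(unique(pts[c("residue", "nucleus", "field_T", "temp_K")]))
    cat("DispersionExperiment:", np, "profile(s),", nrow(pts), "points",
        if (!is.null(object@truth)) "(with ground truth)" else "", "\n")
})

setMethod("show", "TwoStateFit", function(object) {
    cat("TwoStateFit: kex =", format(object@kex, digits = 5), "1/s, pE =",
        format(object@pE, digits = 4),
        sprintf("(red. chi^2 = %.3g)\n", object@redChisq))
    if (!object@converged) cat("  WARNING: optimizer did not converge\n")
    if (!object@identifiable)
        cat("  WARNING: exchange parameters unidentifiable (flat profiles)\n")
    cat("  dw (ppm):", paste(names(object@dwPpm),
                             format(object@dwPpm, digits = 3),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "StateTraj", function(object) {
    cat("StateTraj:", length(object@states), "frames, dt =",
        format(object@dt), ",", object@nStates, "states\n")
})

setMethod("show", "MarkovModel", function(object) {
    cat("MarkovModel:", nrow(object@transition), "states at lag",
        format(object@lag),
        if (object@reversible) "(reversible)" else "(non-reversible)", "\n")
    t2 <- object@timescales[2]
    if (is.finite(t2)) cat("  slowest implied timescale:", format(t2), "\n")
    if (length(object@trimmed))
        cat("  trimmed states:", paste(object@trimmed, collapse = ", "), "\n")
})

setMethod("show", "Lumping", function(object) {
    cat("Lumping:", length(object@assignment), "microstates ->",
        object@nMacro, "macrostates\n")
    if (nchar(object@warning)) cat("  warning:", object@warning, "\n")
})

setMethod("show", "TptResult", function(object) {
    cat("TptResult: total A->B flux =", format(object@totalFlux), "\n")
    if (nrow(object@pathways))
        cat("  ", nrow(object@pathways), "pathway(s), top fraction",
            format(object@pathways$fraction[1], digits = 3), "\n")
})
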