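#' Construct a two-state exchange parameter set
#'
#' @param kex exchange rate kBE + kEB (1/s).
#' @param pE minor-state fractional population, in (0, 0.5).
#' @param dwPpm named numeric vector of chemical-shift differences (ppm), one
#'   per residue.
#' @param r20 intrinsic transverse relaxation rate(s) (1/s), one per field
#'   (recycled if a single value is given).
#' @param nucleus "15N" or "1H".
#' @param fieldT static field(s) in tesla.
#' @param tempK temperature in kelvin.
#' @return an \code{\linkS4class{ExchangeParams}} object.
#' @examples
#' exchangeParams(kex = 2000, pE = 0.03,
#'                dwPpm = c(L99 = 2, F114 = 1.2, K135 = 2.8),
#'                r20 = 12, nucleus = "15N", fieldT = 11.7, tempK = 293.55)
#' @export
exchangeParams <- function(kex, pE, dwPpm, r20, nucleus = "15N",
                           fieldT = 11.7, tempK = 298.15) {
    if (is.null(names(dwPpm)))
        names(dwPpm) <- paste0("res", seq_along(dwPpm))
    r20 <- rep_len(r20, length(fieldT))
    names(r20) <- format(fieldT)
    new("ExchangeParams", kex = kex, pE = pE, dwPpm = dwPpm, r20 = r20,
        nucleus = nucleus, fieldT = fieldT, tempK = tempK)
}

#' Simulate a CPMG relaxation dispersion dataset
#'
#' Generates one dispersion profile per residue per field from the numerical
#' Bloch-McConnell forward model (\code{\link{simulateR2effBM}}) and adds
#' homoscedastic Gaussian noise to the R2,eff values. The generating
#' parameters are attached to the returned object so downstream fits can be
#' checked against ground truth.
#'
#' @param truth an \code{\linkS4class{ExchangeParams}} object.
#' @param nu CPMG refocusing frequencies (Hz). Every value must be at least
#'   1/tCpmg and commensurate with tCpmg (an integer number of echo elements).
#' @param tCpmg constant-time relaxation delay (s).
#' @param noiseSd standard deviation of the Gaussian noise on R2,eff (1/s).
#'   The default 0.3 1/s is a package choice: the repeat-measurement errors of
#'   typical amide 15N CPMG data are a few tenths of 1/s.
#' @param seed integer seed; the generator is a pure function of
#'   (truth, nu, tCpmg, noiseSd, seed).
#' @param sigma per-point uncertainty recorded in the dataset. Defaults to
#'   \code{noiseSd} when positive, otherwise 1 (nominal unit weights for
#'   noiseless data).
#' @return a \code{\linkS4class{DispersionExperiment}}.
#' @examples
#' tr <- exchangeParams(2000, 0.03, c(A = 2), r20 = 10, tempK = 293.55)
#' ds <- simulateCpmgDataset(tr, nu = seq(50, 1000, by = 50), tCpmg = 0.02,
#'                           noiseSd = 0.3, seed = 1)
#' @export
simulateCpmgDataset <- function(truth, nu, tCpmg, noiseSd = 0.3, seed,
                                sigma = NULL) {
    stopifnot(is(truth, "ExchangeParams"))
    if (length(nu) == 0) stop("empty nu list")
    if (any(nu < 1 / tCpmg - 1e-9))
        stop("nu below the minimum possible value 1/T_cpmg")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (is.null(sigma)) sigma <- if (noiseSd > 0) noiseSd else 1
    set.seed(as.integer(seed))
    rows <- list()
    for (f in seq_along(truth@fieldT)) {
        for (res in names(truth@dwPpm)) {
            r2 <- simulateR2effBM(kex = truth@kex, pE = truth@pE,
                                  dwPpm = truth@dwPpm[[res]],
                                  r20 = truth@r20[[f]],
                                  nucleus = truth@nucleus,
                                  fieldT = truth@fieldT[f],
                                  nu = nu, tCpmg = tCpmg)
            noise <- if (noiseSd > 0) stats::rnorm(length(nu), 0, noiseSd) else 0
            rows[[length(rows) + 1L]] <- data.frame(
                residue = res, nucleus = truth@nucleus,
                field_T = truth@fieldT[f], temp_K = truth@tempK,
                t_cpmg_s = tCpmg, nu_cpmg_hz = nu,
                r2eff_s1 = r2 + noise, sigma_s1 = sigma,
                stringsAsFactors = FALSE)
        }
    }
    new("DispersionExperiment", points = do.call(rbind, rows), truth = truth)
}

#' Ground truth attached to a synthetic dataset
#'
#' @param x a \code{\linkS4class{DispersionExperiment}}.
#' @return the generating \code{ExchangeParams}, or NULL for measured data.
#' @export
datasetTruth <- function(x) {
    stopifnot(is(x, "DispersionExperiment"))
    x@truth
}

#' Dispersion points of a dataset
#'
#' @param x a \code{\linkS4class{DispersionExperiment}}.
#' @return the underlying data.frame of dispersion points.
#' @export
dispersionPoints <- function(x) {
    stopifnot(is(x, "DispersionExperiment"))
    x@points
}
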