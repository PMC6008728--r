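#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib confex, .registration = TRUE
NULL

#' Two-state exchange parameters
#'
#' Container for the parameters of a two-state (B <-> E) chemical exchange
#' process observed by CPMG relaxation dispersion: the exchange rate
#' \eqn{k_{ex} = k_{BE} + k_{EB}}, the minor-state population \eqn{p_E},
#' per-residue chemical-shift differences \eqn{\Delta\omega} (ppm, shared
#' across static fields), and per-field intrinsic transverse relaxation rates
#' \eqn{R_{2,0}}. Used both as the ground truth handed to
#' \code{\link{simulateCpmgDataset}} and as the parameter block of a fit.
#'
#' @slot kex exchange rate \eqn{k_{BE} + k_{EB}} in 1/s.
#' @slot pE minor-state fractional population, in (0, 0.5) by the minor-state
#'   convention.
#' @slot dwPpm named numeric, chemical-shift difference per residue in ppm.
#' @slot r20 named numeric, intrinsic \eqn{R_{2,0}} (1/s) per field; names are
#'   the field strengths in tesla formatted by \code{format()}.
#' @slot nucleus "15N" or "1H".
#' @slot fieldT spectrometer field(s) in tesla.
#' @slot tempK sample temperature in kelvin.
#' @exportClass ExchangeParams
setClass("ExchangeParams",
    representation(kex = "numeric", pE = "numeric", dwPpm = "numeric",
                   r20 = "numeric", nucleus = "character", fieldT = "numeric",
                   tempK = "numeric"))

setValidity("ExchangeParams", function(object) {
    msg <- character()
    if (length(object@kex) != 1L || !is.finite(object@kex) || object@kex <= 0)
        msg <- c(msg, "kex must be a single positive number")
    if (length(object@pE) != 1L || object@pE <= 0 || object@pE >= 0.5)
        msg <- c(msg, "pE must lie in (0, 0.5) (minor-state convention)")
    if (length(object@dwPpm) < 1L || is.null(names(object@dwPpm)))
        msg <- c(msg, "dwPpm must be a named vector (one entry per residue)")
    if (any(object@dwPpm < 0))
        msg <- c(msg, "dwPpm must be >= 0 (sign is not identifiable by CPMG)")
    if (any(object@r20 < 0)) msg <- c(msg, "r20 must be >= 0")
    if (length(object@r20) != length(object@fieldT))
        msg <- c(msg, "need one r20 per field")
    if (!object@nucleus %in% c("15N", "1H"))
        msg <- c(msg, "nucleus must be '15N' or '1H'")
    if (length(msg)) msg else TRUE
})

#' CPMG relaxation dispersion dataset
#'
#' A set of dispersion profiles: per residue, nucleus, field and temperature,
#' the effective transverse relaxation rate \eqn{R_{2,eff}} measured as a
#' function of the CPMG refocusing frequency \eqn{\nu_{CPMG}}. When the data
#' were generated synthetically the generating \code{ExchangeParams} ride
#' along in the \code{truth} slot so recovery can be tested.
#'
#' @slot points data.frame with columns \code{residue}, \code{nucleus},
#'   \code{field_T}, \code{temp_K}, \code{t_cpmg_s}, \code{nu_cpmg_hz},
#'   \code{r2eff_s1}, \code{sigma_s1}.
#' @slot truth an \code{ExchangeParams} object or \code{NULL}.
#' @exportClass DispersionExperiment
setClass("DispersionExperiment",
    representation(points = "data.frame", truth = "ANY"))

setValidity("DispersionExperiment", function(object) {
    need <- c("residue", "nucleus", "field_T", "temp_K", "t_cpmg_s",
              "nu_cpmg_hz", "r2eff_s1", "sigma_s1")
    pts <- object@points
    msg <- character()
    if (!all(need %in% names(pts)))
        return(paste("points must have columns:", paste(need, collapse = ", ")))
    if (any(pts$nu_cpmg_hz <= 0)) msg <- c(msg, "nu_cpmg_hz must be > 0")
    if (any(pts$sigma_s1 < 0)) msg <- c(msg, "sigma_s1 must be >= 0")
    if (any(pts$nu_cpmg_hz < 1 / pts$t_cpmg_s - 1e-9))
        msg <- c(msg, "nu_cpmg_hz below the minimum 1/T_cpmg")
    pid <- interaction(pts$residue, pts$nucleus, pts$field_T, pts$temp_K,
                       drop = TRUE)
    dup <- vapply(split(pts$nu_cpmg_hz, pid), anyDuplicated, 0L)
    if (any(dup > 0)) msg <- c(msg, "duplicated nu_cpmg_hz within a profile")
    if (!is.null(object@truth) && !is(object@truth, "ExchangeParams"))
        msg <- c(msg, "truth must be NULL or an ExchangeParams")
    if (length(msg)) msg else TRUE
})

#' Global two-state dispersion fit
#'
#' Result of fitting all dispersion profiles of a dataset together to a
#' two-state exchange model: global \eqn{(k_{ex}, p_E)}, one
#' \eqn{\Delta\omega} per residue (shared across fields) and one
#' \eqn{R_{2,0}} per profile.
#'
#' @slot kex fitted exchange rate (1/s).
#' @slot pE fitted minor-state population.
#' @slot dwPpm named numeric, fitted shift differences (ppm) per residue.
#' @slot r20 named numeric, fitted \eqn{R_{2,0}} (1/s) per profile.
#' @slot chisq sum of squared weighted residuals.
#' @slot redChisq chi-square divided by (n points - n parameters).
#' @slot converged logical, optimizer convergence.
#' @slot identifiable logical, FALSE when the exchange contribution of the
#'   best fit is negligible (flat profiles, pE*dw^2 ~ 0).
#' @slot boot list of bootstrap summaries (empty until
#'   \code{\link{bootstrapErrors}} is run).
#' @slot residuals data.frame of per-point weighted residuals.
#' @slot multistart data.frame of chi-square per optimizer start.
#' @exportClass TwoStateFit
setClass("TwoStateFit",
    representation(kex = "numeric", pE = "numeric", dwPpm = "numeric",
                   r20 = "numeric", chisq = "numeric", redChisq = "numeric",
                   converged = "logical", identifiable = "logical",
                   boot = "list", residuals = "data.frame",
                   multistart = "data.frame"))

#' Discrete-state trajectory
#'
#' An ordered sequence of integer microstate ids (0-based, matching the usual
#' MSM state numbering) sampled at a fixed frame interval.
#'
#' @slot states integer vector of 0-based state ids.
#' @slot dt frame interval, in time units (seconds unless stated otherwise).
#' @slot nStates number of states in the underlying model (ids run
#'   0..nStates-1); frames need not visit all of them.
#' @exportClass StateTraj
setClass("StateTraj",
    representation(states = "integer", dt = "numeric", nStates = "integer"))

setValidity("StateTraj", function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (length(object@states) < 1L) msg <- c(msg, "empty trajectory")
    if (any(object@states < 0L) || any(object@states >= object@nStates))
        msg <- c(msg, "state ids must lie in 0..nStates-1")
    if (length(msg)) msg else TRUE
})

#' Continuous-feature trajectory
#'
#' A trajectory in a low-dimensional feature space (here 2D), e.g. from an
#' overdamped Langevin simulation standing in for projected MD coordinates.
#'
#' @slot coords numeric matrix, one row per frame.
#' @slot dt frame interval (time units).
#' @exportClass FeatureTraj
setClass("FeatureTraj",
    representation(coords = "matrix", dt = "numeric"))

#' Markov state model
#'
#' Count matrix, row-stochastic transition matrix, stationary distribution,
#' spectrum and implied timescales estimated at a fixed lag time. States
#' outside the largest strongly connected component of the count graph are
#' trimmed; \code{active} maps matrix rows back to original 0-based ids.
#'
#' @slot lag lag time (time units).
#' @slot lagSteps lag in frames.
#' @slot dt frame interval of the input trajectories.
#' @slot counts count matrix at the lag (active set only).
#' @slot transition row-stochastic transition matrix.
#' @slot reversible logical; TRUE when estimated from symmetrized counts.
#' @slot stationary stationary distribution on the active set.
#' @slot eigenvalues complex eigenvalues sorted by decreasing modulus
#'   (real for reversible estimates; lambda_1 = 1).
#' @slot rightVectors,leftVectors eigenvector matrices (columns).
#' @slot timescales implied timescales t_i = -lag/log(lambda_i), i >= 2;
#'   t_1 is Inf.
#' @slot active integer, original 0-based ids of the active states.
#' @slot trimmed integer, 0-based ids removed by ergodic trimming.
#' @exportClass MarkovModel
setClass("MarkovModel",
    representation(lag = "numeric", lagSteps = "integer", dt = "numeric",
                   counts = "matrix", transition = "matrix",
                   reversible = "logical", stationary = "numeric",
                   eigenvalues = "complex", rightVectors = "matrix",
                   leftVectors = "matrix", timescales = "numeric",
                   active = "integer", trimmed = "integer"))

setValidity("MarkovModel", function(object) {
    msg <- character()
    Tm <- object@transition
    if (nrow(Tm) != ncol(Tm)) msg <- c(msg, "transition matrix must be square")
    if (any(abs(rowSums(Tm) - 1) > 1e-12))
        msg <- c(msg, "transition matrix rows must sum to 1 (1e-12)")
    pi <- object@stationary
    if (any(pi < -1e-12)) msg <- c(msg, "stationary distribution must be >= 0")
    if (abs(sum(pi) - 1) > 1e-9) msg <- c(msg, "stationary must sum to 1")
    if (max(abs(pi %*% Tm - pi)) > 1e-10)
        msg <- c(msg, "stationary distribution must satisfy pi T = pi (1e-10)")
    if (any(Mod(object@eigenvalues) > 1 + 1e-9))
        msg <- c(msg, "eigenvalue moduli must be <= 1")
    if (length(msg)) msg else TRUE
})

#' Micro-to-macrostate lumping
#'
#' A surjective assignment of microstates to metastable macrostates obtained
#' from the slow eigenvectors (PCCA-style), with macrostate stationary
#' weights.
#'
#' @slot assignment integer vector: macrostate id (0-based) per active
#'   microstate.
#' @slot nMacro number of macrostates.
#' @slot weights macrostate stationary weights (sum to 1).
#' @slot warning character, non-empty when the spectral gap was questionable
#'   (e.g. complex eigenvalue at the cut).
#' @exportClass Lumping
setClass("Lumping",
    representation(assignment = "integer", nMacro = "integer",
                   weights = "numeric", warning = "character"))

setValidity("Lumping", function(object) {
    msg <- character()
    if (any(object@assignment < 0L) || any(object@assignment >= object@nMacro))
        msg <- c(msg, "macrostate ids must lie in 0..nMacro-1")
    if (length(unique(object@assignment)) != object@nMacro)
        msg <- c(msg, "every macrostate must receive at least one microstate")
    if (abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "macro weights must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Transition path theory result
#'
#' Forward/backward committors, reactive gross and net fluxes, total A->B
#' flux and the bottleneck decomposition of the net flux into pathways.
#'
#' @slot qPlus,qMinus forward and backward committors per state.
#' @slot A,B integer, 0-based source and sink state ids.
#' @slot flux gross reactive flux matrix f_ij = pi_i q-_i T_ij q+_j.
#' @slot netFlux net flux max(f_ij - f_ji, 0).
#' @slot totalFlux total A->B reactive flux.
#' @slot pathways data.frame: \code{path} (state ids joined by "->"),
#'   \code{flux}, \code{fraction} (non-increasing).
#' @slot residualFraction flux fraction left undecomposed at the stopping
#'   threshold.
#' @exportClass TptResult
setClass("TptResult",
    representation(qPlus = "numeric", qMinus = "numeric", A = "integer",
                   B = "integer", flux = "matrix", netFlux = "matrix",
                   totalFlux = "numeric", pathways = "data.frame",
                   residualFraction = "numeric"))

setValidity("TptResult", function(object) {
    msg <- character()
    if (any(object@qPlus < -1e-12 | object@qPlus > 1 + 1e-12))
        msg <- c(msg, "committors must lie in [0, 1]")
    if (any(abs(object@qPlus[object@A + 1L]) > 1e-12))
        msg <- c(msg, "q+ must be 0 on the source set")
    if (any(abs(object@qPlus[object@B + 1L] - 1) > 1e-12))
        msg <- c(msg, "q+ must be 1 on the sink set")
    if (any(object@flux < -1e-12)) msg <- c(msg, "gross flux must be >= 0")
    if (length(msg)) msg else TRUE
})
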