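#' Directional rates from exchange rate and minor population
#'
#' With the minor state E and major state B, detailed balance gives
#' \eqn{k_{BE} = p_E k_{ex}} and \eqn{k_{EB} = (1 - p_E) k_{ex}}.
#' Uncertainties, when supplied, are propagated to first order assuming
#' independent errors on kex and pE.
#'
#' @param kex exchange rate(s) (1/s, > 0).
#' @param pE minor-state fraction(s) in (0, 1).
#' @param kexSd,pESd optional standard errors.
#' @return data.frame with columns \code{kBE}, \code{kEB} and, when errors
#'   are given, \code{kBE_sd}, \code{kEB_sd}.
#' @examples
#' ratesFromKexPe(6100, 0.036)  # kBE = 219.6, kEB = 5880.4
#' @export
ratesFromKexPe <- function(kex, pE, kexSd = NULL, pESd = NULL) {
    if (any(kex <= 0)) stop("kex must be > 0")
    if (any(pE <= 0 | pE >= 1)) stop("pE must lie in (0, 1)")
    out <- data.frame(kBE = pE * kex, kEB = (1 - pE) * kex)
    if (!is.null(kexSd) && !is.null(pESd)) {
        out$kBE_sd <- sqrt((pE * kexSd)^2 + (kex * pESd)^2)
        out$kEB_sd <- sqrt(((1 - pE) * kexSd)^2 + (kex * pESd)^2)
    }
    out
}

#' Build a temperature series of directional rates
#'
#' @param tempK temperatures (K).
#' @param kex,kexSd exchange rates and errors (1/s).
#' @param pE,pESd minor-state fractions and errors.
#' @return data.frame with the inputs plus derived kBE, kEB and propagated
#'   errors; invariant kBE + kEB = kex holds by construction.
#' @export
rateSeries <- function(tempK, kex, kexSd, pE, pESd) {
    stopifnot(length(tempK) == length(kex), length(kex) == length(pE))
    dir <- ratesFromKexPe(kex, pE, kexSd, pESd)
    cbind(data.frame(temp_K = tempK, kex = kex, kex_sd = kexSd,
                     pE = pE, pE_sd = pESd), dir)
}

#' Packaged experimental rate series (five-temperature CPMG study)
#'
#' The bundled fixture of five (temperature, kex, pE) rows measured between
#' 1 and 20.4 degC for the B<->E interconversion of the T4 lysozyme cavity
#' triple mutant, with their reported uncertainties.
#'
#' @return data.frame as from \code{\link{rateSeries}}.
#' @export
table1Rates <- function() {
    path <- system.file("extdata", "table1_rates.csv", package = "confex")
    raw <- utils::read.csv(path)
    rateSeries(tempK = celsiusToKelvin(raw$temp_C), kex = raw$kex_s1,
               kexSd = raw$kex_sigma_s1, pE = raw$pE_pct / 100,
               pESd = raw$pE_sigma_pct / 100)
}

#' Weighted Arrhenius fit
#'
#' Weighted least squares of \eqn{\ln k} on \eqn{1/T}:
#' \eqn{\ln k = \ln A - E_a/(R T)} with R = 8.314 J/mol/K. Weights are
#' \eqn{1/\sigma_{\ln k}^2} with \eqn{\sigma_{\ln k} = \sigma_k / k}
#' (first-order); the fit is unweighted when no errors are supplied. The
#' parameter covariance is the inverse weighted normal matrix (known-error
#' convention) for weighted fits, and the usual residual-variance-scaled
#' covariance otherwise.
#'
#' @param tempK temperatures (K), at least 2 distinct values.
#' @param k rate constants (1/s, > 0).
#' @param kSd optional standard errors on k.
#' @return list of class \code{"ArrheniusFit"}: \code{Ea} (J/mol),
#'   \code{lnA}, \code{cov} (2x2 covariance of (lnA, Ea)), \code{n},
#'   \code{weighted}.
#' @export
fitArrhenius <- function(tempK, k, kSd = NULL) {
    if (any(k <= 0)) stop("rates must be > 0")
    if (length(unique(tempK)) < 2)
        stop("rank-deficient fit: need at least 2 distinct temperatures")
    y <- log(k)
    X <- cbind(1, 1 / tempK)
    if (!is.null(kSd)) {
        w <- (k / kSd)^2
        XtWX <- crossprod(X * sqrt(w))
        beta <- solve(XtWX, crossprod(X * w, y))
        covb <- solve(XtWX)
    } else {
        fit <- stats::lm.fit(X, y)
        beta <- fit$coefficients
        s2 <- sum(fit$residuals^2) / max(fit$df.residual, 1)
        covb <- s2 * solve(crossprod(X))
    }
    # beta = (lnA, -Ea/R); transform covariance to (lnA, Ea)
    J <- rbind(c(1, 0), c(0, -.RGAS))
    structure(list(Ea = -beta[[2]] * .RGAS, lnA = beta[[1]],
                   cov = J %*% covb %*% t(J), n = length(k),
                   weighted = !is.null(kSd)),
              class = "ArrheniusFit")
}

#' Evaluate an Arrhenius fit at a temperature
#'
#' \eqn{k(T) = \exp(\ln A - E_a / (R T))} with the standard error propagated
#' from the fit covariance (delta method).
#'
#' @param fit an \code{"ArrheniusFit"}.
#' @param tempK temperature(s) (K).
#' @return data.frame with columns \code{temp_K}, \code{k}, \code{k_sd}.
#' @export
extrapolateRate <- function(fit, tempK) {
    stopifnot(inherits(fit, "ArrheniusFit"))
    lnk <- fit$lnA - fit$Ea / (.RGAS * tempK)
    vlnk <- vapply(tempK, function(Tx) {
        g <- c(1, -1 / (.RGAS * Tx))
        drop(g %*% fit$cov %*% g)
    }, 0)
    k <- exp(lnk)
    data.frame(temp_K = tempK, k = k, k_sd = k * sqrt(pmax(vlnk, 0)))
}

#' Equilibrium thermodynamics from the two directional Arrhenius fits
#'
#' With B the reference (major) state, \eqn{\Delta X = X_E - X_B}:
#' \eqn{\Delta H = E_a(B \to E) - E_a(E \to B)},
#' \eqn{\Delta G(T) = -RT \ln(k_{BE}(T)/k_{EB}(T))},
#' \eqn{\Delta S = (\Delta H - \Delta G)/T}. Errors assume independent fits.
#'
#' @param fitBE,fitEB \code{"ArrheniusFit"}s of kBE(T) and kEB(T).
#' @param tempK reference temperature(s) (K).
#' @return list of class \code{"ThermoParams"}: \code{dH}, \code{dH_sd}
#'   (J/mol), per-temperature data.frame \code{byTemp} with \code{dG},
#'   \code{dG_sd} (J/mol), \code{dS}, \code{dS_sd} (J/mol/K), and
#'   \code{reference = "B"}.
#' @export
equilibriumThermo <- function(fitBE, fitEB, tempK) {
    dH <- fitBE$Ea - fitEB$Ea
    dHsd <- sqrt(fitBE$cov[2, 2] + fitEB$cov[2, 2])
    by <- do.call(rbind, lapply(tempK, function(Tx) {
        g <- c(1, -1 / (.RGAS * Tx))
        vln <- drop(g %*% fitBE$cov %*% g) + drop(g %*% fitEB$cov %*% g)
        lnr <- (fitBE$lnA - fitEB$lnA) - dH / (.RGAS * Tx)
        dG <- -.RGAS * Tx * lnr
        dGsd <- .RGAS * Tx * sqrt(vln)
        data.frame(temp_K = Tx, dG = dG, dG_sd = dGsd,
                   dS = (dH - dG) / Tx,
                   dS_sd = sqrt(dHsd^2 + dGsd^2) / Tx)
    }))
    structure(list(dH = dH, dH_sd = dHsd, byTemp = by, reference = "B"),
              class = "ThermoParams")
}

#' Activation free energy from a rate and a transition path time
#'
#' Uses the rate relation \eqn{k = (2\tau_{TPT})^{-1} e^{-\Delta G^\ddag /
#' k_B T}}, i.e. \eqn{\Delta G^\ddag = RT \ln(1 / (2 k \tau_{TPT}))}. When
#' \eqn{2 k \tau_{TPT} \ge 1} the process is effectively barrierless: the
#' value is still reported (it is <= 0) together with a flag rather than an
#' error.
#'
#' @param k rate constant (1/s).
#' @param tauTpt mean transition path time (s).
#' @param tempK temperature (K).
#' @return list: \code{dG_Jmol}, \code{dG_kJmol}, \code{dG_kBT},
#'   \code{barrierless}.
#' @examples
#' barrierFromTpt(897, 60.5e-9, 310.15)  # ~9.1 kBT
#' @export
barrierFromTpt <- function(k, tauTpt, tempK) {
    stopifnot(k > 0, tauTpt > 0, tempK > 0)
    x <- 2 * k * tauTpt
    dG <- .RGAS * tempK * log(1 / x)
    list(dG_Jmol = dG, dG_kJmol = dG / 1000,
         dG_kBT = log(1 / x), barrierless = x >= 1)
}

#' Activation entropy from activation enthalpy and free energy
#'
#' \eqn{\Delta S^\ddag = (\Delta H^\ddag - \Delta G^\ddag)/T}; also reported
#' as \eqn{T \Delta S^\ddag} in multiples of \eqn{k_B T}.
#'
#' @param dHact activation enthalpy (J/mol).
#' @param dGact activation free energy (J/mol).
#' @param tempK temperature (K).
#' @return list: \code{dS} (J/mol/K), \code{TdS_kBT}.
#' @examples
#' activationEntropy(65000, 25300, 310.15)  # 128 J/mol/K, 15.4 kBT
#' @export
activationEntropy <- function(dHact, dGact, tempK) {
    stopifnot(tempK > 0)
    list(dS = (dHact - dGact) / tempK,
         TdS_kBT = (dHact - dGact) / (.RGAS * tempK))
}

#' State lifetime from its exit rate
#'
#' The lifetime of a state is the reciprocal of its total exit rate; for the
#' minor state E that is \eqn{1/k_{EB}}.
#'
#' @param kOut exit rate (1/s, > 0).
#' @return lifetime in seconds.
#' @export
lifetime <- function(kOut) {
    if (any(kOut <= 0)) stop("exit rate must be > 0")
    1 / kOut
}

#' Arrhenius analysis of a directional rate series
#'
#' Convenience pipeline: fits weighted Arrhenius models to kBE(T) and kEB(T)
#' of a rate series (as from \code{\link{rateSeries}} or
#' \code{\link{table1Rates}}), extrapolates both to the requested
#' temperatures and assembles the equilibrium and activation thermodynamics.
#'
#' @param series data.frame from \code{\link{rateSeries}}.
#' @param extrapTempK temperatures (K) at which to report extrapolations.
#' @return list: \code{fitBE}, \code{fitEB} (Arrhenius fits), \code{extrap}
#'   (data.frame: temp_K, kBE, kEB, kex, pE_pct, lifetimeE_us with errors),
#'   \code{thermo} (\code{"ThermoParams"}), \code{dHactBE} = Ea of kBE.
#' @export
arrheniusAnalysis <- function(series, extrapTempK = c(310.15, 323.15)) {
    fitBE <- fitArrhenius(series$temp_K, series$kBE, series$kBE_sd)
    fitEB <- fitArrhenius(series$temp_K, series$kEB, series$kEB_sd)
    eBE <- extrapolateRate(fitBE, extrapTempK)
    eEB <- extrapolateRate(fitEB, extrapTempK)
    kex <- eBE$k + eEB$k
    pE <- eBE$k / kex
    extrap <- data.frame(
        temp_K = extrapTempK, kBE = eBE$k, kBE_sd = eBE$k_sd,
        kEB = eEB$k, kEB_sd = eEB$k_sd, kex = kex,
        kex_sd = sqrt(eBE$k_sd^2 + eEB$k_sd^2),
        pE_pct = 100 * pE, lifetimeE_us = 1e6 * lifetime(eEB$k))
    list(fitBE = fitBE, fitEB = fitEB, extrap = extrap,
         thermo = equilibriumThermo(fitBE, fitEB, extrapTempK),
         dHactBE = fitBE$Ea)
}
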