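# Split a dataset into profiles (residue x nucleus x field x temperature),
# keeping per-profile metadata needed by the forward model.
.profiles <- function(data) {
    pts <- dispersionPoints(data)
    pid <- interaction(pts$residue, pts$nucleus, pts$field_T, pts$temp_K,
                       drop = TRUE, sep = "@")
    lapply(split(pts, pid), function(p) {
        p <- p[order(p$nu_cpmg_hz), ]
        list(id = paste(p$residue[1], p$field_T[1], sep = "@"),
             residue = as.character(p$residue[1]), nucleus = p$nucleus[1],
             fieldT = p$field_T[1], tCpmg = p$t_cpmg_s[1],
             nu = p$nu_cpmg_hz, obs = p$r2eff_s1, sigma = p$sigma_s1)
    })
}

# Exchange contribution (R2,eff with R2,0 = 0) for one profile.  R2,0 enters
# the Bloch-McConnell propagator as a scalar factor exp(-R2,0 T_cpmg), so
# R2,eff is exactly R2,0 + rex and R2,0 can be profiled out linearly.
.rexProfile <- function(kex, pE, dwPpm, prof) {
    simulateR2effBM(kex, pE, dwPpm, r20 = 0, nucleus = prof$nucleus,
                    fieldT = prof$fieldT, nu = prof$nu, tCpmg = prof$tCpmg)
}

.globalResiduals <- function(par, profs, residues) {
    kex <- par[1]; pE <- par[2]
    dw <- par[-(1:2)]
    names(dw) <- residues
    unlist(lapply(profs, function(prof) {
        rex <- .rexProfile(kex, pE, dw[[prof$residue]], prof)
        w <- 1 / prof$sigma^2
        r20 <- sum(w * (prof$obs - rex)) / sum(w)   # profiled-out intercept
        (prof$obs - rex - r20) / prof$sigma
    }), use.names = FALSE)
}

.fitR20 <- function(kex, pE, dw, profs) {
    vapply(profs, function(prof) {
        rex <- .rexProfile(kex, pE, dw[[prof$residue]], prof)
        w <- 1 / prof$sigma^2
        sum(w * (prof$obs - rex)) / sum(w)
    }, 0)
}

#' Global two-state fit of a dispersion dataset
#'
#' Minimises \eqn{\sum ((R_{2,eff}^{obs} - R_{2,eff}^{model})/\sigma)^2} over
#' a global exchange rate and minor population, one \eqn{\Delta\omega} per
#' residue (ppm, shared across fields; constrained >= 0 since CPMG does not
#' determine its sign) and one \eqn{R_{2,0}} per profile. Because the two
#' exchanging states share R2,0, the per-profile intercepts are profiled out
#' analytically, and the nonlinear search runs over (kex, pE, dw) only, by
#' bounded Levenberg-Marquardt least squares started from a grid of initial
#' guesses (kex in {500, 2000, 8000} x pE in {0.01, 0.05, 0.2} by default);
#' the start with the lowest chi-square wins.
#'
#' @param data a \code{\linkS4class{DispersionExperiment}}; all sigma > 0.
#' @param init optional named list of extra starting values merged into the
#'   default start grid: components \code{kex}, \code{pE} (vectors,
#'   crossed) and \code{dw} (values in ppm, used for every residue). The
#'   default grid is always retained, so recovery does not depend on the
#'   quality of a user-supplied guess.
#' @param bounds named list of length-2 vectors \code{kex}, \code{pE},
#'   \code{dw}.
#' @return a \code{\linkS4class{TwoStateFit}}. Non-convergence of all starts
#'   leaves \code{converged = FALSE} with the best diagnostics retained;
#'   a fit whose exchange contribution is negligible (all profiles flat,
#'   pE*dw^2 ~ 0) is flagged \code{identifiable = FALSE}.
#' @export
fitTwoStateGlobal <- function(data, init = NULL,
                              bounds = list(kex = c(10, 1e6),
                                            pE = c(1e-4, 0.499),
                                            dw = c(0, 20))) {
    profs <- .profiles(data)
    if (length(profs) < 1) stop("need at least one profile")
    if (any(vapply(profs, function(p) any(p$sigma <= 0), TRUE)))
        stop("all sigma must be > 0")
    residues <- unique(vapply(profs, `[[`, "", "residue"))
    kexGrid <- unique(c(500, 2000, 8000, init$kex))
    pEGrid <- unique(c(0.01, 0.05, 0.2, init$pE))
    dwGrid <- unique(c(1.5, init$dw))
    lower <- c(bounds$kex[1], bounds$pE[1], rep(bounds$dw[1], length(residues)))
    upper <- c(bounds$kex[2], bounds$pE[2], rep(bounds$dw[2], length(residues)))
    starts <- expand.grid(kex = kexGrid, pE = pEGrid, dw = dwGrid)
    runs <- lapply(seq_len(nrow(starts)), function(i) {
        p0 <- c(starts$kex[i], starts$pE[i],
                rep(starts$dw[i], length(residues)))
        p0 <- pmin(pmax(p0, lower), upper)
        fit <- try(minpack.lm::nls.lm(
            par = p0, lower = lower, upper = upper,
            fn = .globalResiduals, profs = profs, residues = residues,
            control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
        if (inherits(fit, "try-error")) return(NULL)
        list(par = fit$par, chisq = fit$deviance,
             converged = fit$info %in% 1:3, info = fit$info)
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs)) stop("optimizer failed for every start")
    chis <- vapply(runs, `[[`, 0, "chisq")
    best <- runs[[which.min(chis)]]
    kex <- best$par[1]; pE <- best$par[2]
    dw <- best$par[-(1:2)]; names(dw) <- residues
    r20 <- .fitR20(kex, pE, dw, profs)
    names(r20) <- vapply(profs, `[[`, "", "id")
    resid <- do.call(rbind, lapply(seq_along(profs), function(i) {
        prof <- profs[[i]]
        rex <- .rexProfile(kex, pE, dw[[prof$residue]], prof)
        data.frame(profile = prof$id, nu_cpmg_hz = prof$nu,
                   fitted = rex + r20[[i]],
                   weighted_residual = (prof$obs - rex - r20[[i]]) / prof$sigma)
    }))
    # identifiability: does the exchange model beat the exchange-free model
    # (per-profile weighted-mean R2,0 only) by more than chance?
    chisqFlat <- sum(vapply(profs, function(prof) {
        w <- 1 / prof$sigma^2
        mu <- sum(w * prof$obs) / sum(w)
        sum(((prof$obs - mu) / prof$sigma)^2)
    }, 0))
    dfExch <- 2L + length(residues)
    identifiable <- (chisqFlat - best$chisq) >
        stats::qchisq(0.99, df = dfExch)
    nobs <- sum(vapply(profs, function(p) length(p$nu), 0L))
    npar <- 2L + length(residues) + length(profs)
    new("TwoStateFit", kex = kex, pE = pE, dwPpm = dw, r20 = r20,
        chisq = best$chisq,
        redChisq = best$chisq / max(nobs - npar, 1L),
        converged = best$converged,
        identifiable = identifiable,
        boot = list(), residuals = resid,
        multistart = data.frame(kex0 = starts$kex, pE0 = starts$pE,
                                dw0 = starts$dw, chisq = chis))
}

#' Residual-resampling bootstrap for a global dispersion fit
#'
#' Resamples the residuals of the converged fit (inflated by
#' \eqn{\sqrt{n/(n-p)}} to undo the downward bias of fitted residuals), adds
#' them back to the fitted curves, and refits each replicate starting from
#' the original solution. Returns the fit with per-parameter bootstrap
#' draws, standard deviations and central 95\% quantiles in its \code{boot}
#' slot.
#'
#' @param data the dataset that produced \code{fit}.
#' @param fit a converged \code{\linkS4class{TwoStateFit}}.
#' @param nBoot number of replicates (>= 10).
#' @param seed integer seed.
#' @return the fit with a populated \code{boot} slot: \code{draws}
#'   (data.frame), \code{sd}, \code{lower}, \code{upper} (2.5/97.5\%
#'   quantiles).
#' @export
bootstrapErrors <- function(data, fit, nBoot = 50, seed = 1) {
    if (nBoot < 10) stop("nBoot must be >= 10")
    if (!fit@converged) stop("bootstrap requires a converged fit")
    profs <- .profiles(data)
    residues <- names(fit@dwPpm)
    fitted <- lapply(profs, function(prof) {
        rex <- .rexProfile(fit@kex, fit@pE, fit@dwPpm[[prof$residue]], prof)
        rex + fit@r20[[prof$id]]
    })
    nobs <- sum(lengths(lapply(profs, `[[`, "obs")))
    npar <- 2L + length(residues) + length(profs)
    resids <- unlist(lapply(seq_along(profs), function(i)
        profs[[i]]$obs - fitted[[i]]), use.names = FALSE) *
        sqrt(nobs / max(nobs - npar, 1L))
    p0 <- c(fit@kex, fit@pE, fit@dwPpm)
    lower <- c(10, 1e-4, rep(0, length(residues)))
    upper <- c(1e6, 0.499, rep(20, length(residues)))
    set.seed(as.integer(seed))
    draws <- matrix(NA_real_, nBoot, 2L + length(residues))
    for (b in seq_len(nBoot)) {
        bprofs <- profs
        off <- 0L
        for (i in seq_along(bprofs)) {
            n <- length(bprofs[[i]]$obs)
            bprofs[[i]]$obs <- fitted[[i]] +
                sample(resids, n, replace = TRUE)
            off <- off + n
        }
        bf <- try(minpack.lm::nls.lm(
            par = p0, lower = lower, upper = upper,
            fn = .globalResiduals, profs = bprofs, residues = residues,
            control = minpack.lm::nls.lm.control(maxiter = 100)),
            silent = TRUE)
        if (!inherits(bf, "try-error")) draws[b, ] <- bf$par
    }
    colnames(draws) <- c("kex", "pE", paste0("dw_", residues))
    draws <- as.data.frame(draws[stats::complete.cases(draws), , drop = FALSE])
    fit@boot <- list(
        draws = draws,
        sd = vapply(draws, stats::sd, 0),
        lower = vapply(draws, stats::quantile, 0, probs = 0.025),
        upper = vapply(draws, stats::quantile, 0, probs = 0.975))
    fit
}
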