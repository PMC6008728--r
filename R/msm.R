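#' Construct a discrete-state trajectory
#'
#' @param states integer vector of 0-based state ids.
#' @param dt frame interval (time units).
#' @param nStates number of states of the model; defaults to max(states)+1.
#' @return a \code{\linkS4class{StateTraj}}.
#' @export
stateTraj <- function(states, dt, nStates = max(states) + 1L) {
    new("StateTraj", states = as.integer(states), dt = dt,
        nStates = as.integer(nStates))
}

.asTrajList <- function(trajs) {
    if (is(trajs, "StateTraj")) list(trajs) else trajs
}

#' Cluster feature trajectories into microstates
#'
#' k-means clustering of the pooled feature vectors with a seed-fixed
#' initialisation; every frame is assigned to its nearest center, giving one
#' discrete trajectory per input trajectory.
#'
#' @param features a \code{\linkS4class{FeatureTraj}} or list of them.
#' @param nMicro number of microstates (<= total frames).
#' @param seed integer seed for the k-means initialisation.
#' @param nstart number of random k-means starts.
#' @param maxFit centers are fitted on a random subsample of at most this
#'   many frames (all frames are then assigned to the nearest center),
#'   keeping the clustering cost bounded for long trajectories.
#' @return list: \code{trajs} (list of \code{\linkS4class{StateTraj}} with
#'   0-based cluster ids), \code{centers} (nMicro x d matrix).
#' @export
assignMicrostates <- function(features, nMicro, seed, nstart = 10,
                              maxFit = 100000) {
    if (is(features, "FeatureTraj")) features <- list(features)
    X <- do.call(rbind, lapply(features, function(f) f@coords))
    if (nMicro > nrow(X)) stop("nMicro exceeds the number of frames")
    set.seed(as.integer(seed))
    Xfit <- if (nrow(X) > maxFit) X[sample(nrow(X), maxFit), , drop = FALSE]
            else X
    # Quick-TRANSfer warnings on dense low-dimensional data are expected
    # and harmless here: centers need to be deterministic given the seed,
    # not globally optimal
    km <- suppressWarnings(stats::kmeans(Xfit, centers = nMicro,
                                         nstart = nstart, iter.max = 100))
    # assign every frame to its nearest center
    cn <- rowSums(km$centers^2)
    idx <- max.col(X %*% t(km$centers) - rep(cn / 2, each = nrow(X)),
                   ties.method = "first") - 1L
    off <- 0L
    trajs <- lapply(features, function(f) {
        n <- nrow(f@coords)
        s <- idx[(off + 1L):(off + n)]
        off <<- off + n
        stateTraj(s, dt = f@dt, nStates = as.integer(nMicro))
    })
    list(trajs = trajs, centers = km$centers)
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Translates both coordinate sets to their centroids and rotates Y onto X
#' with the optimal proper rotation from the singular value decomposition of
#' the covariance matrix (reflections are excluded by flipping the sign of
#' the smallest singular vector when needed).
#'
#' @param X,Y n x d coordinate matrices with equal dimensions, n >= 3.
#' @return the minimal root-mean-square deviation.
#' @export
kabschRmsd <- function(X, Y) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (!all(dim(X) == dim(Y))) stop("coordinate sets differ in size")
    if (nrow(X) < 3) stop("need at least 3 points")
    Xc <- scale(X, scale = FALSE)
    Yc <- scale(Y, scale = FALSE)
    s <- svd(crossprod(Yc, Xc))
    d <- sign(det(s$v %*% t(s$u)))
    D <- diag(c(rep(1, ncol(X) - 1), d))
    R <- s$v %*% D %*% t(s$u)
    sqrt(mean(rowSums((Xc - Yc %*% t(R))^2)))
}

#' Transition count matrix at a lag
#'
#' Counts observed pairs (x_t = i, x_(t+lag) = j) within each trajectory;
#' trajectories are never concatenated. Sliding mode counts every admissible
#' t; strided mode advances t by the lag.
#'
#' @param trajs a \code{\linkS4class{StateTraj}} or list of them, sharing
#'   nStates and dt.
#' @param lagSteps lag in frames (>= 1).
#' @param mode "sliding" (default) or "strided".
#' @return integer count matrix (nStates x nStates).
#' @export
countMatrix <- function(trajs, lagSteps, mode = c("sliding", "strided")) {
    mode <- match.arg(mode)
    trajs <- .asTrajList(trajs)
    lagSteps <- as.integer(lagSteps)
    if (lagSteps < 1L) stop("lagSteps must be >= 1")
    n <- trajs[[1]]@nStates
    C <- matrix(0L, n, n)
    any <- FALSE
    for (tr in trajs) {
        s <- tr@states
        L <- length(s)
        if (L <= lagSteps) next
        any <- TRUE
        from <- if (mode == "sliding") seq_len(L - lagSteps)
                else seq(1L, L - lagSteps, by = lagSteps)
        idx <- cbind(s[from] + 1L, s[from + lagSteps] + 1L)
        tab <- table(factor(idx[, 1], levels = 1:n),
                     factor(idx[, 2], levels = 1:n))
        C <- C + unclass(tab)
    }
    if (!any) stop("lag is at least as long as every trajectory: no counts")
    storage.mode(C) <- "integer"
    dimnames(C) <- NULL
    C
}

# largest strongly connected component of the directed count graph,
# weighted by total counts; returns 1-based indices
.largestScc <- function(C) {
    g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
    comp <- igraph::components(g, mode = "strong")
    tot <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
    keep <- which(comp$membership == as.integer(names(which.max(tot))))
    sort(keep)
}

#' Estimate a Markov state model from a count matrix
#'
#' Restricts the counts to the largest strongly connected component (ergodic
#' trimming; removed states are reported in the \code{trimmed} slot), then
#' row-normalises either the raw counts (non-reversible) or the symmetrized
#' counts \eqn{(C + C^T)/2} (reversible, the default), which enforces
#' detailed balance by construction. For the reversible estimator the
#' stationary distribution is the normalised row sum of the symmetrized
#' counts and the spectrum is computed from the symmetric similarity
#' transform (guaranteeing a real spectrum); otherwise the leading left
#' eigenvector is used. Implied timescales are \eqn{t_i = -\tau/\ln
#' \lambda_i} for i >= 2 (NA where \eqn{\lambda_i} is complex or
#' non-positive); \eqn{t_1} is infinite.
#'
#' @param C count matrix (as from \code{\link{countMatrix}}).
#' @param dt frame interval of the counted trajectories (time units).
#' @param lagSteps lag (frames) at which C was counted.
#' @param reversible logical, default TRUE.
#' @return a \code{\linkS4class{MarkovModel}}.
#' @export
transitionModel <- function(C, dt, lagSteps, reversible = TRUE) {
    n0 <- nrow(C)
    keep <- .largestScc(C)
    trimmed <- setdiff(seq_len(n0), keep)
    if (length(trimmed))
        message("ergodic trimming removed ", length(trimmed), " state(s): ",
                paste(trimmed - 1L, collapse = ", "))
    C <- C[keep, keep, drop = FALSE]
    n <- nrow(C)
    if (n == 1) {
        # trivial one-state chain: only the infinite equilibrium timescale
        return(new("MarkovModel", lag = lagSteps * dt,
                   lagSteps = as.integer(lagSteps), dt = dt, counts = C,
                   transition = matrix(1, 1, 1), reversible = reversible,
                   stationary = 1, eigenvalues = as.complex(1),
                   rightVectors = matrix(1, 1, 1),
                   leftVectors = matrix(1, 1, 1), timescales = Inf,
                   active = as.integer(keep - 1L),
                   trimmed = as.integer(trimmed - 1L)))
    }
    if (reversible) {
        Cs <- (C + t(C)) / 2
        Tm <- Cs / rowSums(Cs)
        pi <- rowSums(Cs) / sum(Cs)
        d <- sqrt(pi)
        S <- Tm * d / rep(d, each = n)
        S <- (S + t(S)) / 2
        es <- eigen(S, symmetric = TRUE)
        ord <- order(es$values, decreasing = TRUE)
        lam <- as.complex(es$values[ord])
        right <- es$vectors[, ord, drop = FALSE] / d
        left <- es$vectors[, ord, drop = FALSE] * d
    } else {
        Tm <- C / rowSums(C)
        es <- eigen(t(Tm))
        ordl <- order(Mod(es$values), decreasing = TRUE)
        piv <- Re(es$vectors[, ordl[1]])
        pi <- abs(piv) / sum(abs(piv))
        er <- eigen(Tm)
        ord <- order(Mod(er$values), decreasing = TRUE)
        lam <- as.complex(er$values[ord])
        right <- er$vectors[, ord, drop = FALSE]
        left <- es$vectors[, ordl, drop = FALSE]
    }
    lamr <- Re(lam)
    ts <- rep(NA_real_, n)
    ts[1] <- Inf
    ok <- seq_len(n) > 1 & abs(Im(lam)) < 1e-12 & lamr > 0 & lamr < 1
    ts[ok] <- -(lagSteps * dt) / log(lamr[ok])
    new("MarkovModel", lag = lagSteps * dt, lagSteps = as.integer(lagSteps),
        dt = dt, counts = C, transition = Tm, reversible = reversible,
        stationary = pi, eigenvalues = lam,
        rightVectors = if (is.complex(right)) Re(right) else right,
        leftVectors = if (is.complex(left)) Re(left) else left,
        timescales = ts, active = as.integer(keep - 1L),
        trimmed = as.integer(trimmed - 1L))
}

#' Build a Markov state model from trajectories
#'
#' @param trajs state trajectory or list of them.
#' @param lagSteps lag in frames.
#' @param reversible passed to \code{\link{transitionModel}}.
#' @param mode counting mode, see \code{\link{countMatrix}}.
#' @return a \code{\linkS4class{MarkovModel}}.
#' @export
buildMsm <- function(trajs, lagSteps, reversible = TRUE, mode = "sliding") {
    trajs <- .asTrajList(trajs)
    C <- countMatrix(trajs, lagSteps, mode)
    transitionModel(C, dt = trajs[[1]]@dt, lagSteps = lagSteps,
                    reversible = reversible)
}

#' Implied timescales as a function of lag time
#'
#' Re-estimates the model at each requested lag and tabulates
#' \eqn{t_i(\tau) = -\tau/\ln\lambda_i(\tau)}. A plateau in \eqn{t_i(\tau)}
#' indicates lags at which the discretised dynamics are Markovian.
#'
#' @param trajs state trajectory or list of them.
#' @param lagStepsVec lags in frames.
#' @param nTimescales how many timescales to report (including the infinite
#'   t1).
#' @param reversible estimator choice.
#' @return data.frame: \code{lag_steps}, \code{lag}, \code{index},
#'   \code{timescale}.
#' @export
impliedTimescales <- function(trajs, lagStepsVec, nTimescales = 5,
                              reversible = TRUE) {
    trajs <- .asTrajList(trajs)
    do.call(rbind, lapply(lagStepsVec, function(l) {
        m <- buildMsm(trajs, l, reversible = reversible)
        k <- min(nTimescales, length(m@timescales))
        data.frame(lag_steps = l, lag = m@lag, index = seq_len(k),
                   timescale = m@timescales[seq_len(k)])
    }))
}

#' Propagate a population vector
#'
#' \eqn{P(n\tau) = P(0) T(\tau)^n}; probability mass is conserved by
#' row-stochasticity.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param p0 initial population over the active states (>= 0, sums to 1).
#' @param n number of lag steps (>= 0).
#' @return population vector after n steps.
#' @export
propagatePopulations <- function(model, p0, n) {
    stopifnot(length(p0) == nrow(model@transition), all(p0 >= 0),
              abs(sum(p0) - 1) < 1e-9, n >= 0)
    p <- as.numeric(p0)
    Tn <- model@transition
    n <- as.integer(n)
    # binary exponentiation on the vector
    while (n > 0) {
        if (n %% 2L == 1L) p <- as.numeric(p %*% Tn)
        n <- n %/% 2L
        if (n > 0) Tn <- Tn %*% Tn
    }
    p
}

#' PCCA-style macrostate lumping
#'
#' Crisp assignment of microstates to \code{nMacro} metastable macrostates
#' from the top right eigenvectors, using the deterministic inner-simplex
#' vertex search: the most spread-out eigenvector rows are taken as simplex
#' vertices, memberships follow from the linear transform onto that simplex
#' and each microstate joins the macrostate with its largest membership
#' (ties broken by lowest index). A warning is attached when the eigenvalue
#' at the cut is complex or the spectral gap is marginal.
#'
#' @param model a \code{\linkS4class{MarkovModel}} (reversible estimates
#'   give the cleanest simplex structure).
#' @param nMacro number of macrostates, 2 <= nMacro <= n micro.
#' @return a \code{\linkS4class{Lumping}}.
#' @export
lumpMacrostates <- function(model, nMacro) {
    n <- nrow(model@transition)
    nMacro <- as.integer(nMacro)
    if (nMacro < 2L || nMacro > n) stop("need 2 <= nMacro <= n microstates")
    warn <- character()
    if (nMacro < n && abs(Im(model@eigenvalues[nMacro])) > 1e-12)
        warn <- "eigenvalue at the macrostate cut is complex; no clear gap"
    Psi <- model@rightVectors[, seq_len(nMacro), drop = FALSE]
    Psi[, 1] <- 1
    # inner simplex algorithm: pick rows spanning the eigenvector simplex
    verts <- integer(nMacro)
    W <- Psi
    verts[1] <- which.max(rowSums(W^2))
    W <- sweep(W, 2, W[verts[1], ])
    for (k in seq_len(nMacro - 1L)) {
        nr <- sqrt(rowSums(W^2))
        verts[k + 1L] <- which.max(nr)
        v <- W[verts[k + 1L], ] / nr[verts[k + 1L]]
        W <- W - outer(as.numeric(W %*% v), v)
    }
    chi <- Psi %*% solve(Psi[verts, , drop = FALSE])
    assign <- max.col(chi, ties.method = "first") - 1L
    # relabel macrostates by first occurrence for determinism
    lev <- unique(assign)
    assign <- match(assign, lev) - 1L
    if (length(unique(assign)) < nMacro)
        stop("degenerate lumping: fewer than nMacro macrostates populated")
    w <- vapply(0:(nMacro - 1L), function(m)
        sum(model@stationary[assign == m]), 0)
    new("Lumping", assignment = assign, nMacro = nMacro, weights = w,
        warning = warn)
}

#' Chapman-Kolmogorov test
#'
#' Compares the model prediction \eqn{P(0) T(\tau)^n} for staying within
#' each macro-set against a direct estimate from a transition matrix counted
#' at lag \eqn{n\tau}, starting from the stationary distribution restricted
#' to the set. Entries where the data cannot support a direct estimate at
#' \eqn{n\tau} are marked unavailable.
#'
#' @param trajs the trajectories the model was built from.
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param sets list of integer vectors of 0-based state ids (macro-sets).
#' @param nList multiples of the model lag to test.
#' @return data.frame: \code{set}, \code{n}, \code{model}, \code{direct},
#'   \code{deviation}, \code{available}.
#' @export
ckTest <- function(trajs, model, sets, nList = c(1, 2, 5)) {
    trajs <- .asTrajList(trajs)
    do.call(rbind, lapply(seq_along(sets), function(si) {
        ids <- match(sets[[si]], model@active)
        if (anyNA(ids)) stop("set contains trimmed/unknown states")
        w <- model@stationary[ids]
        w <- w / sum(w)
        do.call(rbind, lapply(nList, function(n) {
            p0 <- numeric(nrow(model@transition))
            p0[ids] <- w
            pm <- sum(propagatePopulations(model, p0, n)[ids])
            direct <- tryCatch({
                Cd <- countMatrix(trajs, model@lagSteps * n, mode = "sliding")
                Cd <- Cd[model@active + 1L, model@active + 1L, drop = FALSE]
                rs <- rowSums(Cd)
                if (any(rs[ids] == 0)) NA_real_ else {
                    Td <- Cd / pmax(rs, 1)
                    sum((w %*% Td[ids, , drop = FALSE])[ids])
                }
            }, error = function(e) NA_real_)
            data.frame(set = si, n = n, model = pm, direct = direct,
                       deviation = abs(pm - direct),
                       available = is.finite(direct))
        }))
    }))
}

#' Two-state reduction of a Markov state model
#'
#' Reduces the model to an effective two-state exchange between a minor set
#' E and a major set B: \eqn{k_{ex} = 1/t_2} (the slowest implied timescale
#' corresponds to the E-B interconversion) and \eqn{p_E =
#' \pi(E)/(\pi(E)+\pi(B))}. Optional bootstrap over trajectories gives
#' standard errors.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param Eset,Bset disjoint non-empty 0-based state id sets.
#' @param trajs trajectories for the bootstrap (required when nBoot > 0).
#' @param nBoot bootstrap replicates over trajectories.
#' @param seed bootstrap seed.
#' @return list: \code{kex}, \code{pE}, and with bootstrap \code{kex_sd},
#'   \code{pE_sd}, \code{draws}.
#' @export
twoStateReduction <- function(model, Eset, Bset, trajs = NULL, nBoot = 0,
                              seed = 1) {
    if (length(intersect(Eset, Bset))) stop("Eset and Bset must be disjoint")
    if (!length(Eset) || !length(Bset)) stop("Eset and Bset must be non-empty")
    reduce <- function(m) {
        t2 <- m@timescales[2]
        if (!is.finite(t2) || t2 <= 0)
            stop("slowest implied timescale is not a positive real number")
        ie <- match(Eset, m@active); ib <- match(Bset, m@active)
        piE <- sum(m@stationary[ie[!is.na(ie)]])
        piB <- sum(m@stationary[ib[!is.na(ib)]])
        c(kex = 1 / t2, pE = piE / (piE + piB))
    }
    out <- as.list(reduce(model))
    if (nBoot > 0) {
        if (is.null(trajs)) stop("bootstrap needs the trajectories")
        trajs <- .asTrajList(trajs)
        set.seed(as.integer(seed))
        draws <- t(vapply(seq_len(nBoot), function(b) {
            idx <- sample(length(trajs), replace = TRUE)
            tryCatch(reduce(buildMsm(trajs[idx], model@lagSteps,
                                     reversible = model@reversible)),
                     error = function(e) c(kex = NA_real_, pE = NA_real_))
        }, c(kex = 0, pE = 0)))
        draws <- draws[stats::complete.cases(draws), , drop = FALSE]
        out$kex_sd <- stats::sd(draws[, "kex"])
        out$pE_sd <- stats::sd(draws[, "pE"])
        out$draws <- as.data.frame(draws)
    }
    out
}

#' Free-energy surface and 1D PMF projections from a discretised trajectory
#'
#' Histograms the feature frames on a 2D grid with each frame weighted by
#' \eqn{\pi(\textrm{its microstate}) / (\textrm{frames in that
#' microstate})}, so the surface reflects the stationary distribution of the
#' Markov model rather than the raw (possibly non-equilibrium) visitation.
#' \eqn{F = -k_B T \ln(\textrm{weighted histogram})}, minimum shifted to 0,
#' empty bins +Inf. 1D profiles project the probability (not F) onto each
#' axis.
#'
#' @param features a \code{\linkS4class{FeatureTraj}} or list.
#' @param stateTrajs matching \code{\linkS4class{StateTraj}} assignments (as
#'   from \code{\link{assignMicrostates}}).
#' @param model \code{\linkS4class{MarkovModel}} supplying the stationary
#'   weights.
#' @param bins number of bins per axis (length 1 or 2, >= 2).
#' @param kT thermal energy for the F scale.
#' @return list: \code{x}, \code{y} (bin centers), \code{F} (matrix, kT
#'   units), \code{pmfX}, \code{pmfY} (data.frames with coordinate and F).
#' @export
freeEnergySurface <- function(features, stateTrajs, model, bins = 60,
                              kT = 1) {
    if (is(features, "FeatureTraj")) features <- list(features)
    stateTrajs <- .asTrajList(stateTrajs)
    X <- do.call(rbind, lapply(features, function(f) f@coords))
    s <- unlist(lapply(stateTrajs, function(t) t@states))
    bins <- rep_len(as.integer(bins), 2)
    if (any(bins < 2)) stop("need at least 2 bins per axis")
    pos <- match(s, model@active)
    keep <- !is.na(pos)
    X <- X[keep, , drop = FALSE]; pos <- pos[keep]
    nframes <- tabulate(pos, nbins = nrow(model@transition))
    wt <- model@stationary[pos] / nframes[pos]
    bx <- seq(min(X[, 1]), max(X[, 1]), length.out = bins[1] + 1L)
    by <- seq(min(X[, 2]), max(X[, 2]), length.out = bins[2] + 1L)
    ix <- pmin(findInterval(X[, 1], bx, rightmost.closed = TRUE), bins[1])
    iy <- pmin(findInterval(X[, 2], by, rightmost.closed = TRUE), bins[2])
    H <- matrix(0, bins[1], bins[2])
    for (k in seq_along(wt)) H[ix[k], iy[k]] <- H[ix[k], iy[k]] + wt[k]
    if (sum(H > 0) < 2) warning("degenerate surface: all frames in one bin")
    P <- H / sum(H)
    F <- -kT * log(P)
    F <- F - min(F)
    px <- rowSums(P); py <- colSums(P)
    fx <- -kT * log(px); fy <- -kT * log(py)
    list(x = (bx[-1] + bx[-length(bx)]) / 2,
         y = (by[-1] + by[-length(by)]) / 2,
         F = F,
         pmfX = data.frame(x = (bx[-1] + bx[-length(bx)]) / 2,
                           F = fx - min(fx[is.finite(fx)])),
         pmfY = data.frame(y = (by[-1] + by[-length(by)]) / 2,
                           F = fy - min(fy[is.finite(fy)])))
}
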