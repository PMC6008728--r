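.tptIdx <- function(model, ids, what) {
    pos <- match(ids, model@active)
    if (anyNA(pos))
        stop(what, " contains states outside the active set: ",
             paste(ids[is.na(pos)], collapse = ", "))
    pos
}

#' Forward and backward committors
#'
#' Solves the committor linear system on the intermediate states,
#' \eqn{q^+_i = \sum_j T_{ij} q^+_j} with boundary conditions
#' \eqn{q^+(A) = 0}, \eqn{q^+(B) = 1}; the backward committor uses the
#' time-reversed chain \eqn{\tilde T_{ij} = \pi_j T_{ji}/\pi_i} (for a
#' reversible model \eqn{q^- = 1 - q^+}). Intermediates from which the sink
#' is unreachable make the system singular and are reported by name.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param A,B disjoint non-empty 0-based source and sink state sets.
#' @return a \code{\linkS4class{TptResult}} with committors filled in and
#'   flux slots computed via \code{\link{reactiveFlux}}.
#' @export
committors <- function(model, A, B) {
    if (length(intersect(A, B))) stop("A and B must be disjoint")
    if (!length(A) || !length(B)) stop("A and B must be non-empty")
    Tm <- model@transition
    n <- nrow(Tm)
    ia <- .tptIdx(model, A, "A")
    ib <- .tptIdx(model, B, "B")
    ii <- setdiff(seq_len(n), c(ia, ib))
    # reachability of B (for a clear error instead of a singular solve)
    reach <- rep(FALSE, n)
    reach[ib] <- TRUE
    repeat {
        new <- reach | (Tm[, reach, drop = FALSE] %*%
                            rep(1, sum(reach)) > 0)
        if (all(new == reach)) break
        reach <- as.logical(new)
    }
    if (any(!reach[ii]))
        stop("sink unreachable from state(s): ",
             paste(model@active[ii[!reach[ii]]], collapse = ", "))
    qp <- numeric(n)
    qp[ib] <- 1
    if (length(ii)) {
        M <- diag(length(ii)) - Tm[ii, ii, drop = FALSE]
        rhs <- rowSums(Tm[ii, ib, drop = FALSE])
        qp[ii] <- solve(M, rhs)
    }
    qp <- pmin(pmax(qp, 0), 1)
    # backward committor on the time-reversed chain
    pi <- model@stationary
    Tr <- t(Tm) * rep(pi, each = n) / pi     # Tr_ij = pi_j T_ji / pi_i
    qm <- numeric(n)
    qm[ia] <- 1
    if (length(ii)) {
        M <- diag(length(ii)) - Tr[ii, ii, drop = FALSE]
        rhs <- rowSums(Tr[ii, ia, drop = FALSE])
        qm[ii] <- solve(M, rhs)
    }
    qm <- pmin(pmax(qm, 0), 1)
    res <- new("TptResult", qPlus = qp, qMinus = qm,
               A = as.integer(sort(A)), B = as.integer(sort(B)),
               flux = matrix(0, n, n), netFlux = matrix(0, n, n),
               totalFlux = 0, pathways = data.frame(),
               residualFraction = NA_real_)
    reactiveFlux(model, res)
}

#' Reactive flux network
#'
#' Transition-path-theory gross flux \eqn{f_{ij} = \pi_i q^-_i T_{ij}
#' q^+_j} (i != j), net flux \eqn{f^+_{ij} = \max(f_{ij} - f_{ji}, 0)} and
#' total A->B flux (the net flux out of the source set). The net flux has
#' zero divergence at intermediate states.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param tpt a \code{\linkS4class{TptResult}} holding the committors.
#' @return the \code{TptResult} with flux slots filled.
#' @export
reactiveFlux <- function(model, tpt) {
    Tm <- model@transition
    n <- nrow(Tm)
    pi <- model@stationary
    f <- (pi * tpt@qMinus) * Tm * rep(tpt@qPlus, each = n)
    diag(f) <- 0
    net <- pmax(f - t(f), 0)
    ia <- .tptIdx(model, tpt@A, "A")
    tot <- sum(net[ia, , drop = FALSE]) - sum(net[, ia, drop = FALSE])
    tpt@flux <- f
    tpt@netFlux <- net
    tpt@totalFlux <- tot
    tpt
}

# widest (max-bottleneck) path from any state in src to any in dst under
# capacities W; deterministic lexicographic tie-break.  Returns 1-based path.
.widestPath <- function(W, src, dst) {
    n <- nrow(W)
    width <- rep(-Inf, n)
    prev <- rep(NA_integer_, n)
    width[src] <- Inf
    visited <- rep(FALSE, n)
    repeat {
        cand <- which(!visited & width > 0)
        if (!length(cand)) break
        u <- cand[order(-width[cand], cand)][1]
        visited[u] <- TRUE
        if (u %in% dst) break
        for (v in which(W[u, ] > 0)) {
            wv <- min(width[u], W[u, v])
            if (wv > width[v]) {
                width[v] <- wv
                prev[v] <- u
            }
        }
    }
    reached <- dst[visited[dst]]
    if (!length(reached)) return(NULL)
    end <- reached[1]
    path <- end
    while (!is.na(prev[end])) {
        end <- prev[end]
        path <- c(end, path)
    }
    list(path = path, width = width[path[length(path)]])
}

#' Decompose the net reactive flux into pathways
#'
#' Iterative bottleneck decomposition: repeatedly find the A->B path whose
#' minimum edge flux is maximal, record it with that bottleneck flux,
#' subtract the flux along the path and continue until the accumulated
#' fraction reaches \code{stopFraction} (or no path remains). Each
#' iteration strictly decreases the remaining flux, so the loop terminates;
#' ties between paths are broken by lexicographic state order.
#'
#' @param tpt a \code{\linkS4class{TptResult}} with fluxes.
#' @param stopFraction stop once this fraction of the total flux is
#'   decomposed (default 0.999).
#' @param maxPaths safety cap on the number of paths.
#' @return the \code{TptResult} with \code{pathways} (data.frame:
#'   \code{path}, \code{flux}, \code{fraction}, non-increasing) and
#'   \code{residualFraction} filled.
#' @export
decomposePathways <- function(tpt, stopFraction = 0.999, maxPaths = 10000) {
    W <- tpt@netFlux
    src <- tpt@A + 1L
    dst <- tpt@B + 1L
    tot <- tpt@totalFlux
    paths <- list()
    acc <- 0
    while (acc / tot < stopFraction && length(paths) < maxPaths) {
        wp <- .widestPath(W, src, dst)
        if (is.null(wp) || wp$width <= 0) break
        for (k in seq_len(length(wp$path) - 1L))
            W[wp$path[k], wp$path[k + 1L]] <-
                W[wp$path[k], wp$path[k + 1L]] - wp$width
        acc <- acc + wp$width
        paths[[length(paths) + 1L]] <- data.frame(
            path = paste(wp$path - 1L, collapse = "->"),
            flux = wp$width, fraction = wp$width / tot)
    }
    tpt@pathways <- if (length(paths)) do.call(rbind, paths) else
        data.frame(path = character(), flux = numeric(),
                   fraction = numeric())
    tpt@residualFraction <- max(1 - acc / tot, 0)
    tpt
}

#' Extract transition paths and their durations from a trajectory
#'
#' Scans a labeled trajectory for reactive segments: each time the
#' trajectory leaves one core set and next enters the other, the duration
#' from the last frame inside the departed core to the first frame inside
#' the entered core is recorded (A->B and B->A pooled, direction noted).
#' Core membership is strict set membership of the state ids. Also reports
#' the total time assigned to each core under last-visited-core labeling and
#' the corresponding exit rates, so a Kramers-type barrier can be estimated
#' from (rate, mean transition path time).
#'
#' @param traj a \code{\linkS4class{StateTraj}} (for continuous data first
#'   label the frames, e.g. with \code{\link{coreLabels}}).
#' @param A,B disjoint 0-based core state sets.
#' @return list: \code{durations} (data.frame: direction, duration),
#'   \code{meanTpt}, \code{rangeTpt}, \code{nAB}, \code{nBA},
#'   \code{timeInA}, \code{timeInB}, \code{rateAB}, \code{rateBA}. Empty
#'   sample (no transitions) gives zero counts and NA statistics.
#' @export
extractTransitionPaths <- function(traj, A, B) {
    stopifnot(is(traj, "StateTraj"))
    if (length(intersect(A, B))) stop("A and B must be disjoint")
    s <- traj@states
    dt <- traj@dt
    lab <- ifelse(s %in% A, 1L, ifelse(s %in% B, 2L, 0L))
    durations <- list()
    cur <- 0L          # current core (0 = none yet)
    lastIn <- NA_integer_
    timeIn <- c(0, 0)  # frames assigned by last-visited core
    for (t in seq_along(lab)) {
        if (cur > 0L) timeIn[cur] <- timeIn[cur] + 1
        if (lab[t] == 0L) next
        if (cur == 0L) {
            cur <- lab[t]
        } else if (lab[t] != cur) {
            durations[[length(durations) + 1L]] <- data.frame(
                direction = if (cur == 1L) "A->B" else "B->A",
                duration = (t - lastIn) * dt)
            cur <- lab[t]
        }
        lastIn <- t
    }
    d <- if (length(durations)) do.call(rbind, durations) else
        data.frame(direction = character(), duration = numeric())
    nAB <- sum(d$direction == "A->B")
    nBA <- sum(d$direction == "B->A")
    tA <- timeIn[1] * dt
    tB <- timeIn[2] * dt
    list(durations = d,
         meanTpt = if (nrow(d)) mean(d$duration) else NA_real_,
         rangeTpt = if (nrow(d)) range(d$duration) else c(NA_real_, NA_real_),
         nAB = nAB, nBA = nBA, timeInA = tA, timeInB = tB,
         rateAB = if (tA > 0) nAB / tA else NA_real_,
         rateBA = if (tB > 0) nBA / tB else NA_real_)
}

#' Label continuous frames by core membership
#'
#' Assigns each frame of a feature trajectory to core A (state 0), core B
#' (state 1) or neither (state 2) by Euclidean distance to the core centers.
#'
#' @param ftraj a \code{\linkS4class{FeatureTraj}}.
#' @param centerA,centerB core centers (length-2).
#' @param radius core radius (same for both cores unless length 2).
#' @return a \code{\linkS4class{StateTraj}} with nStates = 3.
#' @export
coreLabels <- function(ftraj, centerA, centerB, radius) {
    stopifnot(is(ftraj, "FeatureTraj"))
    radius <- rep_len(radius, 2)
    X <- ftraj@coords
    dA <- sqrt((X[, 1] - centerA[1])^2 + (X[, 2] - centerA[2])^2)
    dB <- sqrt((X[, 1] - centerB[1])^2 + (X[, 2] - centerB[2])^2)
    s <- ifelse(dA <= radius[1], 0L, ifelse(dB <= radius[2], 1L, 2L))
    stateTraj(s, dt = ftraj@dt, nStates = 3L)
}

#' Reorder the states of a model by committor
#'
#' Permutes the active states so that forward committors are ascending
#' (source states first, sink states last); the spectrum is untouched by
#' this similarity transform.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param tpt the \code{\linkS4class{TptResult}} for the same model.
#' @return list: \code{model} (permuted), \code{perm} (1-based permutation
#'   applied to the active states).
#' @export
orderStatesByCommittor <- function(model, tpt) {
    perm <- order(tpt@qPlus, seq_along(tpt@qPlus))
    m <- model
    m@counts <- model@counts[perm, perm, drop = FALSE]
    m@transition <- model@transition[perm, perm, drop = FALSE]
    m@stationary <- model@stationary[perm]
    m@rightVectors <- model@rightVectors[perm, , drop = FALSE]
    m@leftVectors <- model@leftVectors[perm, , drop = FALSE]
    m@active <- model@active[perm]
    list(model = m, perm = perm)
}
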