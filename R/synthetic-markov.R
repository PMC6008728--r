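#' Specify a discrete-state trajectory generator
#'
#' Either a row-stochastic transition matrix \code{T} at step \code{dt}, or a
#' rate matrix \code{K} (off-diagonal >= 0, rows summing to zero) from which
#' the step transition matrix is obtained as \code{expm(K dt)}.
#'
#' @param T row-stochastic transition matrix (rows sum to 1 within 1e-12).
#' @param K rate matrix in 1/s (rows sum to 0 within 1e-12); ignored when
#'   \code{T} is given.
#' @param dt time step (s).
#' @return a list with elements \code{T}, \code{dt}, \code{nStates}.
#' @examples
#' spec <- markovGeneratorSpec(T = rbind(c(0.9, 0.1), c(0.3, 0.7)), dt = 1e-9)
#' @export
markovGeneratorSpec <- function(T = NULL, K = NULL, dt) {
    if (is.null(T)) {
        if (is.null(K)) stop("supply either T or K")
        if (max(abs(rowSums(K))) > 1e-12 * max(1, max(abs(K))))
            stop("rate matrix rows must sum to 0")
        if (any(K[row(K) != col(K)] < 0))
            stop("off-diagonal rates must be >= 0")
        T <- pracma::expm(K * dt)
        T[T < 0] <- 0
        T <- T / rowSums(T)
    }
    if (nrow(T) != ncol(T)) stop("transition matrix must be square")
    if (max(abs(rowSums(T) - 1)) > 1e-12)
        stop("transition matrix rows must sum to 1 within 1e-12")
    if (any(T < 0)) stop("transition probabilities must be >= 0")
    if (dt <= 0) stop("dt must be > 0")
    list(T = T, dt = dt, nStates = nrow(T))
}

#' Sample a discrete Markov-chain trajectory
#'
#' Draws an exact realisation of the Markov chain defined by a generator
#' specification; used to give the MSM estimators data with known truth.
#'
#' @param spec a generator from \code{\link{markovGeneratorSpec}}.
#' @param nSteps trajectory length in frames (>= 1).
#' @param seed integer seed; same seed, same trajectory.
#' @param start 0-based starting state id.
#' @return a \code{\linkS4class{StateTraj}}.
#' @examples
#' spec <- markovGeneratorSpec(T = rbind(c(0.9, 0.1), c(0.3, 0.7)), dt = 1e-9)
#' tr <- simulateMarkovChain(spec, nSteps = 1000, seed = 1, start = 0)
#' @export
simulateMarkovChain <- function(spec, nSteps, seed, start = 0L) {
    if (nSteps < 1) stop("nSteps must be >= 1")
    start <- as.integer(start)
    if (start < 0L || start >= spec$nStates)
        stop("start state outside 0..nStates-1")
    set.seed(as.integer(seed))
    s <- .markov_chain_cpp(spec$T, as.integer(nSteps), start)
    new("StateTraj", states = s, dt = spec$dt,
        nStates = as.integer(spec$nStates))
}

#' Sample several Markov-chain trajectories
#'
#' Convenience wrapper drawing \code{n} independent trajectories with
#' consecutive sub-seeds derived from \code{seed}.
#'
#' @param spec generator specification.
#' @param n number of trajectories.
#' @param nSteps frames per trajectory.
#' @param seed base seed; trajectory i uses seed + i - 1.
#' @param start 0-based start state, recycled across trajectories.
#' @return list of \code{\linkS4class{StateTraj}}.
#' @export
simulateMarkovChains <- function(spec, n, nSteps, seed, start = 0L) {
    start <- rep_len(as.integer(start), n)
    lapply(seq_len(n), function(i)
        simulateMarkovChain(spec, nSteps, seed = as.integer(seed) + i - 1L,
                            start = start[i]))
}

#' A 19-state metastable generator mirroring a two-conformer protein
#'
#' Builds a reversible 19-state transition matrix with one minor metastable
#' state (state 0, "E"), a cluster of four fast-mixing major states
#' (15-18, "B"), transient intermediates along three cross-linked parallel
#' pathways, two dead-end kinetic traps and six major-basin satellites. The
#' global scale of the connecting rates is calibrated so that the slowest
#' relaxation time equals \code{t2} exactly, and the stationary weights are
#' set so the minor fraction pi(E)/(pi(E)+pi(B)) equals \code{pE}. Defaults
#' mirror the conditions of an E<->B protein interconversion with t2 = 3 us
#' and pE = 1.4\% analysed at a 22.5 ns lag.
#'
#' @param t2 target slowest implied timescale (s).
#' @param pE target minor-state fraction among E and B states.
#' @param dt generator time step (s); frames are saved finer than the
#'   natural 22.5 ns estimation lag, as for saved MD frames.
#' @return list with the generator \code{spec}, the transition matrix
#'   \code{T} at step dt, stationary vector \code{pi}, exact slowest
#'   timescale \code{t2}, exact \code{kex} = 1/t2, exact \code{pE}, the
#'   state sets \code{Eset}, \code{Bset} (0-based ids) and the recommended
#'   \code{lagSteps} corresponding to a 22.5 ns lag.
#' @export
nineteenStateModel <- function(t2 = 3e-6, pE = 0.014, dt = 2.25e-9) {
    n <- 19L
    # stationary weights: state 0 minor metastable, 15-18 the fast-mixing
    # major basin, 1-8 pathway intermediates (7 and 8 are dead-end kinetic
    # traps), 9-14 major-basin satellites
    piB <- c(0.40, 0.25, 0.18, 0.14)
    piI <- rep(6e-4, 14)
    piI[c(2, 4, 6)] <- 6e-3       # path states adjacent to the major basin
    piI[c(7, 8)] <- 4e-3          # traps hanging off states 1 and 4
    piI[9:14] <- 2e-3
    pi0 <- pE / (1 - pE) * sum(piB)
    pi <- c(pi0, piI, piB)
    pi <- pi / sum(pi)
    # conductance network: edge (i, j) with symmetric weight S gives rates
    # k_ij = S/pi_i, k_ji = S/pi_j, so detailed balance holds exactly.
    # Three parallel E->B pathways (cross-linked), faster edges where the
    # paths join the major basin, trap branches, satellites, fast basin
    # mixing.
    edges <- rbind(
        c(0, 1, 1), c(1, 2, 1), c(2, 15, 20),
        c(0, 3, 1), c(3, 4, 1), c(4, 16, 20),
        c(0, 5, 1), c(5, 6, 1), c(6, 17, 20),
        c(1, 7, 2), c(4, 8, 2),
        c(1, 4, 0.5),
        cbind(rbind(c(15, 9), c(16, 10), c(17, 11), c(18, 12), c(15, 13),
                    c(16, 14)), 40),
        cbind(rbind(c(15, 16), c(16, 17), c(17, 18), c(15, 18), c(15, 17)),
              100))
    buildK <- function(scale) {
        K <- matrix(0, n, n)
        for (e in seq_len(nrow(edges))) {
            i <- edges[e, 1] + 1L; j <- edges[e, 2] + 1L
            s <- edges[e, 3] * scale
            K[i, j] <- s / pi[i]
            K[j, i] <- s / pi[j]
        }
        diag(K) <- -rowSums(K)
        K
    }
    # slowest relaxation time from the rate-matrix spectrum (well
    # conditioned, unlike log of an eigenvalue close to 1)
    slowest <- function(K) {
        d <- sqrt(pi)
        Ks <- K * d / rep(d, each = n)
        Ks <- (Ks + t(Ks)) / 2
        mu <- sort(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
        -1 / mu[2]
    }
    # all rates scale linearly, so t2(scale) = t2(1)/scale exactly
    sc <- slowest(buildK(1)) / t2
    K <- buildK(sc)
    T <- pracma::expm(K * dt)
    # make detailed balance exact: symmetrize the stationary flux and let
    # the stationary vector absorb the (1e-9-level) renormalisation
    F <- (pi * T + t(pi * T)) / 2
    F[F < 0] <- 0
    rs <- rowSums(F)
    T <- F / rs
    pi <- rs / sum(rs)
    t2x <- slowest(K)
    list(spec = markovGeneratorSpec(T = T, dt = dt), T = T, pi = pi,
         t2 = t2x, kex = 1 / t2x,
         pE = pi[1] / (pi[1] + sum(pi[16:19])),
         Eset = 0L, Bset = 15:18,
         lagSteps = as.integer(round(22.5e-9 / dt)))
}
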