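test_that("committors solve their boundary-value problem", {
    # symmetric 3-state chain: the intermediate is the transition state
    T3 <- rbind(c(0.8, 0.2, 0), c(0.3, 0.4, 0.3), c(0, 0.2, 0.8))
    m <- exactCountModel(T3)
    tpt <- committors(m, A = 0L, B = 2L)
    expect_equal(forwardCommittor(tpt), c(0, 0.5, 1))
    # gambler's-ruin closed form on an unbiased chain
    N <- 7
    mg <- exactCountModel(gamblersChain(N))
    tg <- committors(mg, A = 0L, B = as.integer(N))
    expect_equal(forwardCommittor(tg), (0:N) / N, tolerance = 1e-9)
    # backward committor of a reversible chain is the complement
    expect_equal(backwardCommittor(tg), 1 - forwardCommittor(tg),
                 tolerance = 1e-10)
    expect_error(committors(mg, A = 0L, B = 0L), "disjoint")
    # intermediates that can only reach the sink through the source have a
    # vanishing forward committor
    Tu <- rbind(c(0.4, 0.5, 0.1, 0), c(0.5, 0.5, 0, 0),
                c(0.2, 0, 0.4, 0.4), c(0, 0, 0.5, 0.5))
    tu <- committors(exactCountModel(Tu), A = 0L, B = 1L)
    expect_equal(forwardCommittor(tu)[3:4], c(0, 0), tolerance = 1e-12)
})

test_that("reactive flux is conserved and matches the chain closed form", {
    set.seed(3)
    n <- 5
    p <- runif(n - 1, 0.1, 0.4)
    q <- runif(n - 1, 0.1, 0.4)
    Tm <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
        Tm[i, i + 1] <- p[i]
        Tm[i + 1, i] <- q[i]
    }
    diag(Tm) <- 1 - rowSums(Tm)
    m <- exactCountModel(Tm)
    tpt <- committors(m, A = 0L, B = as.integer(n - 1))
    # electrical-network closed form for a birth-death chain:
    # F = 1 / sum_i 1/(pi_i p_i)
    pi <- stationaryDistribution(m)
    Fb <- 1 / sum(1 / (pi[1:(n - 1)] * m@transition[cbind(1:(n - 1), 2:n)]))
    expect_equal(totalFlux(tpt), Fb, tolerance = 1e-9)
    # zero divergence at intermediates
    net <- netFluxMatrix(tpt)
    div <- rowSums(net) - colSums(net)
    expect_lt(max(abs(div[2:(n - 1)])), 1e-12)
    expect_true(all(tpt@flux >= 0))
})

test_that("bottleneck decomposition accounts for the flux deterministically", {
    # single linear chain: one path carrying everything
    T3 <- rbind(c(0.8, 0.2, 0), c(0.3, 0.4, 0.3), c(0, 0.2, 0.8))
    t1 <- decomposePathways(committors(exactCountModel(T3), 0L, 2L))
    expect_equal(nrow(pathways(t1)), 1)
    expect_equal(pathways(t1)$fraction, 1, tolerance = 1e-9)
    expect_equal(pathways(t1)$path, "0->1->2")
    # two parallel branches with conductances 3:1
    T4 <- rbind(c(0.6, 0.3, 0.1, 0),
                c(0.3, 0.4, 0, 0.3),
                c(0.3, 0, 0.4, 0.3),
                c(0.05, 0.075, 0.025, 0.85))
    t2 <- decomposePathways(committors(exactCountModel(T4), 0L, 3L))
    expect_equal(pathways(t2)$fraction, c(0.75, 0.25), tolerance = 1e-6)
    expect_equal(pathways(t2)$path, c("0->1->3", "0->2->3"))
    # fractions are non-increasing and the residual is below the stop level
    gen <- nineteenStateModel()
    mg <- exactCountModel(gen$T, scale = 1e9)
    tg <- decomposePathways(committors(mg, gen$Eset, gen$Bset))
    expect_true(all(diff(pathways(tg)$fraction) <= 1e-12))
    expect_lt(tg@residualFraction, 0.001)
    expect_gt(nrow(pathways(tg)), 1)
})

test_that("transition paths are clipped to the barrier-crossing segment", {
    # A,A,I,I,I,B with unit steps: one A->B path of duration 4
    tr <- stateTraj(c(0, 0, 2, 2, 2, 1), dt = 1, nStates = 3L)
    tp <- extractTransitionPaths(tr, A = 0L, B = 1L)
    expect_equal(nrow(tp$durations), 1)
    expect_equal(tp$durations$duration, 4)
    expect_equal(tp$durations$direction, "A->B")
    # a trajectory that never reaches B yields an empty, well-formed sample
    tr2 <- stateTraj(c(0, 2, 0, 2, 0), dt = 1, nStates = 3L)
    tp2 <- extractTransitionPaths(tr2, A = 0L, B = 1L)
    expect_equal(nrow(tp2$durations), 0)
    expect_equal(tp2$nAB + tp2$nBA, 0)
    expect_true(is.na(tp2$meanTpt))
})

test_that("barrier crossings are much faster than basin waiting times", {
    dw <- doubleWellPotential()
    pb <- potentialBarrier(dw)
    tr <- simulateLangevin(dw, dt = 0.001, nSteps = 2e6, seed = 3,
                           x0 = c(-1, 0))
    lab <- coreLabels(tr, pb$minima[1, ], pb$minima[2, ], radius = 0.45)
    tp <- extractTransitionPaths(lab, A = 0L, B = 1L)
    expect_gt(tp$nAB + tp$nBA, 20)
    wait <- (tp$timeInA + tp$timeInB) / (tp$nAB + tp$nBA)
    expect_lt(tp$meanTpt / wait, 0.05)
})

test_that("committor ordering permutes states without touching the spectrum", {
    N <- 5
    m <- exactCountModel(gamblersChain(N))
    tpt <- committors(m, A = as.integer(N), B = 0L)  # committor decreasing
    ord <- orderStatesByCommittor(m, tpt)
    expect_equal(ord$perm, (N + 1):1)
    expect_equal(sort(Re(ord$model@eigenvalues)),
                 sort(Re(m@eigenvalues)), tolerance = 1e-12)
    # already ordered: identity permutation
    t2 <- committors(m, A = 0L, B = as.integer(N))
    expect_equal(orderStatesByCommittor(m, t2)$perm, 1:(N + 1))
})

test_that("deeper intermediate traps spread the flux over more pathways", {
    countPaths <- function(trapScale) {
        pot <- ruggedPotential(trapScale)
        tr <- simulateLangevin(pot, dt = 0.001, nSteps = 4e6, seed = 21,
                               x0 = c(-1.3, 0), stride = 4)
        am <- assignMicrostates(tr, 40, seed = 31)
        m <- suppressMessages(buildMsm(am$trajs, 5, reversible = TRUE))
        dA <- colSums((t(am$centers) - c(-1.3, 0))^2)
        dB <- colSums((t(am$centers) - c(1.3, 0))^2)
        A <- m@active[match(which.min(dA) - 1L, m@active)]
        B <- m@active[match(which.min(dB) - 1L, m@active)]
        tpt <- decomposePathways(committors(m, A, B), stopFraction = 0.75)
        nrow(pathways(tpt))
    }
    base <- countPaths(1)
    deep <- countPaths(2)
    expect_gt(base, 1)
    expect_gt(deep, base)
})
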