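test_that("count matrices enumerate lagged pairs within trajectories", {
    t1 <- stateTraj(c(0, 0, 0), dt = 1, nStates = 1L)
    expect_equal(countMatrix(t1, 1), matrix(2L, 1, 1))
    t2 <- stateTraj(c(0, 1, 0, 1), dt = 1, nStates = 2L)
    C <- countMatrix(t2, 1)
    expect_equal(C[1, 2], 2L)
    expect_equal(C[2, 1], 1L)
    C2 <- countMatrix(t2, 2)
    expect_equal(diag(C2), c(1L, 1L))
    expect_equal(sum(C2), 2L)
    # strided counting advances by the lag
    t3 <- stateTraj(c(0, 1, 0, 1, 0), dt = 1, nStates = 2L)
    expect_equal(sum(countMatrix(t3, 2, mode = "strided")), 2L)
    expect_error(countMatrix(t1, 5), "no counts")
    # trajectories are never concatenated
    Cs <- countMatrix(list(stateTraj(c(0, 0), 1, 2L),
                           stateTraj(c(1, 1), 1, 2L)), 1)
    expect_equal(Cs[1, 2], 0L)
})

test_that("transition matrix estimators match hand linear algebra", {
    C <- rbind(c(8, 2), c(1, 9))
    m <- transitionModel(C, dt = 1, lagSteps = 1, reversible = FALSE)
    expect_equal(m@transition, rbind(c(0.8, 0.2), c(0.1, 0.9)))
    expect_equal(m@stationary, c(1, 2) / 3, tolerance = 1e-12)
    # symmetric counts: both estimators coincide
    Cs <- rbind(c(8, 2), c(2, 12))
    mr <- transitionModel(Cs, 1, 1, reversible = TRUE)
    mn <- transitionModel(Cs, 1, 1, reversible = FALSE)
    expect_equal(mr@transition, mn@transition)
    # detailed balance holds for the reversible estimator by construction
    m2 <- transitionModel(rbind(c(50, 3, 1), c(7, 60, 2), c(2, 4, 80)),
                          1, 1, reversible = TRUE)
    F <- m2@stationary * m2@transition
    expect_equal(F, t(F), tolerance = 1e-12)
    expect_true(all(abs(Im(m2@eigenvalues)) < 1e-12))
    expect_true(all(diff(Re(m2@eigenvalues)) <= 1e-12))
    expect_true(all(m2@stationary > 0))
})

test_that("ergodic trimming restricts to the largest connected component", {
    C <- rbind(c(10, 2, 0), c(3, 10, 0), c(0, 0, 5))
    expect_message(m <- transitionModel(C, 1, 1), "trimm")
    expect_equal(m@active, c(0L, 1L))
    expect_equal(m@trimmed, 2L)
})

test_that("implied timescales follow the spectrum and scale invariances", {
    # two-state closed form at a 22.5 (ns) lag: t2 = -22.5/log(0.6)
    Tg <- rbind(c(0.9, 0.1), c(0.3, 0.7))
    m <- exactCountModel(Tg, dt = 22.5, lagSteps = 1)
    expect_equal(m@timescales[1], Inf)
    expect_equal(m@timescales[2], -22.5 / log(0.6), tolerance = 1e-6)
    # duplication of the data leaves timescales untouched
    tr <- simulateMarkovChain(markovGeneratorSpec(T = Tg, dt = 22.5),
                              5000, seed = 12, start = 0)
    one <- buildMsm(tr, 1)
    two <- buildMsm(list(tr, tr), 1)
    expect_equal(one@timescales, two@timescales, tolerance = 1e-12)
    # constant trajectory: only the infinite equilibrium timescale remains
    cst <- buildMsm(stateTraj(rep(0L, 50), 1, 1L), 1)
    expect_equal(cst@timescales, Inf)
    # lag table
    it <- impliedTimescales(tr, c(1, 2, 4), nTimescales = 2)
    expect_equal(nrow(it), 6)
    t2s <- it$timescale[it$index == 2]
    expect_lt(max(abs(t2s - t2s[1])) / t2s[1], 0.25)  # flat in lag
})

test_that("population propagation matches stepwise multiplication", {
    Tg <- rbind(c(0.9, 0.08, 0.02), c(0.2, 0.7, 0.1), c(0.05, 0.15, 0.8))
    m <- exactCountModel(Tg, scale = 1e8)
    p0 <- c(1, 0, 0)
    expect_equal(propagatePopulations(m, p0, 0), p0)
    step <- p0
    for (i in 1:7) step <- as.numeric(step %*% m@transition)
    expect_equal(propagatePopulations(m, p0, 7), step, tolerance = 1e-12)
    expect_equal(sum(propagatePopulations(m, p0, 50)), 1, tolerance = 1e-12)
    expect_equal(propagatePopulations(m, m@stationary, 13), m@stationary,
                 tolerance = 1e-10)
})

test_that("metastable blocks are recovered by eigenvector lumping", {
    eps <- 0.01
    Tb <- rbind(c(0.7 - eps, 0.3, eps, 0),
                c(0.3, 0.7 - eps, 0, eps),
                c(eps, 0, 0.7 - eps, 0.3),
                c(0, eps, 0.3, 0.7 - eps))
    m <- exactCountModel(Tb, reversible = TRUE, scale = 1e5)
    l <- lumpMacrostates(m, 2)
    expect_equal(l@assignment, c(0L, 0L, 1L, 1L))
    expect_equal(sum(l@weights), 1)
    # full-resolution lumping is the identity partition
    l4 <- lumpMacrostates(m, 4)
    expect_equal(sort(unique(l4@assignment)), 0:3)
    # every microstate belongs to exactly one macrostate
    expect_length(l@assignment, 4)
})

test_that("Chapman-Kolmogorov holds for Markov data and fails for hidden states", {
    gen <- markovGeneratorSpec(T = rbind(c(0.95, 0.05), c(0.1, 0.9)), dt = 1)
    trs <- simulateMarkovChains(gen, 20, 5000, seed = 9, start = 0)
    m <- buildMsm(trs, 1, reversible = FALSE)
    ck <- ckTest(trs, m, sets = list(0L, 1L), nList = c(1, 5, 10))
    expect_equal(ck$deviation[ck$n == 1], c(0, 0), tolerance = 1e-12)
    expect_true(all(ck$deviation < 0.02))
    # lumping two hidden states with slow internal exchange breaks it
    Th <- rbind(c(0.90, 0.10, 0.00),
                c(0.20, 0.78, 0.02),
                c(0.00, 0.02, 0.98))
    hid <- simulateMarkovChains(markovGeneratorSpec(T = Th, dt = 1),
                                20, 20000, seed = 3, start = 0)
    obs <- lapply(hid, function(t) stateTraj(pmin(t@states, 1L), 1, 2L))
    mo <- buildMsm(obs, 1, reversible = FALSE)
    ckh <- ckTest(obs, mo, sets = list(0L, 1L), nList = 50)
    expect_true(all(ckh$deviation > 0.03))
})

test_that("superposition removes rigid-body differences exactly", {
    X <- matrix(rnorm(30, sd = 2), ncol = 3)
    expect_equal(kabschRmsd(X, X), 0)
    th <- 0.8
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    Y <- X %*% t(R) + rep(c(3, -1, 7), each = 10)
    expect_lt(kabschRmsd(X, Y), 1e-10)
    expect_error(kabschRmsd(X, X[1:5, ]), "differ in size")
    # single displaced atom: brute-force quaternion search oracle
    Z <- X
    Z[1, ] <- Z[1, ] + c(1.5, -0.5, 0.7)
    quatRot <- function(q) {
        q <- q / sqrt(sum(q^2))
        w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
        rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
              c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
              c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
    }
    Xc <- scale(X, scale = FALSE); Zc <- scale(Z, scale = FALSE)
    obj <- function(q) sqrt(mean(rowSums((Xc - Zc %*% t(quatRot(q)))^2)))
    set.seed(7)
    best <- min(vapply(1:200, function(i)
        stats::optim(rnorm(4), obj, control = list(reltol = 1e-14))$value, 0))
    expect_equal(kabschRmsd(X, Z), best, tolerance = 1e-6)
})

test_that("two-state reduction returns the model's own rate and population", {
    Tg <- rbind(c(0.9, 0.1), c(0.3, 0.7))
    m <- exactCountModel(Tg, dt = 22.5e-9, lagSteps = 1)
    red <- twoStateReduction(m, Eset = 0L, Bset = 1L)
    expect_equal(red$kex, 1 / m@timescales[2], tolerance = 1e-9)
    expect_equal(red$pE, 0.75, tolerance = 1e-6)
    expect_error(twoStateReduction(m, 0L, 0L), "disjoint")
    # restricting to a subset of states still uses the restricted ratio
    gen <- nineteenStateModel()
    mg <- exactCountModel(gen$T, dt = gen$spec$dt, lagSteps = 1,
                          scale = 1e9)
    redg <- twoStateReduction(mg, gen$Eset, gen$Bset)
    expect_equal(redg$pE, gen$pE, tolerance = 1e-3)
    expect_equal(redg$kex, gen$kex, tolerance = 0.01)
})

test_that("free-energy surfaces reproduce occupancy ratios and potentials", {
    # single microstate: surface reduces to the raw histogram
    n1 <- 2718L; n2 <- 1000L
    xy <- cbind(c(rep(-1, n1), rep(1, n2)), 0)
    ft <- new("FeatureTraj", coords = xy, dt = 1)
    st <- stateTraj(rep(0L, n1 + n2), dt = 1, nStates = 1L)
    # uniform occupancy over two bins: no free-energy difference
    xyu <- cbind(rep(c(-1, 1), each = 500), 0)
    stu <- stateTraj(rep(0L, 1000), 1, 1L)
    m1 <- suppressMessages(transitionModel(matrix(c(10L), 1, 1), 1, 1))
    fes_u <- freeEnergySurface(new("FeatureTraj", coords = xyu, dt = 1),
                               stu, m1, bins = c(2, 2))
    Fu <- fes_u$F[is.finite(fes_u$F)]
    expect_equal(max(Fu) - min(Fu), 0, tolerance = 1e-12)
    # occupancy ratio e:1 across two bins: dF = 1 kT
    fes <- freeEnergySurface(ft, st, m1, bins = c(2, 2))
    Fv <- sort(fes$F[is.finite(fes$F)])
    expect_equal(Fv[2] - Fv[1], log(n1 / n2), tolerance = 1e-12)
    expect_equal(Fv[2] - Fv[1], 1, tolerance = 1e-3)
})

test_that("surfaces from Langevin sampling recover the constructed basins", {
    pot <- potentialSpec(centers = rbind(c(-1, 0), c(1, 0)),
                         depths = c(6, 7), widths = c(0.5, 0.5), kconf = 1)
    truth <- potentialFreeEnergyDifference(pot)
    tr <- simulateLangevin(pot, dt = 0.001, nSteps = 3e6, seed = 11,
                           x0 = c(1, 0), stride = 3)
    am <- assignMicrostates(tr, 30, seed = 5)
    m <- suppressMessages(buildMsm(am$trajs, 5, reversible = TRUE))
    fes <- freeEnergySurface(tr, am$trajs, m, bins = 50)
    P <- exp(-fes$F)
    P[!is.finite(fes$F)] <- 0
    P <- P / sum(P)
    dF <- -log(sum(P[fes$x < 0, ]) / sum(P[fes$x >= 0, ]))
    expect_lt(abs(dF - truth), 0.3)
    # 1D projections carry probability, not free energy
    pX <- exp(-fes$pmfX$F)
    expect_equal(-log(sum(pX[fes$pmfX$x < 0]) / sum(pX[fes$pmfX$x >= 0])),
                 dF, tolerance = 1e-9)
})

test_that("microstate assignment separates well-resolved density modes", {
    set.seed(2)
    X <- rbind(matrix(rnorm(2000, -3, 0.3), ncol = 2),
               matrix(rnorm(2000, 3, 0.3), ncol = 2))
    ft <- new("FeatureTraj", coords = X, dt = 1)
    am <- assignMicrostates(ft, 2, seed = 4)
    s <- am$trajs[[1]]@states
    purity <- max(mean(s[1:1000] == s[1]), mean(s[1:1000] != s[1]))
    expect_equal(purity, 1)
    expect_identical(assignMicrostates(ft, 2, seed = 4)$centers, am$centers)
    expect_equal(length(unique(assignMicrostates(ft, 1, seed = 1)$
                                   trajs[[1]]@states)), 1)
    expect_error(assignMicrostates(ft, nrow(X) + 1, seed = 1), "exceeds")
})
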