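test_that("intensity-to-rate conversion matches the closed form", {
    expect_equal(r2effFromIntensities(1, 1, 0.02), 0)
    expect_equal(r2effFromIntensities(exp(-1), 1, 0.02), 50)
    expect_equal(r2effFromIntensities(exp(-1.5), 1, 0.03), 50)
    expect_error(r2effFromIntensities(0, 1, 0.02), "non-positive")
    expect_error(r2effFromIntensities(1, -2, 0.02), "non-positive")
})

test_that("propagator reduces to R2,0 without a minor state or shift", {
    nu <- c(50, 250, 1000)
    expect_equal(simulateR2effBM(2000, 0, 2, 11, nu = nu, tCpmg = 0.02),
                 rep(11, 3), tolerance = 1e-12)
    expect_equal(simulateR2effBM(2000, 0.03, 0, 11, nu = nu, tCpmg = 0.02),
                 rep(11, 3), tolerance = 1e-12)
})

test_that("fast-exchange propagation matches the Luz-Meiboom closed form", {
    nu <- nuGrid()
    bm <- simulateR2effBM(20000, 0.03, 1, 8, "15N", 11.7, nu, 0.02)
    lm <- luzMeiboom(20000, 0.03, 1, 8, "15N", 11.7, nu)
    expect_lt(max(abs(bm - lm) / lm), 0.01)
})

test_that("incommensurate pulse trains are rejected, not rounded", {
    expect_error(simulateR2effBM(2000, 0.03, 2, 10, nu = 33.3, tCpmg = 0.02),
                 "incommensurate")
})

test_that("R2,eff is non-increasing in refocusing frequency", {
    for (kex in c(500, 2000, 10000)) for (dw in c(0.5, 2, 4)) {
        r <- simulateR2effBM(kex, 0.03, dw, 10, nu = nuGrid(), tCpmg = 0.02)
        expect_true(all(diff(r) <= 1e-9))
    }
})

test_that("the infinite-frequency limit restores the intrinsic rate", {
    for (kex in c(1000, 5000, 10000)) {
        r <- simulateR2effBM(kex, 0.05, 2, 10, nu = 1e4, tCpmg = 0.02)
        expect_lt(abs(r - 10) / 10, 0.01)
    }
})

test_that("slow-exchange dispersion plateaus at the forward rate", {
    # kex << dw, nu at its minimum, long T_cpmg so amplitude terms vanish
    kex <- 50; pE <- 0.02
    r <- simulateR2effBM(kex, pE, 4, 10, "15N", 11.7, nu = 2.5, tCpmg = 0.4)
    kBE <- pE * kex
    expect_lt(abs((r - 10) - kBE) / kBE, 0.1)
})

test_that("Carver-Richards closed form handles its degenerate branch", {
    expect_equal(carverRichardsR2eff(2000, 0.03, 0, 10, nu = c(100, 500)),
                 rep(10, 2))
    expect_equal(carverRichardsR2eff(2000, 0, 2, 10, nu = 100), 10)
    # slow-exchange plateau: R2,eff - R2,0 -> kBE as nu -> small
    kex <- 100; pE <- 0.05
    cr <- carverRichardsR2eff(kex, pE, 4, 10, "15N", 11.7, nu = 10)
    expect_lt(abs((cr - 10) - pE * kex) / (pE * kex), 0.05)
})

test_that("propagator and Carver-Richards agree on the cross-oracle grid", {
    # long relaxation delay: both measure the asymptotic decay rate
    worst <- 0
    for (kex in c(500, 2000, 5000, 10000, 20000))
        for (pE in c(0.01, 0.03, 0.05, 0.08, 0.1))
            for (dw in c(0.5, 1, 2, 3, 4)) {
                nu <- c(100, 500, 1000)
                a <- simulateR2effBM(kex, pE, dw, 10, "15N", 11.7, nu, 0.5)
                b <- carverRichardsR2eff(kex, pE, dw, 10, "15N", 11.7, nu)
                worst <- max(worst, max(abs(a - b) / a))
            }
    expect_lt(worst, 0.005)
})
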