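test_that("directional rates follow the minor-state convention", {
    r <- ratesFromKexPe(6100, 0.036)
    expect_equal(r$kBE, 219.6, tolerance = 1e-10)
    expect_equal(r$kEB, 5880.4, tolerance = 1e-10)
    r2 <- ratesFromKexPe(649, 0.047)
    expect_equal(r2$kBE, 30.503, tolerance = 1e-10)
    expect_equal(r2$kEB, 618.497, tolerance = 1e-10)
    r3 <- ratesFromKexPe(1000, 0.5)
    expect_equal(r3$kBE, r3$kEB)
    expect_error(ratesFromKexPe(1000, 1.2), "pE")
    # first-order error propagation
    r4 <- ratesFromKexPe(6100, 0.036, kexSd = 350, pESd = 0.006)
    expect_equal(r4$kBE_sd, sqrt((0.036 * 350)^2 + (6100 * 0.006)^2))
})

test_that("Arrhenius fits reproduce closed forms and round-trip", {
    # two-point closed form
    f <- fitArrhenius(c(300, 310), c(1e3, 1e4))
    expect_equal(f$Ea, 8.314 * log(10) / (1 / 300 - 1 / 310),
                 tolerance = 1e-10)
    # temperature-independent rates: zero activation energy
    f0 <- fitArrhenius(c(280, 290, 300), rep(500, 3))
    expect_equal(f0$Ea, 0, tolerance = 1e-8)
    expect_error(fitArrhenius(c(300, 300), c(1, 2)), "rank-deficient")
    # round trip through extrapolation at five temperatures
    Ts <- seq(274, 294, by = 5)
    k <- exp(25 - 60000 / (8.314 * Ts))
    f2 <- fitArrhenius(Ts, k, kSd = 0.03 * k)
    expect_equal(f2$Ea, 60000, tolerance = 1e-9)
    expect_equal(f2$lnA, 25, tolerance = 1e-9)
    ex <- extrapolateRate(f2, Ts)
    expect_equal(ex$k, k, tolerance = 1e-9)
    # flat fit extrapolates flat
    expect_equal(extrapolateRate(f0, 350)$k, 500, tolerance = 1e-6)
})

test_that("equilibrium thermodynamics are internally consistent", {
    Ts <- seq(274, 294, by = 5)
    fBE <- fitArrhenius(Ts, exp(30 - 66000 / (8.314 * Ts)))
    fEB <- fitArrhenius(Ts, exp(32 - 80000 / (8.314 * Ts)))
    th <- equilibriumThermo(fBE, fEB, c(310.15, 323.15))
    expect_equal(th$dH, -14000)
    # dG = dH - T dS at every temperature
    expect_equal(th$byTemp$dG, th$dH - th$byTemp$temp_K * th$byTemp$dS,
                 tolerance = 1e-9)
    # dG equals -RT log(pE/(1-pE)) with pE from the same rates
    kbe <- extrapolateRate(fBE, 310.15)$k
    keb <- extrapolateRate(fEB, 310.15)$k
    pE <- kbe / (kbe + keb)
    expect_equal(th$byTemp$dG[1], -8.314 * 310.15 * log(pE / (1 - pE)),
                 tolerance = 1e-9)
    # symmetric rates: no thermodynamic difference
    th0 <- equilibriumThermo(fBE, fBE, 310.15)
    expect_equal(th0$dH, 0)
    expect_equal(th0$byTemp$dG, 0, tolerance = 1e-9)
})

test_that("transition-path-time barrier relation and entropy bookkeeping", {
    expect_equal(barrierFromTpt(1 / (2 * 60e-9), 60e-9, 310.15)$dG_kBT, 0)
    b <- barrierFromTpt(897, 60.5e-9, 310.15)
    expect_equal(b$dG_kBT, 9.128, tolerance = 1e-3)
    expect_equal(b$dG_kJmol, 23.54, tolerance = 1e-3)
    expect_false(b$barrierless)
    b2 <- barrierFromTpt(3.81e4, 60.5e-9, 310.15)
    expect_equal(b2$dG_kBT, 5.380, tolerance = 1e-3)
    # barrierless signal instead of an exception
    expect_true(barrierFromTpt(1e7, 60e-9, 310.15)$barrierless)
    # monotone decreasing in both rate and path time
    ks <- c(100, 1000, 10000)
    expect_true(all(diff(vapply(ks, function(k)
        barrierFromTpt(k, 60e-9, 310.15)$dG_kBT, 0)) < 0))
    taus <- c(10e-9, 60e-9, 200e-9)
    expect_true(all(diff(vapply(taus, function(tau)
        barrierFromTpt(1000, tau, 310.15)$dG_kBT, 0)) < 0))
    # activation entropy
    a <- activationEntropy(65000, 25300, 310.15)
    expect_equal(a$dS, 128.0, tolerance = 1e-3)
    expect_equal(a$TdS_kBT, 15.4, tolerance = 1e-2)
    expect_equal(activationEntropy(5e4, 5e4, 300)$dS, 0)
    # lifetimes
    expect_equal(lifetime(1e6), 1e-6)
    expect_equal(lifetime(5880.4) * 1e6, 170.06, tolerance = 1e-4)
    # kBT bookkeeping at 37 degC
    expect_lt(abs(kBT(310.15) - 2.578), 1e-3)
})

test_that("the packaged five-temperature rate series loads coherently", {
    s <- table1Rates()
    expect_equal(nrow(s), 5)
    expect_equal(s$temp_K[1], 274.15)
    expect_equal(s$kBE + s$kEB, s$kex, tolerance = 1e-9)
    expect_equal(s$kBE, s$pE * s$kex, tolerance = 1e-9)
    expect_true(all(diff(s$kex) > 0))
})
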