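test_that("noiseless data return the generating parameters from any start", {
    ds <- simulateCpmgDataset(smallTruth(), nuGrid(), 0.02, noiseSd = 0,
                              seed = 1)
    for (init in list(NULL, list(kex = 300, pE = 0.15),
                      list(kex = 20000, pE = 0.005, dw = 5))) {
        fit <- fitTwoStateGlobal(ds, init = init)
        expect_true(fit@converged)
        expect_lt(abs(fit@kex - 2000) / 2000, 1e-3)
        expect_lt(abs(fit@pE - 0.03) / 0.03, 1e-3)
        expect_lt(max(abs(fit@dwPpm - c(A = 2, B = 1, C = 3)) /
                          c(2, 1, 3)), 1e-3)
        expect_lt(max(abs(fit@r20 - 10)), 0.01)
    }
})

test_that("two-field data share one shift difference per residue", {
    ds <- simulateCpmgDataset(twoFieldTruth(), nuGrid(), 0.02, noiseSd = 0,
                              seed = 3)
    fit <- fitTwoStateGlobal(ds)
    expect_length(fit@dwPpm, 3)       # residues, not residue x field
    expect_length(fit@r20, 6)         # one intercept per profile
    expect_lt(abs(fit@kex - 2000) / 2000, 1e-3)
})

test_that("flat profiles raise the unidentifiability flag", {
    tr <- exchangeParams(2000, 0.03, c(A = 0, B = 0), r20 = 10,
                         tempK = 293.55)
    ds <- simulateCpmgDataset(tr, nuGrid(), 0.02, noiseSd = 0.3, seed = 2)
    fit <- fitTwoStateGlobal(ds)
    expect_false(fit@identifiable)
    # and a dataset with real exchange does not
    ds2 <- simulateCpmgDataset(smallTruth(), nuGrid(), 0.02, noiseSd = 0.3,
                               seed = 2)
    expect_true(fitTwoStateGlobal(ds2)@identifiable)
})

test_that("non-positive uncertainties are rejected", {
    ds <- simulateCpmgDataset(smallTruth(), nuGrid(), 0.02, noiseSd = 0,
                              seed = 1, sigma = 1)
    ds@points$sigma_s1[3] <- 0
    expect_error(fitTwoStateGlobal(ds), "sigma")
})

test_that("bootstrap uncertainties behave like a calibrated resampler", {
    ds <- simulateCpmgDataset(twoFieldTruth(), nuGrid(), 0.02, noiseSd = 0.3,
                              seed = 11)
    fit <- fitTwoStateGlobal(ds)
    expect_error(bootstrapErrors(ds, fit, nBoot = 5, seed = 1), "nBoot")
    b1 <- bootstrapErrors(ds, fit, nBoot = 20, seed = 4)
    b2 <- bootstrapErrors(ds, fit, nBoot = 20, seed = 4)
    expect_identical(b1@boot$draws, b2@boot$draws)   # seed determinism
    expect_gt(b1@boot$sd[["kex"]], 0)
    # near-noiseless data give near-zero interval widths
    ds0 <- simulateCpmgDataset(smallTruth(), nuGrid(), 0.02, noiseSd = 1e-4,
                               seed = 5, sigma = 1)
    f0 <- fitTwoStateGlobal(ds0)
    b0 <- bootstrapErrors(ds0, f0, nBoot = 20, seed = 6)
    expect_lt(b0@boot$upper[["kex"]] - b0@boot$lower[["kex"]], 2)
})

test_that("interval widths shrink roughly as one over root data volume", {
    # quadruplicating the residues (independent noise) should halve the
    # kex interval width, up to bootstrap noise
    widths <- vapply(c(1, 4), function(N) {
        dw <- rep(c(A = 2, B = 1, C = 3), N)
        names(dw) <- paste0(names(dw), rep(seq_len(N), each = 3))
        tr <- exchangeParams(2000, 0.03, dw, r20 = 10, tempK = 293.55)
        ds <- simulateCpmgDataset(tr, nuGrid(), 0.02, noiseSd = 0.3,
                                  seed = 21)
        fit <- fitTwoStateGlobal(ds)
        b <- bootstrapErrors(ds, fit, nBoot = 25, seed = 22)
        b@boot$upper[["kex"]] - b@boot$lower[["kex"]]
    }, 0)
    expect_lt(widths[2] / widths[1], 0.8)
    expect_gt(widths[2] / widths[1], 0.25)
})
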