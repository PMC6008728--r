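# Shared fixtures, built in code at test time.

# small single-field exchange truth used across CPMG tests
smallTruth <- function(dw = c(A = 2, B = 1, C = 3)) {
    exchangeParams(kex = 2000, pE = 0.03, dwPpm = dw, r20 = 10,
                   nucleus = "15N", fieldT = 11.7, tempK = 293.55)
}

# the two-field truth mirroring a multi-field experimental design
twoFieldTruth <- function() {
    exchangeParams(kex = 2000, pE = 0.03, dwPpm = c(A = 2, B = 1, C = 3),
                   r20 = c(10, 12), nucleus = "15N", fieldT = c(11.7, 18.8),
                   tempK = 293.55)
}

nuGrid <- function() seq(50, 1000, by = 50)

# Luz-Meiboom fast-exchange closed form (independent oracle)
luzMeiboom <- function(kex, pE, dwPpm, r20, nucleus, fieldT, nu) {
    dw <- ppmToRad(dwPpm, nucleus, fieldT)
    r20 + (1 - pE) * pE * dw^2 / kex *
        (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

# exact-count transition model: turn a probability matrix into large integer
# counts so the estimators see (almost) exact transition probabilities
exactCountModel <- function(Tm, dt = 1, lagSteps = 1, reversible = FALSE,
                            scale = 1e7) {
    C <- matrix(as.integer(round(Tm * scale)), nrow(Tm))
    suppressMessages(transitionModel(C, dt = dt, lagSteps = lagSteps,
                                     reversible = reversible))
}

# unbiased nearest-neighbour chain with reflecting-ish ends (A and B sticky)
gamblersChain <- function(N) {
    Tm <- matrix(0, N + 1, N + 1)
    for (i in 2:N) {
        Tm[i, i - 1] <- 0.5
        Tm[i, i + 1] <- 0.5
    }
    Tm[1, 1] <- 0.5; Tm[1, 2] <- 0.5
    Tm[N + 1, N + 1] <- 0.5; Tm[N + 1, N] <- 0.5
    Tm
}
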