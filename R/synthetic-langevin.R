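#' Specify a 2D potential of Gaussian wells with harmonic confinement
#'
#' \deqn{U(x) = \tfrac12 k_{conf} |x|^2 -
#'   \sum_i d_i \exp(-|x - c_i|^2 / (2 w_i^2))}
#' with well depths \eqn{d_i} in multiples of \eqn{k_B T} when \code{kT = 1}.
#' Fixture potentials built from this spec emulate a rugged conformational
#' free-energy surface with two major minima and optional intermediate traps.
#'
#' @param centers matrix with one row per well (x, y).
#' @param depths well depths (> 0), energy units.
#' @param widths well widths (> 0), length units.
#' @param kconf harmonic confinement constant (>= 0).
#' @param kT thermal energy (energy units).
#' @param D diffusion coefficient (length^2 / time).
#' @return a list of class \code{"PotentialSpec"}.
#' @export
potentialSpec <- function(centers, depths, widths, kconf = 1, kT = 1, D = 1) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    if (length(depths) != nrow(centers) || length(widths) != nrow(centers))
        stop("need one depth and one width per well")
    if (any(depths <= 0)) stop("depths must be > 0")
    if (any(widths <= 0)) stop("widths must be > 0")
    if (kconf < 0 || kT <= 0 || D <= 0) stop("invalid kconf/kT/D")
    structure(list(centers = centers, depths = as.numeric(depths),
                   widths = as.numeric(widths), kconf = kconf, kT = kT,
                   D = D),
              class = "PotentialSpec")
}

#' Symmetric double-well potential fixture
#'
#' Two equal Gaussian wells on the x axis. With the defaults the barrier
#' between the wells (via \code{\link{potentialBarrier}}) is about 3.9 kT:
#' high enough for well-defined metastability, low enough that a trajectory
#' of a few million steps shows dozens of barrier crossings.
#'
#' @param depth,width,separation,kconf,kT,D see \code{\link{potentialSpec}}.
#' @return a \code{"PotentialSpec"}.
#' @export
doubleWellPotential <- function(depth = 6, width = 0.5, separation = 2,
                                kconf = 1, kT = 1, D = 1) {
    a <- separation / 2
    potentialSpec(centers = rbind(c(-a, 0), c(a, 0)),
                  depths = c(depth, depth), widths = c(width, width),
                  kconf = kconf, kT = kT, D = D)
}

#' Rugged potential fixture: two deep wells plus intermediate traps
#'
#' Reads the versioned fixture configuration shipped with the package
#' (\code{extdata/rugged_potential.yaml}): two deep wells ("E" and "B") and
#' two shallow intermediate wells displaced off the direct path, emulating a
#' rugged surface where transitions can proceed directly or through traps.
#'
#' @param trapScale multiplier on the depths of the intermediate trap wells
#'   (1 reproduces the shipped fixture; larger values deepen the traps).
#' @return a \code{"PotentialSpec"} with attribute \code{"wells"} naming the
#'   wells in configuration order.
#' @export
ruggedPotential <- function(trapScale = 1) {
    cfg <- yaml::read_yaml(system.file("extdata", "rugged_potential.yaml",
                                       package = "confex"))
    wells <- do.call(rbind, lapply(cfg$wells, function(w)
        c(w$center[[1]], w$center[[2]],
          w$depth * if (grepl("^trap", w$name)) trapScale else 1,
          w$width)))
    pot <- potentialSpec(centers = wells[, 1:2], depths = wells[, 3],
                         widths = wells[, 4], kconf = cfg$kconf,
                         kT = cfg$kT, D = cfg$D)
    attr(pot, "wells") <- vapply(cfg$wells, `[[`, "", "name")
    pot
}

#' Evaluate a potential on points
#'
#' @param pot a \code{"PotentialSpec"}.
#' @param pts numeric matrix (n x 2) or length-2 vector.
#' @return potential energies.
#' @export
potentialEnergy <- function(pot, pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
    .potential_energy_cpp(pts, pot$centers, pot$depths, pot$widths, pot$kconf)
}

#' Barrier height between two wells of a potential
#'
#' Numerically locates the two minima (local minimisation started from the
#' well centers) and the barrier top as the maximum over x of the
#' y-minimised potential between them. Intended for fixture potentials whose
#' wells are separated mainly along x.
#'
#' @param pot a \code{"PotentialSpec"}.
#' @param from,to well indices (rows of \code{pot$centers}).
#' @param nGrid grid resolution along each axis.
#' @return list with \code{barrier} (energy above the \code{from} minimum),
#'   \code{minima} (2 x 2 matrix) and \code{saddleX}.
#' @export
potentialBarrier <- function(pot, from = 1, to = 2, nGrid = 401) {
    mins <- lapply(c(from, to), function(i) {
        o <- stats::optim(pot$centers[i, ], function(p)
            potentialEnergy(pot, p), method = "Nelder-Mead",
            control = list(reltol = 1e-14))
        o$par
    })
    u0 <- potentialEnergy(pot, mins[[1]])
    xs <- seq(mins[[1]][1], mins[[2]][1], length.out = nGrid)
    yr <- range(pot$centers[, 2]) + c(-1, 1) * 3 * max(pot$widths)
    ys <- seq(yr[1], yr[2], length.out = nGrid)
    grid <- as.matrix(expand.grid(x = xs, y = ys))
    U <- matrix(potentialEnergy(pot, grid), nrow = nGrid)
    prof <- apply(U, 1, min)        # min over y for each x
    isad <- which.max(prof)
    list(barrier = prof[isad] - u0,
         minima = rbind(mins[[1]], mins[[2]]),
         saddleX = xs[isad])
}

#' Free-energy difference between two basins by quadrature
#'
#' Integrates \eqn{e^{-U/kT}} over the two half-planes split at
#' \code{boundaryX} and returns \eqn{\Delta F = -kT \log(Z_{left}/Z_{right})}.
#' Serves as the analytic ground truth for free-energy surfaces estimated
#' from simulated trajectories.
#'
#' @param pot a \code{"PotentialSpec"}.
#' @param boundaryX dividing line x = boundaryX.
#' @param lim integration half-width; the confinement makes the integrand
#'   negligible outside a few length units.
#' @param nGrid quadrature resolution per axis.
#' @return \eqn{F_{left} - F_{right}} in energy units.
#' @export
potentialFreeEnergyDifference <- function(pot, boundaryX = 0, lim = 6,
                                          nGrid = 601) {
    xs <- seq(-lim, lim, length.out = nGrid)
    ys <- seq(-lim, lim, length.out = nGrid)
    grid <- as.matrix(expand.grid(x = xs, y = ys))
    w <- exp(-potentialEnergy(pot, grid) / pot$kT)
    left <- sum(w[grid[, 1] < boundaryX])
    right <- sum(w[grid[, 1] >= boundaryX])
    -pot$kT * log(left / right)
}

#' Free-energy barrier of the x-projected PMF
#'
#' Computes the 1D potential of mean force along x,
#' \eqn{F(x) = -kT \log \int e^{-U(x,y)/kT} dy}, and returns the barrier
#' between its two outer minima. For a multidimensional system this, not
#' the bare saddle energy, is the free-energy barrier that rates and
#' transition-path times report on (the transverse channel width
#' contributes entropy).
#'
#' @param pot a \code{"PotentialSpec"} whose minima are separated along x.
#' @param lim integration half-width per axis.
#' @param nGrid grid resolution per axis.
#' @return list: \code{barrier} (energy units: height of the PMF maximum
#'   between the outer minima above the global PMF minimum), \code{pmf}
#'   (data.frame x, F).
#' @export
potentialPmfBarrier <- function(pot, lim = 4, nGrid = 801) {
    xs <- seq(-lim, lim, length.out = nGrid)
    ys <- seq(-lim, lim, length.out = nGrid)
    grid <- as.matrix(expand.grid(x = xs, y = ys))
    U <- matrix(potentialEnergy(pot, grid), nrow = nGrid)
    Fx <- -pot$kT * log(rowSums(exp(-U / pot$kT)))
    Fx <- Fx - min(Fx)
    xmin <- range(pot$centers[, 1])
    mid <- xs > xmin[1] & xs < xmin[2]
    list(barrier = max(Fx[mid]) - min(Fx),
         pmf = data.frame(x = xs, F = Fx))
}

#' Simulate overdamped Langevin dynamics on a 2D potential
#'
#' Euler-Maruyama integration of
#' \deqn{x \leftarrow x - (D/k_B T) \nabla U \, dt + \sqrt{2 D dt}\,\eta}
#' with standard-normal \eqn{\eta}. The step size must satisfy the stability
#' condition \eqn{dt \cdot |\nabla^2 U|_{max} \cdot D / k_B T < 0.1}
#' (estimated from the well curvatures); trajectories escaping the confining
#' region are flagged as an unstable-step symptom.
#'
#' @param pot a \code{"PotentialSpec"}.
#' @param dt integration time step.
#' @param nSteps number of steps.
#' @param seed integer seed.
#' @param x0 length-2 start coordinate.
#' @param stride keep every \code{stride}-th frame (frame interval of the
#'   returned trajectory is \code{dt * stride}).
#' @param rmax escape radius; default places it well outside the wells.
#' @return a \code{\linkS4class{FeatureTraj}}; attribute \code{"escaped"} is
#'   TRUE if the trajectory left the confining region.
#' @export
simulateLangevin <- function(pot, dt, nSteps, seed, x0 = c(0, 0), stride = 1L,
                             rmax = NULL) {
    curv <- pot$kconf + max(pot$depths / pot$widths^2)
    if (dt * curv * pot$D / pot$kT >= 0.1)
        stop("dt too large: dt * |d2U| * D / kT = ",
             signif(dt * curv * pot$D / pot$kT, 3), " >= 0.1")
    if (is.null(rmax)) {
        r0 <- max(sqrt(rowSums(pot$centers^2)), 1)
        rmax <- if (pot$kconf > 0)
            r0 + 3 * max(pot$widths) + 6 * sqrt(pot$kT / pot$kconf)
        else Inf
    }
    set.seed(as.integer(seed))
    out <- .langevin_cpp(pot$centers, pot$depths, pot$widths, pot$kconf,
                         pot$kT, pot$D, dt, as.integer(nSteps),
                         as.numeric(x0), as.integer(stride), rmax)
    if (isTRUE(out$escaped))
        warning("trajectory escaped the confining region; dt may be unstable")
    tr <- new("FeatureTraj", coords = out$coords, dt = dt * stride)
    attr(tr, "escaped") <- isTRUE(out$escaped)
    tr
}
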