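#' Read a dispersion dataset from CSV
#'
#' Reads the CSV dialect written by \code{\link{writeDispersionCsv}}:
#' columns \code{residue}, \code{nucleus}, \code{field_T}, \code{temp_K},
#' \code{t_cpmg_s}, \code{nu_cpmg_hz}, \code{r2eff_s1}, \code{sigma_s1}.
#' Malformed rows are rejected with their line number; decimal points only
#' (locale-independent parsing).
#'
#' @param path CSV file path.
#' @return a \code{\linkS4class{DispersionExperiment}}.
#' @export
readDispersionCsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    pts <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(residue = "character"))
    need <- c("residue", "nucleus", "field_T", "temp_K", "t_cpmg_s",
              "nu_cpmg_hz", "r2eff_s1", "sigma_s1")
    if (!all(need %in% names(pts)))
        stop("missing column(s): ",
             paste(setdiff(need, names(pts)), collapse = ", "))
    num <- c("field_T", "temp_K", "t_cpmg_s", "nu_cpmg_hz", "r2eff_s1",
             "sigma_s1")
    for (cn in num) {
        v <- suppressWarnings(as.numeric(pts[[cn]]))
        bad <- which(!is.finite(v))
        if (length(bad))
            stop("non-numeric ", cn, " at line ", bad[1] + 1L)
        pts[[cn]] <- v
    }
    bad <- which(pts$nu_cpmg_hz <= 0)
    if (length(bad))
        stop("non-positive nu_cpmg_hz at line ", bad[1] + 1L)
    new("DispersionExperiment", points = pts[, need], truth = NULL)
}

#' Write a dispersion dataset to CSV
#'
#' Round-trip stable with \code{\link{readDispersionCsv}}: writing, reading
#' and writing again produces identical bytes.
#'
#' @param x a \code{\linkS4class{DispersionExperiment}}.
#' @param path output path.
#' @export
writeDispersionCsv <- function(x, path) {
    pts <- dispersionPoints(x)
    num <- vapply(pts, is.numeric, TRUE)
    pts[num] <- lapply(pts[num], function(v) format(v, digits = 15,
                                                    trim = TRUE,
                                                    scientific = FALSE))
    utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write an analysis payload as JSON
#'
#' Numbers are written at full precision with scalars unboxed, so repeated
#' runs with identical inputs produce byte-identical files.
#'
#' @param path output path.
#' @param payload a (possibly nested) list of results.
#' @export
writeResultsJson <- function(path, payload) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' Read a rate series CSV
#'
#' Accepts either a \code{temp_K} or a \code{temp_C} column (exact +273.15
#' conversion) plus \code{kex_s1}, \code{kex_sigma_s1} and either percent
#' (\code{pE_pct}, \code{pE_sigma_pct}) or fractional (\code{pE},
#' \code{pE_sigma}) populations.
#'
#' @param path CSV file path.
#' @return data.frame as from \code{\link{rateSeries}}.
#' @export
readRateSeries <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- utils::read.csv(path)
    tempK <- if ("temp_K" %in% names(raw)) raw$temp_K
             else if ("temp_C" %in% names(raw)) celsiusToKelvin(raw$temp_C)
             else stop("need a temp_K or temp_C column")
    pE <- if ("pE_pct" %in% names(raw)) raw$pE_pct / 100 else raw$pE
    pESd <- if ("pE_sigma_pct" %in% names(raw)) raw$pE_sigma_pct / 100
            else raw$pE_sigma
    rateSeries(tempK = tempK, kex = raw$kex_s1, kexSd = raw$kex_sigma_s1,
               pE = pE, pESd = pESd)
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in dependency order with all randomness
#' seeded from the configuration, writing each stage's results as JSON next
#' to the configured output directory. Supported stages: \code{"arrhenius"}
#' (rate series -> thermokinetics), \code{"fit_cpmg"} (dispersion CSV ->
#' global two-state fit) and \code{"barrier"} (rate + transition path time
#' -> activation free energy). A stage failure marks the stage failed and
#' skips downstream stages; referenced input paths are validated before
#' anything runs.
#'
#' @param config a named list or the path of a YAML file with components
#'   \code{stages} (character vector), \code{outdir}, \code{seed} and the
#'   per-stage blocks \code{arrhenius} (\code{rates} path,
#'   \code{extrapolate_C} temperatures in Celsius), \code{fit_cpmg}
#'   (\code{data} path, optional \code{boot}), \code{barrier} (\code{k},
#'   \code{tau_tpt_s}, \code{temp_K}).
#' @return a run report (list): tool version, config digest, per-stage
#'   status and output files, warnings. The report itself is written to
#'   \code{outdir/run_report.json}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    outdir <- config$outdir %||% "confex_out"
    seed <- as.integer(config$seed %||% 1L)
    stages <- config$stages
    order <- c("arrhenius", "fit_cpmg", "barrier")
    stages <- order[order %in% stages]
    # validate every referenced input path before running anything
    paths <- c(config$arrhenius$rates, config$fit_cpmg$data)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("missing input path(s): ", paste(missing, collapse = ", "))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cfgFile <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, cfgFile)
    digest <- unname(tools::md5sum(cfgFile))
    report <- list(tool = "confex",
                   version = as.character(utils::packageVersion("confex")),
                   config_md5 = digest, seed = seed, stages = list(),
                   warnings = character())
    failed <- FALSE
    for (st in stages) {
        if (failed) {
            report$stages[[st]] <- list(status = "skipped")
            next
        }
        res <- tryCatch({
            out <- file.path(outdir, paste0(st, ".json"))
            if (st == "arrhenius") {
                series <- readRateSeries(config$arrhenius$rates)
                tempsK <- celsiusToKelvin(
                    as.numeric(config$arrhenius$extrapolate_C %||% c(37, 50)))
                an <- arrheniusAnalysis(series, tempsK)
                writeResultsJson(out, list(
                    extrapolation = an$extrap,
                    dH_kJmol = an$thermo$dH / 1000,
                    dH_sd_kJmol = an$thermo$dH_sd / 1000,
                    dHact_BE_kJmol = an$dHactBE / 1000,
                    byTemp = an$thermo$byTemp))
            } else if (st == "fit_cpmg") {
                ds <- readDispersionCsv(config$fit_cpmg$data)
                fit <- fitTwoStateGlobal(ds)
                if (!is.null(config$fit_cpmg$boot))
                    fit <- bootstrapErrors(ds, fit,
                                           nBoot = config$fit_cpmg$boot,
                                           seed = seed)
                writeResultsJson(out, list(
                    kex = fit@kex, pE = fit@pE,
                    dw_ppm = as.list(fit@dwPpm), r20 = as.list(fit@r20),
                    red_chisq = fit@redChisq, converged = fit@converged,
                    identifiable = fit@identifiable,
                    boot = fit@boot[c("sd", "lower", "upper")]))
            } else if (st == "barrier") {
                b <- barrierFromTpt(config$barrier$k,
                                    config$barrier$tau_tpt_s,
                                    config$barrier$temp_K)
                writeResultsJson(out, b)
            }
            list(status = "ok", output = out)
        }, error = function(e) list(status = "failed",
                                    message = conditionMessage(e)))
        if (identical(res$status, "failed")) failed <- TRUE
        report$stages[[st]] <- res
    }
    report$exit_status <- if (failed) 1L else 0L
    writeResultsJson(file.path(outdir, "run_report.json"), report)
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
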