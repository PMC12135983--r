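# Reduced SANS interchange: 3-column ASCII tables (Q I dI) with `#` comment
# headers, a plain-text manifest mapping sample names to files, and a
# YAML/JSON contrast configuration. All writers emit files that round-trip
# through the package's own readers.

.readConfigFile <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Read a contrast configuration
#'
#' The configuration lists the solute components and, per sample, the
#' contrast values Delta-rho (solute SLD minus solvent SLD) in
#' 1e-6/Angstrom^2:
#' ```yaml
#' units: 1e-6_A^-2
#' components: [core, shell]
#' samples:
#'   - {name: CS100, delta_rho: [-2.36, -5.36]}
#'   - {name: CS000, delta_rho: [4.56, 1.56]}
#' ```
#' JSON files (by extension) use the same structure. Units are carried
#' through verbatim; no rescaling is ever applied to user input.
#'
#' @param path YAML or JSON file path.
#' @return list with `componentNames`, `sampleNames`, `deltaRho` (N x (p-1)
#'   matrix) and `units`.
#' @export
readContrastConfig <- function(path) {
  cfg <- .readConfigFile(path)
  if (is.null(cfg$components) || is.null(cfg$samples))
    stop("contrast config needs 'components' and 'samples' entries")
  samples <- cfg$samples
  if (is.data.frame(samples))
    samples <- lapply(seq_len(nrow(samples)), function(i)
      list(name = samples$name[i],
           delta_rho = unlist(samples$delta_rho[i])))
  deltas <- do.call(rbind, lapply(samples, function(s)
    as.numeric(unlist(s$delta_rho))))
  if (ncol(deltas) != length(cfg$components))
    stop("each sample needs one delta_rho value per component")
  list(
    componentNames = as.character(cfg$components),
    sampleNames = vapply(samples, function(s) as.character(s$name), ""),
    deltaRho = deltas,
    units = if (is.null(cfg$units)) "1e-6_A^-2" else cfg$units
  )
}

#' @rdname readContrastConfig
#' @param data a [ContrastScatteringSet-class] to export.
#' @export
writeContrastConfig <- function(data, path) {
  d <- contrastDeltas(data)
  cfg <- list(
    units = "1e-6_A^-2",
    components = as.list(componentNames(data)),
    # contrasts serialised as %.17g strings so values round-trip exactly
    samples = lapply(seq_len(nrow(d)), function(i)
      list(name = rownames(d)[i],
           delta_rho = as.list(sprintf("%.17g", unname(d[i, ])))))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(cfg, path)
  invisible(path)
}

.readCurveFile <- function(path) {
  tab <- read.table(path, comment.char = "#", header = FALSE,
                    col.names = c("Q", "I", "dI"), fill = FALSE,
                    sep = "", colClasses = "numeric")
  bad <- which(tab$dI <= 0 | !is.finite(tab$dI))
  if (length(bad))
    stop(sprintf(
      "non-positive sigma in '%s' at data row(s) %s", path,
      paste(bad, collapse = ", ")
    ))
  tab
}

#' Read per-sample intensity tables through a manifest
#'
#' The manifest is a two-column text file (`name path`, `#` comments
#' allowed; paths relative to the manifest) or a named character vector of
#' file paths. Each table holds whitespace- or comma-delimited columns
#' `Q I dI`. All tables must share one Q grid to within 1e-10 relative.
#'
#' @param manifest manifest path or named character vector.
#' @param contrasts optional contrast configuration (path, or the list from
#'   [readContrastConfig()]); when given, a full
#'   [ContrastScatteringSet-class] is assembled (samples matched by name).
#' @return with `contrasts`: a [ContrastScatteringSet-class]; without: list
#'   `q`, `intensities`, `sigmas`, `sampleNames` (rows ordered as in the
#'   manifest).
#' @export
readIntensityTables <- function(manifest, contrasts = NULL) {
  if (is.character(manifest) && length(manifest) == 1L &&
      is.null(names(manifest))) {
    mdir <- dirname(manifest)
    tab <- read.table(manifest, comment.char = "#", header = FALSE,
                      col.names = c("name", "path"),
                      colClasses = "character")
    files <- setNames(
      ifelse(grepl("^/", tab$path), tab$path, file.path(mdir, tab$path)),
      tab$name
    )
  } else {
    if (is.null(names(manifest)))
      stop("a vector manifest must be named by sample")
    files <- manifest
  }
  curves <- lapply(files, .readCurveFile)
  q <- curves[[1L]]$Q
  for (nm in names(curves)) {
    qi <- curves[[nm]]$Q
    if (length(qi) != length(q) ||
        any(abs(qi - q) > 1e-10 * pmax(abs(q), 1e-300)))
      stop(sprintf(
        "Q grid of '%s' does not match '%s' (grids must be identical)",
        files[[nm]], files[[1L]]
      ))
  }
  res <- list(
    q = q,
    intensities = do.call(rbind, lapply(curves, function(x) x$I)),
    sigmas = do.call(rbind, lapply(curves, function(x) x$dI)),
    sampleNames = names(files)
  )
  if (is.null(contrasts)) return(res)
  if (is.character(contrasts)) contrasts <- readContrastConfig(contrasts)
  idx <- match(res$sampleNames, contrasts$sampleNames)
  if (anyNA(idx))
    stop("samples missing from the contrast config: ",
         paste(res$sampleNames[is.na(idx)], collapse = ", "))
  deltas <- contrasts$deltaRho[idx, , drop = FALSE]
  colnames(deltas) <- contrasts$componentNames
  ContrastScatteringSet(res$q, res$intensities, res$sigmas, deltas,
                        sampleNames = res$sampleNames)
}

#' Write a contrast series as manifest + per-sample tables
#'
#' Writes one `Q I dI` table per sample, a `manifest.txt`, a
#' `contrasts.yaml`, and (optionally) the ground-truth partial scattering
#' functions as `true_<pair>.dat`.
#'
#' @param data a [ContrastScatteringSet-class].
#' @param dir output directory (created if needed).
#' @param truth optional L x M matrix of true partial functions.
#' @return (invisibly) the manifest path.
#' @export
writeScatteringSet <- function(data, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- qValues(data)
  I <- intensities(data); Sg <- sigmas(data)
  nm <- colnames(data)
  for (i in seq_along(nm)) {
    f <- file.path(dir, paste0(nm[i], ".dat"))
    lines <- c(
      sprintf("# sample: %s", nm[i]),
      "# columns: Q[1/A] I dI (dI = one standard deviation)"
    )
    writeLines(c(lines, sprintf("%.17g %.17g %.17g", q, I[i, ], Sg[i, ])),
               f)
  }
  writeContrastConfig(data, file.path(dir, "contrasts.yaml"))
  if (!is.null(truth)) {
    for (k in seq_len(nrow(truth))) {
      f <- file.path(dir, sprintf("true_%s.dat",
                                  rownames(truth)[k]))
      writeLines(c("# columns: Q[1/A] S_true",
                   sprintf("%.17g %.17g", q, truth[k, ])), f)
    }
  }
  mf <- file.path(dir, "manifest.txt")
  writeLines(c("# sample file", paste(nm, paste0(nm, ".dat"))), mf)
  invisible(mf)
}

#' Write / read estimated partial scattering functions
#'
#' One delimited file per partial function with columns `Q S dS` and `#`
#' header lines recording the method, kernel family and parameters, and
#' the log marginal likelihood. With `wantCov` estimates the full posterior
#' covariance is dumped as a dense whitespace table `covariance.dat` with
#' an index legend (l-major / Q-minor order).
#'
#' @param est a [PartialEstimate-class].
#' @param dir output directory.
#' @return (invisibly) the written file paths.
#' @export
writeEstimate <- function(est, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- S4Vectors::metadata(est)
  q <- qValues(est)
  mu <- estimateMeans(est); se <- errorBars(est)
  hdr <- c(
    sprintf("# method: %s", md$method),
    "# units: Q [1/A]; S in reciprocal contrast-squared intensity units"
  )
  if (!is.null(md$kernel))
    hdr <- c(hdr, sprintf(
      "# kernel: %s alpha=%.17g l=%.17g tau=%.17g",
      md$kernel@family, md$kernel@alpha, md$kernel@lengthScale,
      md$kernel@tau
    ))
  if (is.finite(md$logMarginalLikelihood))
    hdr <- c(hdr, sprintf("# lml: %.17g", md$logMarginalLikelihood))
  paths <- character(0)
  for (k in seq_len(nrow(mu))) {
    f <- file.path(dir, paste0(pairLabels(est)[k], ".dat"))
    writeLines(c(hdr, "# columns: Q S dS",
                 sprintf("%.17g %.17g %.17g", q, mu[k, ], se[k, ])), f)
    paths <- c(paths, f)
  }
  if (!is.null(md$covariance)) {
    f <- file.path(dir, "covariance.dat")
    writeLines(c(
      "# full posterior covariance, l-major / Q-minor order:",
      sprintf("# row (l-1)*M + m, l in {%s}, M = %d",
              paste(pairLabels(est), collapse = ", "), length(q))
    ), f)
    write.table(md$covariance, f, append = TRUE, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' @rdname writeEstimate
#' @param path one `S_*.dat` file written by `writeEstimate()`.
#' @export
readEstimate <- function(path) {
  hdr <- grep("^#", readLines(path), value = TRUE)
  tab <- read.table(path, comment.char = "#", header = FALSE,
                    col.names = c("Q", "S", "dS"))
  meta <- list(method = sub("^# method: ", "",
                            grep("^# method:", hdr, value = TRUE)))
  kl <- grep("^# kernel:", hdr, value = TRUE)
  if (length(kl)) {
    parts <- strsplit(sub("^# kernel: ", "", kl), " ")[[1L]]
    kv <- strsplit(parts[-1L], "=")
    meta$kernel <- KernelSpec(
      parts[1L],
      alpha = as.numeric(kv[[1L]][2L]),
      lengthScale = as.numeric(kv[[2L]][2L]),
      tau = as.numeric(kv[[3L]][2L])
    )
  }
  ll <- grep("^# lml:", hdr, value = TRUE)
  if (length(ll)) meta$lml <- as.numeric(sub("^# lml: ", "", ll))
  c(list(Q = tab$Q, S = tab$S, dS = tab$dS), meta)
}

.kernelFromConfig <- function(k) {
  if (is.null(k)) return(KernelSpec())
  KernelSpec(
    family = if (is.null(k$family)) "matern52" else k$family,
    alpha = if (is.null(k$alpha)) 1 else k$alpha,
    lengthScale = if (is.null(k$lengthScale)) {
      if (is.null(k$l)) 0.1 else k$l
    } else k$lengthScale,
    tau = if (is.null(k$tau)) 1e-5 else k$tau,
    logQ = isTRUE(k$logQ)
  )
}

.loadRunData <- function(config) {
  if (is.null(config$manifest) || is.null(config$contrasts))
    stop("config needs 'manifest' and 'contrasts' paths")
  for (f in c(config$manifest, config$contrasts))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  data <- readIntensityTables(config$manifest, config$contrasts)
  if (!is.null(config$subsetQmax))
    data <- subsetLowQ(data, config$subsetQmax)
  data
}

.runLog <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

#' Fit partial scattering functions from files on disk
#'
#' End-to-end driver: reads the manifest and contrast configuration, fits
#' GPR or WLS, writes the per-function `Q S dS` tables and a JSON run
#' summary (`run_summary.json`) recording method, kernel parameters, log
#' marginal likelihood, the negativity and Cauchy-Schwarz diagnostics, the
#' seed and the package version. Output is deterministic given the inputs
#' and seed; reruns are bit-identical.
#'
#' @param config list, or a YAML/JSON file path, with fields `manifest`,
#'   `contrasts`, `out`, `method` ("gpr" or "wls"), `kernel`
#'   (list with `family`, `alpha`, `l`, `tau`), optional `subsetQmax`,
#'   `wantCov`, `seed`, `verbose`.
#' @return (invisibly) the [PartialEstimate-class].
#' @export
runFit <- function(config) {
  if (is.character(config)) config <- .readConfigFile(config)
  if (is.null(config$out)) stop("config needs an 'out' directory")
  verbose <- isTRUE(config$verbose)
  data <- .loadRunData(config)
  .runLog(verbose, "assembled %d samples x %d Q points", ncol(data),
          nrow(data))
  method <- if (is.null(config$method)) "gpr" else config$method
  est <- if (method == "wls") {
    fitWLS(data, wantCov = isTRUE(config$wantCov))
  } else {
    spec <- .kernelFromConfig(config$kernel)
    fitGPR(data, spec, wantCov = isTRUE(config$wantCov))
  }
  .runLog(verbose, "fit complete (%s)", method)
  writeEstimate(est, config$out)
  md <- S4Vectors::metadata(est)
  summary <- list(
    method = md$method,
    kernel = if (is.null(md$kernel)) NULL else list(
      family = md$kernel@family, alpha = md$kernel@alpha,
      l = md$kernel@lengthScale, tau = md$kernel@tau
    ),
    logMarginalLikelihood = if (is.finite(md$logMarginalLikelihood))
      md$logMarginalLikelihood else NULL,
    diagnostics = md$diagnostics,
    seed = config$seed,
    package = as.character(packageVersion("cvsansGP"))
  )
  jsonlite::write_json(summary, file.path(config$out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(est)
}

#' Select kernel parameters from files on disk
#'
#' Driver for [gridSearch()]: reads data as in [runFit()], scans the
#' requested grids, writes the full objective table
#' (`selection_table.tsv`) and the chosen specification
#' (`selected_kernel.json`).
#'
#' @param config list or YAML/JSON path with fields `manifest`,
#'   `contrasts`, `out`, optional `families`, `alphaGrid`, `lGrid`, `tau`,
#'   `objective`, `hyper` (list with `alpha`/`l` sub-lists as in
#'   [HyperPrior()]), `refine`, `subsetQmax`, `verbose`.
#' @return (invisibly) the [SelectionResult-class].
#' @export
runSelect <- function(config) {
  if (is.character(config)) config <- .readConfigFile(config)
  if (is.null(config$out)) stop("config needs an 'out' directory")
  data <- .loadRunData(config)
  hyper <- if (!is.null(config$hyper))
    HyperPrior(alpha = config$hyper$alpha, l = config$hyper$l) else NULL
  args <- list(
    data = data,
    objective = if (is.null(config$objective)) "lml" else config$objective,
    hyper = hyper, refine = isTRUE(config$refine)
  )
  for (f in c("families", "alphaGrid", "lGrid", "tau"))
    if (!is.null(config[[f]])) args[[f]] <- config[[f]]
  sel <- do.call(gridSearch, args)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write.table(objectiveTable(sel),
              file.path(config$out, "selection_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- bestSpec(sel)
  jsonlite::write_json(
    list(family = sp@family, alpha = sp@alpha, l = sp@lengthScale,
         tau = sp@tau, objective = sel@objectiveName),
    file.path(config$out, "selected_kernel.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(sel)
}

#' Simulate a core-shell run to disk
#'
#' Writes the synthetic contrast series (manifest, per-sample tables,
#' contrast config, ground-truth partial functions) for a seed.
#'
#' @param out output directory.
#' @param params a [CoreShellParams-class].
#' @param seed RNG seed.
#' @param subset `"B"` (all Q, default) or `"A"` (Q < 0.05 1/A only).
#' @return (invisibly) the manifest path.
#' @export
simulateCoreShellRun <- function(out, params = CoreShellParams(),
                                 seed = params@seed,
                                 subset = c("B", "A")) {
  subset <- match.arg(subset)
  sim <- generateCoreShell(params, seed = seed)
  data <- sim$data
  truth <- sim$truth
  if (subset == "A") {
    data <- subsetLowQ(data)
    truth <- truth[, qValues(sim$data) < 0.05, drop = FALSE]
  }
  writeScatteringSet(data, out, truth = truth)
}

#' Benchmark GPR settings against WLS on synthetic data
#'
#' Runs the reduced core-shell parameter sweep: for each seed, generates a
#' noisy contrast series, fits every (family, alpha, l, tau) combination
#' plus the WLS baseline, and scores each by ground-truth MSE and (for GPR)
#' log marginal likelihood.
#'
#' @param config list or YAML/JSON path with optional fields `seeds`,
#'   `families`, `alphaGrid`, `lGrid`, `tau`, `subset` ("A"/"B"),
#'   `noiseSigma`, `nQ`, `out`, `verbose`.
#' @return data.frame with columns `seed`, `kernel`, `alpha`, `l`, `tau`,
#'   `mse`, `lml` (the WLS row has kernel `"wls"` and `NA` parameters);
#'   written to `<out>/benchmark.tsv` with a winner summary
#'   `<out>/benchmark_winner.json` when `out` is set.
#' @export
runBenchmark <- function(config = list()) {
  if (is.character(config)) config <- .readConfigFile(config)
  seeds <- if (is.null(config$seeds)) 1:3 else config$seeds
  families <- if (is.null(config$families)) "matern52" else config$families
  alphaGrid <- if (is.null(config$alphaGrid)) c(1, 10, 100)
    else config$alphaGrid
  lGrid <- if (is.null(config$lGrid)) c(0.01, 0.03, 0.1)
    else config$lGrid
  tau <- if (is.null(config$tau)) 1e-5 else config$tau
  subset <- if (is.null(config$subset)) "A" else config$subset
  params <- CoreShellParams(
    noiseSigma = if (is.null(config$noiseSigma)) 0.05
      else config$noiseSigma,
    nQ = if (is.null(config$nQ)) 100 else config$nQ
  )
  rows <- list()
  for (sd in seeds) {
    sim <- generateCoreShell(params, seed = sd)
    keep <- if (subset == "A") qValues(sim$data) < 0.05
      else rep(TRUE, length(qValues(sim$data)))
    data <- sim$data[keep, ]
    truth <- sim$truth[, keep, drop = FALSE]
    wls <- fitWLS(data)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = sd, kernel = "wls", alpha = NA_real_, l = NA_real_,
      tau = NA_real_, mse = mseEstimate(wls, truth), lml = NA_real_
    )
    for (fam in families) for (a in alphaGrid) for (l in lGrid)
      for (t in tau) {
        sp <- KernelSpec(fam, alpha = a, lengthScale = l, tau = t)
        est <- fitGPR(data, sp)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = sd, kernel = fam, alpha = a, l = l, tau = t,
          mse = mseEstimate(est, truth),
          lml = S4Vectors::metadata(est)$logMarginalLikelihood
        )
      }
    .runLog(isTRUE(config$verbose), "benchmark seed %d done", sd)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write.table(tab, file.path(config$out, "benchmark.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    gpr <- tab[tab$kernel != "wls", ]
    w <- gpr[which.min(gpr$mse), ]
    jsonlite::write_json(
      list(kernel = w$kernel, alpha = w$alpha, l = w$l, tau = w$tau,
           mse = w$mse, seed = w$seed,
           wlsMedianMse = stats::median(tab$mse[tab$kernel == "wls"])),
      file.path(config$out, "benchmark_winner.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  tab
}

#' Plot an estimate with error ribbons
#'
#' Minimal base-graphics helper: one panel per partial scattering function
#' with the mean curve and a +/- 1 standard-error ribbon.
#'
#' @param est a [PartialEstimate-class].
#' @param pairs subset of pair labels to draw (default: all).
#' @param log plot axes spec passed to [graphics::plot()] (default `"x"`).
#' @return invisibly `NULL`.
#' @export
plotEstimate <- function(est, pairs = pairLabels(est), log = "x") {
  q <- qValues(est)
  mu <- estimateMeans(est); se <- errorBars(est)
  old <- graphics::par(mfrow = c(length(pairs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pairs) {
    k <- match(p, pairLabels(est))
    ylim <- range(mu[k, ] - se[k, ], mu[k, ] + se[k, ])
    graphics::plot(q, mu[k, ], type = "n", log = log, xlab = "Q [1/A]",
                   ylab = p, ylim = ylim, main = p)
    graphics::polygon(c(q, rev(q)),
                      c(mu[k, ] - se[k, ], rev(mu[k, ] + se[k, ])),
                      col = "grey85", border = NA)
    graphics::lines(q, mu[k, ], lwd = 1.5)
  }
  invisible(NULL)
}
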