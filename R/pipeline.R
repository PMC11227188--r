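#' Pipeline run configuration
#'
#' One object driving the full analysis: input paths (or a simulation
#' config in place of measured data), detrending, resilience and bootstrap
#' settings, output directory and master seed. All defaults match the
#' standard analysis settings: 30-yr/50% spline, ratio indices, 2-yr
#' pre/post windows, 5-yr flanks, the historical drought calendar, 95%
#' bootstrap CIs.
#'
#' @param rwl Path to a .rwl collection, or `NULL` when `simulate` is
#'   given.
#' @param climate Named list `variable -> CSV path`, or `NULL` when
#'   `simulate` is given.
#' @param events Calendar CSV path or `"default"`.
#' @param simulate Optional [simulation_config]; replaces `rwl`/`climate`.
#' @param detrend A [detrend_config] (non-prewhitened; the pipeline
#'   prewhitens a copy for climate correlation).
#' @param resilience A [resilience_config].
#' @param n_boot,alpha Bootstrap settings for the climate response.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param component Wood component label for .rwl input.
#' @return Object of class `run_config`.
#' @export
run_config <- function(rwl = NULL, climate = NULL, events = "default",
                       simulate = NULL, detrend = detrend_config(),
                       resilience = resilience_config(),
                       n_boot = 1000L, alpha = 0.05,
                       out_dir = "droughtring-out", seed = 42L,
                       component = "LATEWOOD") {
  if (is.null(simulate) && is.null(rwl))
    stop("either rwl input or a simulation config is required")
  structure(list(rwl = rwl, climate = climate, events = events,
                 simulate = simulate, detrend = detrend,
                 resilience = resilience, n_boot = as.integer(n_boot),
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
                 component = component),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate/load -> detrend -> chronology statistics -> bootstrap climate
#' correlation (on the prewhitened chronology) -> per-tree resilience and
#' decline records -> density/skewness summaries. Writes, under
#' `config$out_dir`: `chronology.csv`, `stats.json`, `response.csv`,
#' `resilience.csv`, `declines.csv`, `config.json` and `run.log`.
#' Idempotent given the seed.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory results (`chronology`,
#'   `stats`, `response`, `resilience`, `declines`, `densities`, `paths`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- c(paste0("seed: ", config$seed))

  inputs <- .stage("load", {
    if (!is.null(config$simulate)) {
      f <- simulate_forest(config$simulate)
      list(collection = f$collection, climate = f$climate)
    } else {
      if (!file.exists(config$rwl))
        stop("missing ring-width file: ", config$rwl)
      cl <- list()
      for (v in names(config$climate)) {
        p <- config$climate[[v]]
        if (!file.exists(p)) stop("missing climate file: ", p)
        cl[[v]] <- read_climate_csv(p, v)
      }
      list(collection = read_rwl(config$rwl, component = config$component),
           climate = cl)
    }
  })
  calendar <- .stage("load", read_drought_calendar(config$events))

  detr <- .stage("detrend", {
    lapply(inputs$collection$series, standardize, config = config$detrend)
  })
  chron <- .stage("detrend", build_chronology(
    detr, min_depth = config$detrend$min_depth,
    biweight_c = config$detrend$biweight_c))
  log_lines <- c(log_lines, sprintf("detrended %d series", length(detr)))

  response <- .stage("climcorr", {
    if (length(inputs$climate) == 0L) NULL else {
      pw <- lapply(detr, prewhiten_ar, max_order = config$detrend$ar_max_order)
      chron_pw <- build_chronology(pw, min_depth = config$detrend$min_depth,
                                   biweight_c = config$detrend$biweight_c)
      bootstrap_correlation(chron_pw, inputs$climate,
                            n_boot = config$n_boot, alpha = config$alpha,
                            seed = config$seed)
    }
  })

  res <- .stage("resilience", evaluate_resilience(detr, config$resilience))
  dec <- .stage("resilience", decline_records(detr, calendar,
                                              config$resilience))
  densities <- .stage("resilience", {
    out <- list()
    for (ind in c("Rt", "Rc", "Rs")) {
      v <- res[[ind]]
      if (length(v[is.finite(v)]) >= 5L && stats::var(v, na.rm = TRUE) > 0)
        out[[ind]] <- density_summary(v, ind)
    }
    if (nrow(dec) >= 5L && stats::var(dec$DecU) > 0)
      out$DecU <- density_summary(dec$DecU, "DecU")
    out
  })

  paths <- .stage("write", {
    p <- list(
      chronology = file.path(config$out_dir, "chronology.csv"),
      stats = file.path(config$out_dir, "stats.json"),
      response = file.path(config$out_dir, "response.csv"),
      resilience = file.path(config$out_dir, "resilience.csv"),
      declines = file.path(config$out_dir, "declines.csv"),
      config = file.path(config$out_dir, "config.json"))
    write_chronology_csv(chron, p$chronology)
    st <- chron$stats
    stats_json <- list(
      schema = "droughtring-stats-1",
      component = chron$component,
      n_series = st$n_series,
      common_period = st$common_period,
      ms = st$ms, rbar = st$rbar, eps = st$eps,
      skewness = lapply(densities, function(d) d$skewness))
    jsonlite::write_json(stats_json, p$stats, auto_unbox = TRUE,
                         digits = NA, null = "null")
    if (!is.null(response)) write_response_csv(response, p$response)
    utils::write.csv(res, p$resilience, row.names = FALSE, quote = FALSE)
    utils::write.csv(dec, p$declines, row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$detrend <- unclass(cfg$detrend)
    cfg$resilience <- unclass(cfg$resilience)
    if (!is.null(cfg$simulate)) {
      cfg$simulate <- unclass(cfg$simulate)
      cfg$simulate$drought_calendar <- NULL
    }
    jsonlite::write_json(unclass(cfg), p$config, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    p
  })
  log_lines <- c(log_lines,
                 sprintf("%d resilience records, %d decline records",
                         nrow(res), nrow(dec)))
  writeLines(log_lines, logf)
  invisible(list(chronology = chron, stats = chron$stats,
                 response = response, resilience = res, declines = dec,
                 densities = densities, paths = paths))
}

# ---- minimal CLI -----------------------------------------------------------

.cli_flags <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        out[[key]] <- TRUE; i <- i + 1L
      } else {
        out[[key]] <- args[[i + 1L]]; i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1L
    }
  }
  out
}

.cli_need <- function(flags, key) {
  if (is.null(flags[[key]])) stop("missing required flag --", key)
  flags[[key]]
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write lw.rwl + climate CSVs + truth.json),
#' `detrend` (chronology CSV), `stats` (MS/Rbar/EPS JSON), `climcorr`
#' (bootstrap response CSV), `resilience` (records + declines CSVs) and
#' `run-all` (full pipeline from a JSON config). Intended to be invoked
#' via `Rscript -e 'droughtring::droughtring_cli()' <subcommand> ...`.
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   command line).
#' @return Invisibly, the subcommand's result.
#' @export
droughtring_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: droughtring <simulate|detrend|stats|climcorr|resilience|run-all> [--flags]")
  cmd <- args[[1L]]
  fl <- .cli_flags(args[-1L])
  seed <- as.integer(fl$seed %||% 42L)
  invisible(switch(
    cmd,
    simulate = {
      out_dir <- .cli_need(fl, "out-dir")
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      cfg <- simulation_config(seed = seed)
      if (!is.null(fl$config)) {
        ov <- jsonlite::read_json(fl$config, simplifyVector = TRUE)
        for (k in intersect(names(ov), names(cfg))) cfg[[k]] <- ov[[k]]
        cfg <- do.call(simulation_config, unclass(cfg)[
          setdiff(names(unclass(cfg)), "drought_calendar")])
      }
      f <- simulate_forest(cfg)
      write_rwl(f$collection, file.path(out_dir, "lw.rwl"), precision = 0.001)
      for (v in names(f$climate))
        write_climate_csv(f$climate[[v]],
                          file.path(out_dir, paste0(tolower(v), ".csv")))
      jsonlite::write_json(
        f$truth[setdiff(names(f$truth), "drought_calendar")],
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      f
    },
    detrend = {
      coll <- read_rwl(.cli_need(fl, "rwl"))
      idx <- lapply(coll$series, standardize)
      chron <- build_chronology(idx)
      write_chronology_csv(chron, .cli_need(fl, "out"))
      chron
    },
    stats = {
      coll <- read_rwl(.cli_need(fl, "rwl"))
      idx <- lapply(coll$series, standardize)
      chron <- build_chronology(idx)
      s <- chron$stats
      jsonlite::write_json(
        list(ms = s$ms, rbar = s$rbar, eps = s$eps,
             common_period = s$common_period, n_series = s$n_series),
        .cli_need(fl, "out"), auto_unbox = TRUE, digits = NA)
      s
    },
    climcorr = {
      chron <- read_chronology_csv(.cli_need(fl, "chron"))
      clim <- read_climate_csv(.cli_need(fl, "climate"), .cli_need(fl, "var"))
      resp <- bootstrap_correlation(
        chron, clim, n_boot = as.integer(fl$nboot %||% 1000L), seed = seed)
      write_response_csv(resp, .cli_need(fl, "out"))
      resp
    },
    resilience = {
      coll <- read_rwl(.cli_need(fl, "rwl"))
      idx <- lapply(coll$series, standardize)
      cal <- read_drought_calendar(fl$events %||% "default")
      rec <- evaluate_resilience(idx)
      utils::write.csv(rec, .cli_need(fl, "out"), row.names = FALSE,
                       quote = FALSE)
      if (!is.null(fl$declines)) {
        dec <- decline_records(idx, cal)
        utils::write.csv(dec, fl$declines, row.names = FALSE, quote = FALSE)
      }
      rec
    },
    `run-all` = {
      raw <- jsonlite::read_json(.cli_need(fl, "config"),
                                 simplifyVector = TRUE)
      det <- do.call(detrend_config, as.list(raw$detrend %||% list()))
      resi <- do.call(resilience_config, as.list(raw$resilience %||% list()))
      sim <- if (!is.null(raw$simulate))
        do.call(simulation_config, as.list(raw$simulate)) else NULL
      run_all(run_config(
        rwl = raw$rwl, climate = as.list(raw$climate), events = raw$events %||% "default",
        simulate = sim, detrend = det, resilience = resi,
        n_boot = raw$n_boot %||% 1000L, alpha = raw$alpha %||% 0.05,
        out_dir = raw$out_dir %||% "droughtring-out",
        seed = as.integer(fl$seed %||% raw$seed %||% 42L)))
    },
    stop("unknown subcommand: ", cmd)))
}
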