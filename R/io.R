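# Configuration files (YAML), plain-text run storage (CSV + JSON
# provenance) and the command-style entry points wrapped by
# scripts/channelfe.R.  Identical configuration + seed yields byte-identical
# metrics files.

#' Read a run configuration from YAML
#'
#' The file may contain the sections `grid`, `forcing`, `eddy`, `ecosystem`
#' and `run`; keys inside each section are the corresponding constructor
#' arguments ([build_grid()], [forcing_params()], [eddy_params()],
#' [eco_params()], [run_config()]).  Unknown sections or keys are rejected
#' with the offending key path.
#'
#' @param path Path to a YAML file.
#' @param overrides Character vector of `"section.key=value"` command-line
#'   style overrides applied after the file is read.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path, overrides = character()) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed configuration file '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (is.null(cfg)) cfg <- list()
  known <- c("grid", "forcing", "eddy", "ecosystem", "run")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([a-z]+)\\.([A-Za-z0-9_]+)=(.*)$", ov))[[1]]
    if (length(m) != 4 || !(m[2] %in% known)) {
      stop("bad override '", ov, "': expected section.key=value with ",
           "section one of ", paste(known, collapse = "/"), call. = FALSE)
    }
    val <- m[4]
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
              else if (val %in% c("TRUE", "true")) TRUE
              else if (val %in% c("FALSE", "false")) FALSE
              else val
    cfg[[m[2]]][[m[3]]] <- parsed
  }
  run_config(grid = cfg$grid %||% list(),
             forcing = cfg$forcing %||% list(),
             eddy = cfg$eddy %||% list(),
             eco = cfg$ecosystem %||% list(),
             run = cfg$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip the class attributes so yaml/jsonlite serialize plain lists
config_as_list <- function(config) {
  lapply(unclass(config), function(s) if (is.list(s)) unclass(s) else s)
}

#' Write a run to a directory of plain-text files
#'
#' Stores a `channel_run` as CSV tables (daily diagnostics, per-process
#' flux profiles in long form, snapshots, final state), the fully resolved
#' configuration as YAML, and a JSON provenance block.  The pair with
#' [read_channel_run()] round-trips the object (the grid is rebuilt from
#' the configuration).
#'
#' @param run A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_channel_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(run$daily, "daily.csv")

  flux_long <- function(a) {
    dn <- dimnames(a)[[3]]
    do.call(rbind, lapply(seq_along(dn), function(ip) {
      data.frame(day = rep(seq_len(dim(a)[1]), times = dim(a)[2]),
                 z_face = rep(seq_len(dim(a)[2]), each = dim(a)[1]),
                 process = dn[ip],
                 flux = as.vector(a[, , ip]))
    }))
  }
  w(flux_long(run$flux_fe), "flux_fe.csv")
  w(flux_long(run$flux_p), "flux_p.csv")

  snap_long <- function(lst, day) {
    do.call(rbind, lapply(seq_along(lst), function(i) {
      m <- lst[[i]]
      data.frame(day = day[i], iy = as.vector(row(m)),
                 iz = as.vector(col(m)), value = as.vector(m))
    }))
  }
  if (length(run$snapshots$day)) {
    w(snap_long(run$snapshots$w, run$snapshots$day), "snapshots_w.csv")
    w(snap_long(run$snapshots$fe, run$snapshots$day), "snapshots_fe.csv")
  }
  state_long <- do.call(rbind, lapply(names(run$state), function(tr) {
    m <- run$state[[tr]]
    data.frame(tracer = tr, iy = as.vector(row(m)), iz = as.vector(col(m)),
               value = as.vector(m))
  }))
  w(state_long, "state.csv")
  w(run$drift, "drift.csv")
  yaml::write_yaml(config_as_list(run$config), file.path(dir, "config.yaml"))
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a run written by [write_channel_run()]
#'
#' @param dir Directory containing the run files.
#' @return A `channel_run` object.
#' @export
read_channel_run <- function(dir) {
  need <- c("config.yaml", "daily.csv", "flux_fe.csv", "state.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("run directory '", dir, "' is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- run_config(grid = cfgl$grid %||% list(),
                       forcing = cfgl$forcing %||% list(),
                       eddy = cfgl$eddy %||% list(),
                       eco = cfgl$eco %||% list(),
                       run = cfgl$run %||% list())
  g <- config$grid
  grid <- build_grid(g$ny, g$nz, g$Ly, g$H, g$stretching, g$dz_surface)

  r <- function(name) utils::read.csv(file.path(dir, name))
  daily <- r("daily.csv")
  wide_flux <- function(df) {
    procs <- FE_PROCS
    nd <- max(df$day); nzf <- max(df$z_face)
    a <- array(0, c(nd, nzf, length(procs)),
               dimnames = list(NULL, NULL, procs))
    for (ip in seq_along(procs)) {
      sub <- df[df$process == procs[ip], ]
      a[, , ip] <- matrix(sub$flux, nd, nzf)
    }
    a
  }
  flux_fe <- wide_flux(r("flux_fe.csv"))
  flux_p <- wide_flux(r("flux_p.csv"))

  snapshots <- list(w = list(), fe = list(), day = numeric())
  if (file.exists(file.path(dir, "snapshots_w.csv"))) {
    sw <- r("snapshots_w.csv"); sf <- r("snapshots_fe.csv")
    days <- sort(unique(sw$day))
    snapshots$day <- days
    for (d in days) {
      sub <- sw[sw$day == d, ]
      snapshots$w[[length(snapshots$w) + 1]] <-
        matrix(sub$value[order(sub$iz, sub$iy)], max(sub$iy), max(sub$iz))
      sub <- sf[sf$day == d, ]
      snapshots$fe[[length(snapshots$fe) + 1]] <-
        matrix(sub$value[order(sub$iz, sub$iy)], max(sub$iy), max(sub$iz))
    }
  }
  st <- r("state.csv")
  state <- lapply(split(st, st$tracer), function(sub) {
    matrix(sub$value[order(sub$iz, sub$iy)], max(sub$iy), max(sub$iz))
  })
  state <- state[intersect(c("b", "Fe", "P", "Z", "D"), names(state))]
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  drift <- if (file.exists(file.path(dir, "drift.csv"))) r("drift.csv")
           else NULL
  structure(list(config = config, grid = grid, daily = daily,
                 flux_fe = flux_fe, flux_p = flux_p, snapshots = snapshots,
                 state = state, drift = drift, provenance = prov),
            class = "channel_run")
}

#' Run an experiment from a configuration file
#'
#' Reads and validates the configuration, applies overrides, runs
#' [run_experiment()], and writes the run directory plus the bloom-series
#' metrics CSV.  Log lines report per-year spin-up drift.
#'
#' @param config_path Path to a YAML configuration (`NULL` for defaults).
#' @param overrides Character vector of `"section.key=value"` overrides.
#' @param out_dir Output directory.
#' @param quiet Suppress log messages.
#' @return The `channel_run`, invisibly.
#' @export
cli_run <- function(config_path = NULL, overrides = character(),
                    out_dir = "channelfe_run", quiet = FALSE) {
  config <- if (is.null(config_path)) {
    run_config()
  } else {
    read_run_config(config_path, overrides)
  }
  if (is.null(config_path) && length(overrides)) {
    tmp <- tempfile(fileext = ".yaml"); on.exit(unlink(tmp))
    yaml::write_yaml(list(), tmp)
    config <- read_run_config(tmp, overrides)
  }
  run <- run_experiment(config)
  if (!quiet) {
    for (i in seq_len(nrow(run$drift))) {
      message(sprintf("spin-up year %d: drift Fe %.4f, P %.4f",
                      run$drift$year[i],
                      run$drift$drift_fe[i], run$drift$drift_p[i]))
    }
  }
  write_channel_run(run, out_dir)
  bs <- bloom_series(run)
  utils::write.csv(bs, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  invisible(run)
}

#' Recompute all diagnostics from a stored run
#'
#' Idempotent: reading the run back and recomputing produces the same
#' metrics file.
#'
#' @param run_dir Directory written by [cli_run()] / [write_channel_run()].
#' @param out_csv Path of the metrics CSV (default inside `run_dir`).
#' @return The bloom-series data frame, invisibly.
#' @export
cli_diagnose <- function(run_dir, out_csv = file.path(run_dir,
                                                      "metrics.csv")) {
  run <- read_channel_run(run_dir)
  bs <- bloom_series(run)
  utils::write.csv(bs, out_csv, row.names = FALSE)
  invisible(bs)
}

#' Compare stored scenario runs
#'
#' @param run_dirs Character vector of run directories (at least one).
#' @param out_csv Path for the comparison table.
#' @return The [scenario_compare()] data frame, invisibly.
#' @export
cli_compare <- function(run_dirs, out_csv = "scenario_compare.csv") {
  if (length(run_dirs) < 1) stop("usage: need at least one run directory",
                                 call. = FALSE)
  runs <- lapply(run_dirs, read_channel_run)
  tab <- scenario_compare(runs)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  invisible(tab)
}
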