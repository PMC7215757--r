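#' Read a release curve from delimited text
#'
#' Reads a CSV with header columns `time_h,value` (extra columns are
#' ignored), validates it, and returns a [release_curve] with rows
#' ordered by time. Malformed input raises a parse error naming the
#' offending line (header = line 1).
#'
#' @param path Path to the CSV file.
#' @param scale Scale of the values: `"percent"` or `"mass_ug"`.
#' @param label Curve label; defaults to the file name.
#' @return A [release_curve].
#' @export
read_release_csv <- function(path, scale = c("percent", "mass_ug"),
                             label = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- basename(path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("time_h", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parse error in ", path, " line 1: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    bad <- union(bad, which(is.na(v)))
    if (length(bad)) {
      stop("parse error in ", path, " line ", bad[1] + 1L,
           ": non-numeric '", col, "' value '", df[[col]][bad[1]], "'")
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df$time_h))
  if (length(dup)) {
    stop("parse error in ", path, " line ", dup[1] + 1L,
         ": duplicate time ", df$time_h[dup[1]])
  }
  ord <- order(df$time_h)
  release_curve(df$time_h[ord], df$value[ord], scale = scale, label = label)
}

#' Write a release curve as delimited text
#'
#' Writes columns `time_h,value` with full double precision so that
#' [read_release_csv()] round-trips the values bit-identically.
#'
#' @param curve A [release_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  lines <- c("time_h,value",
             sprintf("%.17g,%.17g", curve$times, curve$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read a formulation registry from YAML or JSON
#'
#' A registry is a list of entries with fields `name`, `a`, `b` and
#' optional `scale` (default `"percent"`), `loading`, `ee_percent`.
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param path Path to the registry file.
#' @return A named list of [formulation] objects.
#' @export
read_formulation_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = FALSE),
                stop("unsupported registry format '.", ext,
                     "': use .yaml/.yml or .json"))
  if (!is.list(raw) || length(raw) == 0L) stop("empty registry: ", path)
  out <- lapply(raw, function(e) {
    if (is.null(e$name) || is.null(e$a) || is.null(e$b)) {
      stop("registry entry needs fields name, a, b")
    }
    formulation(e$name, a = e$a, b = e$b,
                scale = if (is.null(e$scale)) "percent" else e$scale,
                loading = e$loading, ee_percent = e$ee_percent)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write a formulation registry
#'
#' @param formulations Named or unnamed list of [formulation] objects.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_formulation_registry <- function(formulations, path) {
  entries <- lapply(formulations, function(f) {
    e <- list(name = f$name, a = f$params$a, b = f$params$b,
              scale = f$scale)
    if (!is.null(f$loading)) e$loading <- f$loading
    if (!is.null(f$ee_percent)) e$ee_percent <- f$ee_percent
    e
  })
  names(entries) <- NULL
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(entries, path, precision = 15),
         json = jsonlite::write_json(entries, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported registry format '.", ext, "'"))
  invisible(path)
}

#' Run the fit-and-predict release pipeline
#'
#' The end-to-end workflow: fit the first-order model to every input
#' curve, tabulate the fitted parameters with their goodness of fit, and
#' evaluate requested mixture predictions at requested times. Outputs are
#' deterministic for fixed inputs; when `outdir` is given, machine-
#' readable `fits.csv`, `predictions.csv` and `report.json` are written
#' there, and a human-readable summary (4 significant figures) goes to
#' the console. Progress/log lines go to `message()` (stderr). Any stage
#' failure is re-raised with the stage and item name attached.
#'
#' @param curves Named list of [release_curve] objects and/or CSV paths
#'   (read with [read_release_csv()]); the names identify formulations.
#' @param mixtures Named list of mixture requests; each request is a
#'   named numeric vector of mass-percent weights over a subset of the
#'   curve names (weights must sum to 100).
#' @param times Times (hours) at which mixture predictions are evaluated;
#'   default `c(1, 2, 4, 8, 24, 48, 72)`.
#' @param scale Scale of the input curves, used when reading CSV paths
#'   and attached to predictions.
#' @param outdir Optional output directory (created if needed).
#' @param quiet Suppress log messages.
#' @return A list of class `release_pipeline_report`: `fits` (data frame:
#'   name, a, b, rss, r2, r2_adj, n_obs, converged), `predictions` (data
#'   frame: mixture, time_h, value, scale), `scale`, and `paths` of any
#'   files written.
#' @export
run_pipeline <- function(curves, mixtures = list(),
                         times = default_release_times(),
                         scale = c("percent", "mass_ug"),
                         outdir = NULL, quiet = FALSE) {
  scale <- match.arg(scale)
  if (!is.list(curves) || is.null(names(curves)) ||
      any(!nzchar(names(curves)))) {
    stop("curves must be a named list")
  }
  say <- function(...) if (!quiet) message("[releasemix] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  curves <- stage("read", {
    lapply(stats::setNames(names(curves), names(curves)), function(nm) {
      x <- curves[[nm]]
      if (inherits(x, "release_curve")) x
      else read_release_csv(x, scale = scale, label = nm)
    })
  })
  say("read ", length(curves), " curve(s)")

  fits <- stage("fit", lapply(curves, fit_first_order))
  fit_tab <- data.frame(
    name = names(fits),
    a = vapply(fits, function(f) f$params$a, numeric(1)),
    b = vapply(fits, function(f) f$params$b, numeric(1)),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"),
    n_obs = vapply(fits, `[[`, integer(1), "n_obs"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  say("fitted ", nrow(fit_tab), " formulation(s)")

  forms <- lapply(names(fits), function(nm) {
    formulation(nm, a = fits[[nm]]$params$a, b = fits[[nm]]$params$b,
                scale = scale)
  })
  names(forms) <- names(fits)

  pred_tab <- stage("predict", {
    rows <- lapply(names(mixtures), function(mx) {
      w <- mixtures[[mx]]
      if (is.null(names(w)) || !all(names(w) %in% names(forms))) {
        stop("mixture '", mx, "' references unknown formulations: ",
             paste(setdiff(names(w), names(forms)), collapse = ", "))
      }
      mix <- mixture_spec(forms[names(w)], as.numeric(w))
      val <- if (scale == "percent") predict_mixture_percent(mix, times)
             else predict_mixture_mass(mix, times)
      data.frame(mixture = mx, time_h = times, value = val,
                 scale = scale, row.names = NULL)
    })
    if (length(rows)) do.call(rbind, rows)
    else data.frame(mixture = character(), time_h = numeric(),
                    value = numeric(), scale = character())
  })
  say("evaluated ", length(mixtures), " mixture request(s) at ",
      length(times), " time(s)")

  paths <- character()
  if (!is.null(outdir)) {
    paths <- stage("write", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(outdir, c("fits.csv", "predictions.csv", "report.json"))
      utils::write.csv(format_full(fit_tab), p[1], row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(format_full(pred_tab), p[2], row.names = FALSE,
                       quote = FALSE)
      jsonlite::write_json(list(fits = fit_tab, predictions = pred_tab,
                                scale = scale, times = times),
                           p[3], auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      say("wrote ", paste(basename(p), collapse = ", "), " to ", outdir)
      p
    })
  }

  structure(list(fits = fit_tab, predictions = pred_tab, scale = scale,
                 paths = paths),
            class = "release_pipeline_report")
}

# Full-precision numeric formatting for machine-readable CSV.
format_full <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

#' @export
print.release_pipeline_report <- function(x, ...) {
  cat("Release pipeline report (", x$scale, " scale)\n", sep = "")
  cat("\nFitted formulations:\n")
  ft <- x$fits
  for (col in c("a", "b", "rss", "r2", "r2_adj")) ft[[col]] <- signif(ft[[col]], 4)
  print(ft, row.names = FALSE)
  if (nrow(x$predictions)) {
    cat("\nMixture predictions:\n")
    pt <- x$predictions
    pt$value <- signif(pt$value, 4)
    print(pt, row.names = FALSE)
  }
  invisible(x)
}
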