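#' Pipeline configuration
#'
#' All tunable constants of the delineator, with the published defaults.
#' Sample-denominated constants are defined at 1000 Hz. Unknown keys are
#' rejected.
#'
#' @param ... named overrides of the defaults listed below.
#' @return object of class `vcg_config` (a named list).
#' @section Keys:
#' \describe{
#'   \item{ratio_o, ratio_a, ttg, tte, eps_refine}{QRS peak detector:
#'     global threshold ratio 0.7, within-beat ratio 0.7, beat gap 200,
#'     edge zone 200, apex search half-width 10 samples.}
#'   \item{ttls, ratio_ls, ttsn, ttln, trace_gamma}{onset/end zero-crossing
#'     logic: search half-width 150, oscillation ratio 0.3, short/long
#'     unsuitable-interval limits 10/25 samples, trace fraction 0.05.}
#'   \item{tt1ls, tt2ls, tt3ls, eps1, eps2, ttar, wide_energy_ratio,
#'     near_energy_frac}{wide-QRS switching: energy windows 200 samples,
#'     near zones 16/24, scale-70 peak pad 50, 120:70 energy ratio 2,
#'     near-zone veto fraction 0.5.}
#'   \item{tw, start, stop, delta, thslope, slope_fire_min_shift}{slope
#'     refinement: window 10, span 30/0, step 2 samples, slope threshold 10
#'     GAIN.mV per sample, firing shift 3 samples.}
#'   \item{ttbs}{cross-lead alignment threshold, 80 samples.}
#'   \item{tw1, start1, stop1, delta1}{PQ window search: width 20, span
#'     50/10, step 2 samples.}
#'   \item{hp_passband_hz, hp_stopband_hz, hp_stop_atten_db, notch_f0,
#'     notch_bw_hz, notch_atten_db, notch_mode, powerline_ratio}{filters;
#'     `notch_mode` is TRUE, FALSE or `"auto"`.}
#'   \item{scales}{CWT scales computed by the pipeline stack.}
#'   \item{preprocess}{logical; run the filters before delineation.}
#' }
#' @export
vcg_config <- function(...) {
  defaults <- list(
    ratio_o = 0.7, ratio_a = 0.7, ttg = 200, tte = 200, eps_refine = 10,
    ttls = 150, ratio_ls = 0.3, ttsn = 10, ttln = 25, trace_gamma = 0.05,
    tt1ls = 200, tt2ls = 200, tt3ls = 200, eps1 = 16, eps2 = 24, ttar = 50,
    wide_energy_ratio = 2, near_energy_frac = 0.5,
    tw = 10, start = 30, stop = 0, delta = 2, thslope = 10,
    slope_fire_min_shift = 3,
    ttbs = 80,
    tw1 = 20, start1 = 50, stop1 = 10, delta1 = 2,
    hp_passband_hz = 1.0, hp_stopband_hz = 0.5, hp_stop_atten_db = 61,
    notch_f0 = 50, notch_bw_hz = 0.17, notch_atten_db = 60,
    notch_mode = "auto", powerline_ratio = 4,
    scales = c(30, 70, 120),
    preprocess = TRUE
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("config overrides must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(utils::modifyList(defaults, over), class = "vcg_config")
}

#' @export
print.vcg_config <- function(x, ...) {
  cat("<vcg_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format_cfg_value(x[[k]])))
  invisible(x)
}

format_cfg_value <- function(v) {
  if (is.character(v)) v else paste(format(v, digits = 15), collapse = ",")
}

#' Write / read a configuration as flat key = value text
#'
#' One `key = value` line per entry; numeric vectors are comma separated.
#' A dump-load-dump cycle is the identity.
#'
#' @param config a [vcg_config()].
#' @param path file path.
#' @return `config_write` returns `path` invisibly; `config_read` returns a
#'   [vcg_config()].
#' @export
config_write <- function(config, path) {
  stopifnot(inherits(config, "vcg_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, format_cfg_value(config[[k]]))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([a-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) stop("malformed config line")
    val <- m[3]
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[m[2]]] <- if (!anyNA(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  do.call(vcg_config, out)
}
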