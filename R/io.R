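#' Build a model from a configuration file and/or overrides
#'
#' Reads a flat YAML file with keys among `alpha`, `beta`, `k_minus`, `D`,
#' `D_t`, `k_plus`, `N`, `r`, `V`, `target_mean_nM`, `preset`, merges
#' explicit overrides on top (overrides win), and validates the result with
#' [qs_model()]. A `preset` supplies the standard parameterisation first
#' and the remaining keys override its fields. There are no silent
#' defaults for the switching rates: without a preset, `alpha` and `beta`
#' are required. Unknown keys and a `D`/`D_t` conflict are errors.
#'
#' @param path path to a YAML config file, or `NULL`.
#' @param overrides named list of keys (same vocabulary) overriding the
#'   file, e.g. from command-line flags.
#' @return A `"qs_model"`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    # YAML 1.1 resolves a bare `N` key to the boolean FALSE; undo that so
    # the documented key works unquoted
    names(cfg)[names(cfg) %in% c("FALSE", "F")] <- "N"
  }
  cfg[names(overrides)] <- overrides
  valid <- c("alpha", "beta", "k_minus", "D", "D_t", "k_plus", "N", "r",
             "V", "target_mean_nM", "preset")
  bad <- setdiff(names(cfg), valid)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  if (!is.null(cfg[["D"]]) && !is.null(cfg[["D_t"]]))
    stop("give either `D` or `D_t`, not both")
  if (!is.null(cfg[["preset"]])) {
    base <- qs_preset(cfg[["preset"]], D_t = cfg[["D_t"]] %||% 0)
    take <- function(key, def) cfg[[key]] %||% def
    args <- list(alpha = take("alpha", base$alpha),
                 beta = take("beta", base$beta),
                 k_minus = take("k_minus", base$k_minus),
                 N = take("N", base$N), r = take("r", base$r),
                 V = take("V", base$V),
                 k_plus = cfg[["k_plus"]],
                 target_mean_nM = take("target_mean_nM", base$target_mean_nM))
    if (!is.null(cfg[["D"]])) args$D <- cfg[["D"]]
    else args$D_t <- cfg[["D_t"]] %||% 0
    m <- do.call(qs_model, args)
    m$preset <- cfg[["preset"]]
    return(m)
  }
  if (is.null(cfg[["alpha"]]) || is.null(cfg[["beta"]]))
    stop("config must set `alpha` and `beta` (or a `preset`); ",
         "no silent defaults for rates")
  if (is.null(cfg[["D"]]) && is.null(cfg[["D_t"]]))
    stop("config must set `D` or `D_t`")
  do.call(qs_model, cfg)
}

# 17 significant digits: round-trips doubles exactly through text
.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a diffusion scan as CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal separator, floats at 17 significant
#' digits (lossless for doubles). Identical seeds and parameters produce
#' byte-identical files.
#'
#' @param scan a `"qs_scan"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  df <- as.data.frame(scan)
  cols <- lapply(df, function(col)
    if (is.double(col)) .fmt(col) else as.character(col))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\r\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a scan CSV
#' @param path file written by [write_scan_csv()].
#' @export
read_scan_csv <- function(path) {
  utils::read.csv(path)
}

#' Serialise estimates to JSON and back
#'
#' `write_run_json()` stores any list of noise estimates / run summaries
#' with full double precision (no rounding), so reloading reproduces every
#' number bit-exactly.
#'
#' @param x a list (e.g. of `"qs_noise"` records, stripped to plain lists).
#' @param path output file.
#' @export
write_run_json <- function(x, path) {
  strip <- function(v) {
    if (inherits(v, "qs_noise"))
      v <- v[c("eta2", "se", "per_replicate", "n_reps", "source", "seeds")]
    if (is.list(v)) lapply(v, strip) else v
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_run_json
#' @export
read_run_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run manifest
#'
#' Records the command, the full parameter echo (dimensional and
#' dimensionless), seeds, package version, timestamps and md5 digests of
#' the produced files, next to the outputs. Outputs are reproducible from
#' their manifest: the same seeds give identical numbers (the manifest's
#' own timestamps naturally differ between invocations).
#'
#' @param path manifest file to create (JSON).
#' @param command free-form description of the invocation.
#' @param model the `"qs_model"` used.
#' @param seeds seeds used.
#' @param files character vector of produced output files.
#' @export
write_manifest <- function(path, command, model, seeds, files = character()) {
  d <- dimensionless(model)
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("qsnoise")),
    rng = list(kind = RNGkind()[1], seeds = seeds),
    params = list(physical = unclass(model)[c("alpha", "beta", "k_plus",
                                              "k_minus", "D", "N", "r", "V")],
                  dimensionless = unclass(d)[c("alpha_t", "beta_t", "D_t",
                                               "Nr", "k_eff", "k_plus_eff")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
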