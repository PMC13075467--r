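#' Round half away from zero
#'
#' Integer rounding with the half-up convention used in clinical summary
#' tables (so 43.5 -> 44), rather than base R's round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_up(c(43.5, 44.5, 20.4))
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Emit a pipeline log message
#'
#' INFO messages are printed only when `options(cfrank.verbose = TRUE)`;
#' WARN messages are raised as R warnings so they are never silently lost.
#'
#' @param fmt An [sprintf()] format string.
#' @param ... Values interpolated into `fmt`.
#' @param level `"INFO"`, `"DEBUG"` or `"WARN"`.
#' @return Invisibly `NULL`.
#' @export
cf_log <- function(fmt, ..., level = "INFO") {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  if (identical(level, "WARN")) {
    warning(msg, call. = FALSE)
  } else if (isTRUE(getOption("cfrank.verbose", FALSE))) {
    message("[", level, "] ", msg)
  }
  invisible(NULL)
}

#' Derive a reproducible per-entity RNG seed
#'
#' Hashes an identifier (e.g. a sample id) together with a base seed so that
#' each simulated sample gets its own reproducible RNG stream, independent of
#' the order in which samples are generated.
#'
#' @param seed Integer base seed.
#' @param id Character scalar identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Internal: check a probability-like scalar.
is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Internal: stop unless all names are columns of df.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a key-value configuration file
#'
#' Reads a YAML file naming pipeline inputs and parameters (paths, window
#' size, seeds). Values are returned as a named list; nothing is validated
#' beyond YAML syntax, so downstream constructors apply their own checks.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key-value mapping", call. = FALSE)
  cf_log("read %d config entries from %s", length(cfg), path)
  cfg
}
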