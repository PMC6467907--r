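#' Model parameters for the maternal risk-management classifier
#'
#' Bundles the constants of the risk-management model: the replacement-fitness
#' constant `w` (a brood "replaces" the breeder when at least `w` offspring
#' survive: one fertile daughter and one outbreeding son), the set points that
#' partition the investment plane (S, N) into the four selection categories,
#' and the substitute offspring quantity used for broods smaller than `w`.
#'
#' Defaults are the values used for the 87-species classification the model
#' was introduced with: `w = 2`, `s_setpoint = 0.1`, `n_setpoint = 10`,
#' `n_substitute = 2.1`. Set points are study-scope decisions, not estimated
#' from data.
#'
#' @param w Replacement fitness constant (offspring count, > 0).
#' @param s_setpoint Relative-quality threshold separating the low-S
#'   (predation/weak) from the high-S (scarcity/convergent) half-plane.
#'   Comparisons are `S <= s_setpoint` for the low side.
#' @param n_setpoint Offspring-quantity threshold; `N <= n_setpoint` is the
#'   low-quantity side.
#' @param n_substitute Offspring quantity substituted for broods with
#'   `N < w`, so that the predation-mortality formula stays positive. Must
#'   exceed `w`.
#'
#' @return An object of class `matrisk_params`: a named list with the four
#'   constants.
#' @examples
#' model_params()
#' model_params(n_setpoint = 5)
#' @export
model_params <- function(w = 2, s_setpoint = 0.1, n_setpoint = 10,
                         n_substitute = 2.1) {
  stopifnot(
    "`w` must be a single positive number" =
      is.numeric(w) && length(w) == 1 && is.finite(w) && w > 0,
    "`s_setpoint` must be a single positive number" =
      is.numeric(s_setpoint) && length(s_setpoint) == 1 && s_setpoint > 0,
    "`n_setpoint` must be a single number >= 1" =
      is.numeric(n_setpoint) && length(n_setpoint) == 1 && n_setpoint >= 1,
    "`n_substitute` must be a single number" =
      is.numeric(n_substitute) && length(n_substitute) == 1
  )
  if (n_substitute <= w) {
    stop("`n_substitute` must exceed `w` so that substituted broods have P > 0",
         call. = FALSE)
  }
  structure(
    list(w = w, s_setpoint = s_setpoint, n_setpoint = n_setpoint,
         n_substitute = n_substitute),
    class = "matrisk_params"
  )
}

#' @export
print.matrisk_params <- function(x, ...) {
  cat("<matrisk model parameters>\n")
  cat(sprintf("  w (replacement fitness): %g offspring\n", x$w))
  cat(sprintf("  S set point:             %g\n", x$s_setpoint))
  cat(sprintf("  N set point:             %g\n", x$n_setpoint))
  cat(sprintf("  singleton substitute N:  %g\n", x$n_substitute))
  invisible(x)
}

#' Read model parameters from a JSON or YAML config file
#'
#' The file may define any subset of `w`, `s_setpoint`, `n_setpoint`,
#' `n_substitute`; missing keys fall back to the defaults of
#' [model_params()]. Format is chosen by file extension (`.json` vs
#' `.yml`/`.yaml`); anything else is tried as JSON first, then YAML.
#'
#' @param path Path to the config file.
#' @return A `matrisk_params` object.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{"n_setpoint": 5}', cfg)
#' read_model_config(cfg)
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) yaml::read_yaml(path))
  }
  if (!is.list(vals)) stop("config must be a mapping of parameter names",
                           call. = FALSE)
  known <- c("w", "s_setpoint", "n_setpoint", "n_substitute")
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  args <- vals[intersect(names(vals), known)]
  do.call(model_params, args)
}

# Coerce NULL -> default params; validate class otherwise.
as_params <- function(params) {
  if (is.null(params)) return(model_params())
  if (!inherits(params, "matrisk_params")) {
    stop("`params` must be created by model_params() or read_model_config()",
         call. = FALSE)
  }
  params
}
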