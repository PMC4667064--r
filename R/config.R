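#' Runtime configuration for fusion and metrics
#'
#' Central parameter record shared by the library front ends and the CLI.
#' The defaults are the reference operating point for 8-bit, 256 x 256
#' sources: adaptive manifold filter scales `sigma_s = 14` pixels and
#' `sigma_r = 0.10` (on the normalized unit intensity range), a 3 x 3 MSF
#' window, and 256 histogram bins for mutual information.
#'
#' @param sigma_s spatial standard deviation in pixels.
#' @param sigma_r range standard deviation in normalized intensity units.
#' @param msf_window_radius MSF sliding-window radius in pixels.
#' @param metric_bins histogram bin count for mutual information.
#' @return object of class `run_config`.
#' @export
run_config <- function(sigma_s = 14, sigma_r = 0.10, msf_window_radius = 1L,
                       metric_bins = 256L) {
  if (sigma_s <= 0 || sigma_r <= 0)
    stop("filter standard deviations must be positive", call. = FALSE)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 msf_window_radius = as.integer(msf_window_radius),
                 metric_bins = as.integer(metric_bins)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value document mirroring the [run_config()] field
#' names (`sigma_s`, `sigma_r`, `msf_window_radius`, `metric_bins`); absent
#' keys keep their defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("run_config: sigma_s=%g px, sigma_r=%g, ",
                     "msf_window_radius=%d, metric_bins=%d\n"),
              x$sigma_s, x$sigma_r, x$msf_window_radius, x$metric_bins))
  invisible(x)
}
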