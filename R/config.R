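#' Variational inference configuration
#'
#' Bundles every tunable of the per-gene variational fit. Defaults are the
#' package's reference settings; all are plain numbers so a configuration
#' can round-trip through a key-value text file.
#'
#' @param max_iter Maximum number of coordinate-ascent sweeps.
#' @param tol Relative ELBO convergence tolerance: the fit stops when
#'   `|delta ELBO| < tol * |ELBO|`.
#' @param omega_grid_size Number of quadrature points for the dispersion.
#' @param omega_range Range of the dispersion grid; points are placed
#'   uniformly in `log(omega)`.
#' @param intercept_var Prior variance of the intercept (normal prior,
#'   mean zero).
#' @param omega_prior_shape,omega_prior_rate Gamma prior on the dispersion.
#' @param clip Exponent bound: arguments of `exp()` inside the expected
#'   inverse-link are clipped to `[-clip, clip]` (clip events are counted
#'   on the state).
#' @param damping_max Maximum number of step halvings after a
#'   coefficient update that lowers the ELBO.
#' @param damping_tol Tolerated ELBO drop (relative) before damping kicks in.
#' @param fixed_omega Optional positive value: treat the dispersion as known
#'   and skip its update (used for tractable-toy checks).
#' @param fixed_zeta2 Optional positive value: freeze every local shrinkage
#'   scale at this value and skip the horseshoe updates.
#' @param verbose Print per-sweep ELBO values.
#' @return A list of class `vb_config`.
#' @export
vb_config <- function(max_iter = 500L,
                      tol = 1e-6,
                      omega_grid_size = 200L,
                      omega_range = c(1e-2, 1e3),
                      intercept_var = 100,
                      omega_prior_shape = 0.01,
                      omega_prior_rate = 0.01,
                      clip = 50,
                      damping_max = 8L,
                      damping_tol = 1e-8,
                      fixed_omega = NULL,
                      fixed_zeta2 = NULL,
                      verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, omega_grid_size >= 2,
            length(omega_range) == 2, omega_range[1] > 0,
            omega_range[2] > omega_range[1],
            intercept_var > 0, omega_prior_shape > 0, omega_prior_rate > 0,
            clip > 0, damping_max >= 0, damping_tol >= 0)
  if (!is.null(fixed_omega) && fixed_omega <= 0) abort("`fixed_omega` must be positive.")
  if (!is.null(fixed_zeta2) && fixed_zeta2 <= 0) abort("`fixed_zeta2` must be positive.")
  structure(
    list(max_iter = as.integer(max_iter), tol = tol,
         omega_grid_size = as.integer(omega_grid_size),
         omega_range = as.numeric(omega_range),
         intercept_var = intercept_var,
         omega_prior_shape = omega_prior_shape,
         omega_prior_rate = omega_prior_rate,
         clip = clip, damping_max = as.integer(damping_max),
         damping_tol = damping_tol,
         fixed_omega = fixed_omega, fixed_zeta2 = fixed_zeta2,
         verbose = isTRUE(verbose)),
    class = "vb_config"
  )
}

#' Write / read a configuration as plain text
#'
#' Serializes a [vb_config()] to `key = value` lines so that a run's full
#' effective configuration can be logged and reloaded.
#'
#' @param config A `vb_config` object.
#' @param path File path.
#' @return `write_vb_config()` returns `path` invisibly; `read_vb_config()`
#'   returns a `vb_config`.
#' @export
write_vb_config <- function(config, path) {
  stopifnot(inherits(config, "vb_config"))
  fmt <- function(v) {
    if (is.null(v)) "NULL" else paste(format(v, digits = 17), collapse = ",")
  }
  lines <- vapply(names(config), function(k) paste0(k, " = ", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vb_config
#' @export
read_vb_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- p[[2]]
    if (v == "NULL") return(NULL)
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(vb_config, vals)
}
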