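#' Receptor model parameters
#'
#' Bundle the five constants of the campaniform-sensillum discharge model
#' together with a subgroup label and the sign convention applied to the
#' bending force before simulation. The discharge is
#' `y = max(0, a*(u - x) + c*u + d)` where the dynamic threshold `x`
#' follows `tau * dx/dt = sign(u - x) * |u - x|^b`.
#'
#' The default values are a demonstration tuning that produces a
#' phasic-plus-tonic on-response and duration-dependent off-responses; the
#' tunings used for published species-specific simulations are not part of
#' this package.
#'
#' @param a Adaptive (phasic) gain, impulses s^-1 per mN.
#' @param b Adaptation nonlinearity exponent (dimensionless, > 0). `b = 1`
#'   gives exponential threshold relaxation; `b > 1` gives a power-law
#'   tail; `b < 1` gives finite-time convergence.
#' @param c Tonic gain, impulses s^-1 per mN.
#' @param d Constant discharge offset, impulses s^-1.
#' @param tau Threshold time constant, seconds (> 0).
#' @param subgroup `"agonist"` for receptors excited by increasing bending
#'   force (stick insect 6B / cockroach proximal) or `"antagonist"` for the
#'   subgroup with opposite directional sensitivity (6A / distal).
#' @param input_sign +1 or -1, applied to the force before simulation.
#'   Defaults to +1 for the agonist subgroup and -1 for the antagonist.
#'
#' @return An object of class `cs_params`.
#' @examples
#' cs_params()
#' cs_params(subgroup = "antagonist")
#' @export
cs_params <- function(a = 60, b = 1.2, c = 10, d = -1, tau = 0.4,
                      subgroup = c("agonist", "antagonist"),
                      input_sign = NULL) {
  subgroup <- match.arg(subgroup)
  if (is.null(input_sign)) {
    input_sign <- if (subgroup == "agonist") 1 else -1
  }
  for (nm in c("a", "b", "c", "d", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number"),
            class = "campaniform_parameter_error")
    }
  }
  if (tau <= 0) {
    abort("`tau` must be > 0", class = "campaniform_parameter_error")
  }
  if (b <= 0) {
    abort("`b` must be > 0", class = "campaniform_parameter_error")
  }
  if (!input_sign %in% c(-1, 1)) {
    abort("`input_sign` must be +1 or -1",
          class = "campaniform_parameter_error")
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d), tau = as.numeric(tau),
         subgroup = subgroup, input_sign = as.numeric(input_sign)),
    class = "cs_params"
  )
}

#' @export
print.cs_params <- function(x, ...) {
  cat("<cs_params> ", x$subgroup, " (input sign ",
      ifelse(x$input_sign > 0, "+1", "-1"), ")\n", sep = "")
  cat(sprintf("  a = %g Hz/mN, b = %g, c = %g Hz/mN, d = %g Hz, tau = %g s\n",
              x$a, x$b, x$c, x$d, x$tau))
  invisible(x)
}

#' @export
format.cs_params <- function(x, ...) {
  sprintf("cs_params(a=%g, b=%g, c=%g, d=%g, tau=%g, %s)",
          x$a, x$b, x$c, x$d, x$tau, x$subgroup)
}

as_cs_params <- function(x) {
  if (inherits(x, "cs_params")) return(x)
  if (!is.list(x)) {
    abort("model parameters must be a cs_params object or a named list",
          class = "campaniform_parameter_error")
  }
  do.call(cs_params, x[intersect(names(x),
                                 c("a", "b", "c", "d", "tau",
                                   "subgroup", "input_sign"))])
}

#' Read and write model parameters as JSON
#'
#' Parameters round-trip losslessly (full double precision) through a flat
#' JSON object with keys `a`, `b`, `c`, `d`, `tau`, `subgroup`,
#' `input_sign`.
#'
#' @param params A [cs_params()] object.
#' @param path File path.
#' @return `read_params()` returns a `cs_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cs_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  as_cs_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Viscoelastic cuticle parameters (standard linear solid)
#'
#' Constants of a Zener (standard linear solid) description of the leg
#' cuticle: an instantaneous spring `k0` in series with a delayed
#' Kelvin-Voigt arm of stiffness `k1`. The equilibrium stiffness is
#' `k_eq = (1/k0 + 1/k1)^-1 < k0`. Creep and relaxation time constants are
#' kept as independent fields so asymmetric data can be fitted; a strict
#' Zener ties them together.
#'
#' @param k0 Instantaneous stiffness, mN per length unit (> 0).
#' @param k1 Delayed stiffness, mN per length unit (> 0).
#' @param tau_c Creep time constant, s (> 0).
#' @param tau_r Stress-relaxation time constant, s (> 0).
#' @return An object of class `zener_params` (with derived field `k_eq`).
#' @examples
#' zener_params()
#' @export
zener_params <- function(k0 = 10, k1 = 20, tau_c = 1.5, tau_r = 1.5) {
  for (nm in c("k0", "k1", "tau_c", "tau_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"),
            class = "campaniform_parameter_error")
    }
  }
  structure(
    list(k0 = as.numeric(k0), k1 = as.numeric(k1),
         tau_c = as.numeric(tau_c), tau_r = as.numeric(tau_r),
         k_eq = 1 / (1 / k0 + 1 / k1)),
    class = "zener_params"
  )
}

#' @export
print.zener_params <- function(x, ...) {
  cat("<zener_params>\n")
  cat(sprintf("  k0 = %g, k1 = %g mN/unit (k_eq = %g)\n", x$k0, x$k1, x$k_eq))
  cat(sprintf("  tau_c = %g s, tau_r = %g s\n", x$tau_c, x$tau_r))
  invisible(x)
}

as_zener_params <- function(x) {
  if (inherits(x, "zener_params")) return(x)
  if (!is.list(x)) {
    abort("cuticle parameters must be a zener_params object or a named list",
          class = "campaniform_parameter_error")
  }
  do.call(zener_params,
          x[intersect(names(x), c("k0", "k1", "tau_c", "tau_r"))])
}
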