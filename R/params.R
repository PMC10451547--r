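#' Kinetic parameters of the radical-generating system
#'
#' Bundles the rate constants and initiator load that define the radical
#' source term and radical-radical recombination.  The initiation rate is
#' `Wi(t) = 2 * efficiency * ki * [I](t)`; with the defaults (0.1 M AAPH at
#' 37 degC, `ki = 1e-6` 1/s) this gives the commonly used
#' `Wi = 2e-7` M/s at `t = 0`.
#'
#' @param ki First-order initiator decomposition constant, 1/s.  The
#'   standard magnitude for AAPH at 37 degC is about `1e-6` 1/s.
#' @param two_k2 Lumped peroxyl-radical recombination/disproportionation
#'   constant `2*k2`, 1/(M*s).  Default `5e4`.
#' @param initiator_c0 Initial initiator concentration, M.  Default 0.1 M.
#' @param temperature Reaction temperature, K.  Default 310.15 K (37 degC).
#' @param efficiency Radical cage-escape efficiency in (0, 1]; the fraction
#'   of decomposition events that release two scavengeable peroxyl radicals.
#'   Default 1.
#'
#' @return An object of class `kp_rate_params`.
#' @examples
#' p <- rate_params()
#' initiation_rate(p, 0)   # 2e-7 M/s
#' @export
rate_params <- function(ki = 1e-6,
                        two_k2 = 5e4,
                        initiator_c0 = 0.1,
                        temperature = 310.15,
                        efficiency = 1) {
  stopifnot(is.numeric(ki), length(ki) == 1L,
            is.numeric(two_k2), length(two_k2) == 1L,
            is.numeric(initiator_c0), length(initiator_c0) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (ki <= 0) abort("`ki` must be strictly positive.")
  if (two_k2 <= 0) abort("`two_k2` must be strictly positive.")
  if (initiator_c0 < 0) abort("`initiator_c0` must be non-negative.")
  if (temperature < 273 || temperature > 373)
    abort("`temperature` must lie in [273, 373] K.")
  if (efficiency <= 0 || efficiency > 1)
    abort("`efficiency` must lie in (0, 1].")
  structure(
    list(ki = ki, two_k2 = two_k2, initiator_c0 = initiator_c0,
         temperature = temperature, efficiency = efficiency),
    class = "kp_rate_params"
  )
}

#' @export
print.kp_rate_params <- function(x, ...) {
  cat("<kp_rate_params>\n")
  cat(sprintf("  ki           = %g 1/s\n", x$ki))
  cat(sprintf("  2k2          = %g 1/(M*s)\n", x$two_k2))
  cat(sprintf("  [I]0         = %g M\n", x$initiator_c0))
  cat(sprintf("  temperature  = %g K\n", x$temperature))
  cat(sprintf("  Wi(0)        = %g M/s\n", initiation_rate(x, 0)))
  invisible(x)
}

#' Antioxidant specification
#'
#' One row per inhibitor.  `q` is the stoichiometric factor: the number of
#' peroxyl radicals scavenged per antioxidant molecule (2 for classical
#' two-radical scavengers such as ascorbate).  Rows can be combined with
#' [rbind()] / [dplyr::bind_rows()] to describe mixtures.
#'
#' @param name Label used for trajectory columns and reports.
#' @param c0 Initial concentration in the reaction vessel, M.
#' @param kinh Inhibition rate constant, 1/(M*s).
#' @param q Stoichiometric factor, radicals scavenged per molecule (> 0).
#' @param mediator_compatible Logical; `FALSE` marks compounds whose
#'   reaction with ferricyanide is too slow or confounded (e.g. thiadiazines
#'   that slowly rearrange to mercaptopyrazoles), for which the
#'   residual-concentration method is not applicable.
#'
#' @return A one-row tibble of class `kp_antioxidants`.
#' @examples
#' ao <- antioxidant("ascorbic", c0 = 1e-4, kinh = 3.95e3)
#' mix <- rbind(ao, antioxidant("tocopherol", c0 = 1e-4, kinh = 7.5e2))
#' @export
antioxidant <- function(name, c0, kinh, q = 2, mediator_compatible = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (c0 < 0) abort("`c0` must be non-negative.")
  if (kinh <= 0) abort("`kinh` must be strictly positive.")
  if (q <= 0) abort("`q` must be strictly positive.")
  out <- tibble(name = name, c0 = c0, kinh = kinh, q = q,
                mediator_compatible = isTRUE(mediator_compatible))
  class(out) <- c("kp_antioxidants", class(out))
  out
}

as_antioxidants <- function(x) {
  if (inherits(x, "kp_antioxidants")) return(x)
  if (is.data.frame(x)) {
    need <- c("name", "c0", "kinh")
    if (!all(need %in% names(x)))
      abort("antioxidant table needs columns name, c0, kinh.")
    if (is.null(x$q)) x$q <- 2
    if (is.null(x$mediator_compatible)) x$mediator_compatible <- TRUE
    out <- as_tibble(x)
    class(out) <- c("kp_antioxidants", class(out))
    return(out)
  }
  abort("cannot interpret `antioxidants`; use antioxidant() rows.")
}

# empty spec (uninhibited control)
no_antioxidant <- function() {
  out <- tibble(name = character(), c0 = numeric(), kinh = numeric(),
                q = numeric(), mediator_compatible = logical())
  class(out) <- c("kp_antioxidants", class(out))
  out
}
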