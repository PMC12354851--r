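#' Define an alpha-emitting isotope
#'
#' An isotope bundles the decay constant with the alpha-emission properties of
#' its full decay chain: the number of alpha particles emitted per primary
#' (parent) decay and their energies.
#'
#' @param name Character name, e.g. `"Ac-225"`.
#' @param half_life_s Half-life in seconds (> 0).
#' @param alphas_per_primary Integer number of alpha particles emitted per
#'   primary decay of the parent (>= 1).
#' @param alpha_energies_mev Numeric vector of alpha energies in MeV, one per
#'   chain alpha (`length == alphas_per_primary`).
#' @return An object of class `"isotope"` with fields `name`, `half_life_s`,
#'   `lambda` (decay constant, 1/s), `alphas_per_primary`,
#'   `alpha_energies_mev`.
#' @examples
#' iso <- isotope("demo", half_life_s = 3600, alphas_per_primary = 1,
#'                alpha_energies_mev = 6)
#' iso$lambda * iso$half_life_s  # log(2)
#' @export
isotope <- function(name, half_life_s, alphas_per_primary, alpha_energies_mev) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L || half_life_s <= 0)
    stop("'half_life_s' must be a positive scalar")
  alphas_per_primary <- as.integer(alphas_per_primary)
  if (alphas_per_primary < 1L) stop("'alphas_per_primary' must be >= 1")
  if (length(alpha_energies_mev) != alphas_per_primary)
    stop("'alpha_energies_mev' must have one energy per chain alpha")
  if (any(!is.finite(alpha_energies_mev)) || any(alpha_energies_mev <= 0))
    stop("alpha energies must be positive and finite")
  structure(list(
    name = name,
    half_life_s = half_life_s,
    lambda = log(2) / half_life_s,
    alphas_per_primary = alphas_per_primary,
    alpha_energies_mev = as.numeric(alpha_energies_mev)
  ), class = "isotope")
}

#' @export
print.isotope <- function(x, ...) {
  cat(sprintf("<isotope> %s: half-life %.4g d, %d alpha(s)/primary at %s MeV\n",
              x$name, x$half_life_s / 86400, x$alphas_per_primary,
              paste(format(x$alpha_energies_mev), collapse = ", ")))
  invisible(x)
}

#' Built-in isotopes
#'
#' `ac225()` returns Actinium-225 with a 9.920-day half-life and the four
#' dominant chain alpha lines (Ac-225, Fr-221, At-217, Po-213; the small
#' Bi-213 alpha branch is folded into the Po-213 line).
#' `single_alpha_isotope()` returns a generic one-alpha isotope, mainly
#' useful for analytically tractable tests.
#'
#' @param half_life_s Half-life in seconds.
#' @param energy_mev Alpha energy in MeV.
#' @return An [isotope()] object.
#' @export
ac225 <- function() {
  isotope("Ac-225",
          half_life_s = 9.920 * 86400,
          alphas_per_primary = 4L,
          alpha_energies_mev = c(5.830, 6.341, 7.067, 8.375))
}

#' @rdname ac225
#' @export
single_alpha_isotope <- function(half_life_s = 86400, energy_mev = 6.0) {
  isotope("generic-1alpha", half_life_s = half_life_s,
          alphas_per_primary = 1L, alpha_energies_mev = energy_mev)
}

as_isotope <- function(x) {
  if (inherits(x, "isotope")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (toupper(x) %in% c("AC-225", "AC225")) return(ac225())
    stop("unknown isotope name: ", x)
  }
  stop("'isotope' must be an isotope object or a known name")
}
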