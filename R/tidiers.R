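#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold report
#'
#' @param x A `shidr_thresholds` object.
#' @param ... Unused.
#' @return A tibble with one row per analytical quantity (`quantity`,
#'   `value`).
#' @method tidy shidr_thresholds
#' @export
tidy.shidr_thresholds <- function(x, ...) {
  keys <- c(
    "R1", "R2", "phi_star", "B", "S_star",
    "alpha_max", "alpha_min", "rho_min", "rho_max",
    "sigma_min", "sigma_max", "F_star", "P_floor"
  )
  tibble::tibble(
    quantity = keys,
    value = vapply(keys, function(k) as.numeric(x[[k]]), numeric(1),
      USE.NAMES = FALSE
    )
  )
}

#' Glance at a threshold report
#'
#' @param x A `shidr_thresholds` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities and the verdict
#'   each one supports.
#' @method glance shidr_thresholds
#' @export
glance.shidr_thresholds <- function(x, ...) {
  tibble::tibble(
    R1 = x$R1, R2 = x$R2, phi_star = x$phi_star,
    phi_star_status = x$phi_star_status,
    B = x$B, S_star = x$S_star, F_star = x$F_star, P_floor = x$P_floor,
    extinction_guaranteed = x$R1 < 1,
    permanence_guaranteed = x$R2 > 1
  )
}
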