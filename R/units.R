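# Standard gravity, m s^-2. Fixed: it is the constant that defines the
# gram-force, not a tunable model parameter.
.standard_gravity <- 9.80665

#' Convert between newtons and gram-force
#'
#' Monofilament ratings are quoted in gram-force (gf), the weight of one
#' gram under standard gravity (9.80665 m s^-2). Internally all forces are
#' carried in newtons; these helpers convert on entry and exit.
#'
#' @param force_n Force in newtons (vectorised).
#' @param force_gf Force in gram-force (vectorised).
#'
#' @return `newton_to_gramforce()` returns gram-force; `gramforce_to_newton()`
#'   returns newtons. The two are exact inverses.
#'
#' @examples
#' newton_to_gramforce(0.0980665)   # 10 gf by definition
#' gramforce_to_newton(10)          # 0.0980665 N
#' @export
newton_to_gramforce <- function(force_n) {
  stopifnot(is.numeric(force_n), all(is.finite(force_n)))
  force_n / .standard_gravity * 1000
}

#' @rdname newton_to_gramforce
#' @export
gramforce_to_newton <- function(force_gf) {
  stopifnot(is.numeric(force_gf), all(is.finite(force_gf)))
  force_gf * .standard_gravity / 1000
}
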