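#' Convert a metal concentration from ng/m3 to mg/m3
#'
#' Metal concentrations are reported and stored in ng/m3; all dose
#' arithmetic is carried out in mg-based units. This is the single place
#' in the package where that conversion (an exact factor of 1e-6) happens.
#'
#' @param x Numeric vector of concentrations in ng/m3.
#' @return Concentrations in mg/m3.
#' @export
#' @examples
#' ngm3_to_mgm3(117) # 1.17e-4 mg/m3
ngm3_to_mgm3 <- function(x) {
  stopifnot(is.numeric(x))
  x * 1e-6
}
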