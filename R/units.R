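#' Application-rate unit conversion
#'
#' Converts field application rates between kg a.i./ha and lb a.i./acre.
#' The residue-unit-dose and contact-unit-dose defaults of the tier-1 bee
#' exposure model are defined per lb a.i./acre, while use reports and field
#' studies commonly record kg/ha, so every exposure computation funnels
#' through this conversion.
#'
#' @param rate numeric vector of application rates, all >= 0.
#' @param from,to unit names, one of `"kg_per_ha"` or `"lb_per_acre"`.
#' @return numeric vector of rates expressed in `to` units.
#' @examples
#' convert_rate(1.12085, "kg_per_ha", "lb_per_acre") # ~1
#' @export
convert_rate <- function(rate, from = c("kg_per_ha", "lb_per_acre"),
                         to = c("lb_per_acre", "kg_per_ha")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("beescreen_unit_error: rates must be finite and >= 0")
  }
  if (from == to) return(rate)
  if (from == "kg_per_ha") rate * .lb_acre_per_kg_ha else rate / .lb_acre_per_kg_ha
}

# 1 kg/ha expressed in lb/acre (0.45359237 kg/lb, 0.40468564224 ha/acre)
.lb_acre_per_kg_ha <- 0.892179
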