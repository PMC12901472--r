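#' Health states of the disease-progression model
#'
#' The model tracks a cohort over five mutually exclusive health states:
#' mild cognitive impairment due to AD (`MCI`), mild, moderate and severe
#' dementia due to AD, and `DEATH`, the unique absorbing state. `MCI` and
#' `MILD` together constitute early AD, the population eligible for
#' anti-amyloid treatment.
#'
#' @return Character vector of the five state labels, in severity order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("MCI", "MILD", "MODERATE", "SEVERE", "DEATH")
}

#' @rdname health_states
#' @export
alive_states <- function() {
  c("MCI", "MILD", "MODERATE", "SEVERE")
}

#' @rdname health_states
#' @export
early_ad_states <- function() {
  c("MCI", "MILD")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
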