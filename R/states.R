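#' Reproductive state coding
#'
#' States are stored as character labels in memory and as small integer codes
#' in exported CSV files: 0 = subordinate, 1 = sneaker, 2 = guard, 3 = dead.
#'
#' @format Character vector of the three live states plus the absorbing death
#'   state, in code order.
#' @export
STATES <- c("subordinate", "sneaker", "guard", "dead")

LIVE_STATES <- STATES[1:3]

#' Convert between state labels and integer codes
#'
#' @param state character vector of state labels.
#' @param code integer vector of state codes (0-3).
#' @return `state_code()` returns integer codes; `state_label()` returns
#'   character labels.
#' @examples
#' state_code("guard")    # 2
#' state_label(0L)        # "subordinate"
#' @export
state_code <- function(state) {
  i <- match(state, STATES)
  if (anyNA(i)) stop("unknown state label: ", paste(setdiff(state, STATES), collapse = ", "))
  i - 1L
}

#' @rdname state_code
#' @export
state_label <- function(code) {
  if (any(code < 0 | code > 3)) stop("state codes must be in 0..3")
  STATES[code + 1L]
}
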