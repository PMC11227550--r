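#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# stop with a classed condition so tests can assert on error class
fm_abort <- function(message, class) {
  abort(message, class = c(class, "funmorph_error"))
}

# deterministic sign convention: the entry of largest absolute value
# (ties -> lowest index) is made positive; returns +1 or -1
sign_fix <- function(v) {
  i <- which.max(abs(v))
  s <- sign(v[i])
  if (s == 0) 1 else s
}

# apply sign convention to the columns of a matrix
sign_fix_cols <- function(m) {
  s <- apply(m, 2, sign_fix)
  sweep(m, 2, s, `*`)
}

# signs needed to fix columns (so companion matrices can be flipped consistently)
col_signs <- function(m) apply(m, 2, sign_fix)

# derive a child seed from a master seed; stays well below 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}
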