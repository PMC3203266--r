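# broom-style accessors for fitted objects.

#' Tidy a position-specific scoring matrix
#'
#' @param x A `coro_pssm`.
#' @param ... Unused.
#' @return A long tibble (`column`, `residue`, `score`).
#' @export
tidy.coro_pssm <- function(x, ...) {
  m <- unclass(x)
  tibble(
    column = rep(seq_len(ncol(m)), each = nrow(m)),
    residue = rep(rownames(m), ncol(m)),
    score = as.numeric(m)
  )
}

#' One-row summary of a PSSM
#'
#' @param x A `coro_pssm`.
#' @param ... Unused.
#' @return A tibble with the width, pseudocount, consensus and the maximum
#'   attainable (consensus) score.
#' @export
glance.coro_pssm <- function(x, ...) {
  m <- unclass(x)
  tibble(
    width = ncol(m),
    pseudocount = attr(x, "pseudocount"),
    consensus = pssm_consensus(x),
    max_score = sum(apply(m, 2, max))
  )
}

#' Tidy a sequence logo
#'
#' @param x A `coro_logo`.
#' @param ... Unused.
#' @return The underlying long tibble.
#' @export
tidy.coro_logo <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a sequence logo
#'
#' @param x A `coro_logo`.
#' @param ... Unused.
#' @return A tibble with the number of columns, mean and total information
#'   content (gap-only columns excluded).
#' @export
glance.coro_logo <- function(x, ...) {
  ic <- x |> distinct(.data$column, .data$ic) |> pull(.data$ic)
  tibble(
    n_columns = length(ic),
    mean_ic = mean(ic, na.rm = TRUE),
    total_ic = sum(ic, na.rm = TRUE),
    n_undefined = sum(is.na(ic))
  )
}
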