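#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join rename n
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap
NULL

# round half away from zero at `digits` decimals (the convention used by the
# printed report tables; base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fold-change formatted the way rate-comparison tables print it
#'
#' Ratio of two distances rounded half-away-from-zero to one decimal; ratios
#' of ten or more are printed as integers.
#'
#' @param numerator,denominator Non-negative distances.
#' @return Numeric fold change (`NA` if the denominator is zero or any input
#'   is `NA`).
#' @examples
#' fold_ratio(0.235, 0.054)  # 4.4
#' fold_ratio(0.307, 0.019)  # 16
#' @export
fold_ratio <- function(numerator, denominator) {
  r <- numerator / denominator
  out <- ifelse(!is.finite(r), NA_real_,
                ifelse(round_half_up(r, 1) >= 10,
                       round_half_up(r, 0), round_half_up(r, 1)))
  out
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
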