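#' Truncate a number for display
#'
#' Display values throughout the package are truncated (digits past the
#' requested place are dropped, not rounded): a growth rate of 0.90494
#' displays as 0.904 and a stage proportion of 6.72\% displays as 6\%.
#' Internal arithmetic always keeps full double precision; truncation is a
#' formatting convention only.
#'
#' A guard of 1e-9 (toward zero) absorbs binary floating-point
#' representation error so that a value stored as 74.999999999996 for an
#' intended 75 truncates to 75, not 74.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep (default 0).
#' @return `x` truncated to `digits` decimal places.
#' @examples
#' trunc_dec(0.90494, 3)   # 0.904
#' trunc_dec(6.72)         # 6
#' @export
trunc_dec <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(x * scale + sign(x) * 1e-9) / scale
}

# Fixed machine formatting: 12 significant digits, plain decimal/scientific
# as needed, locale-independent.
fmt_num <- function(x) trimws(formatC(x, digits = 12, format = "g"))
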