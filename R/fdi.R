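#' FDI numbering for the 32 permanent teeth
#'
#' Fixed bijection between classifier class indices 1..32 and two-digit FDI
#' codes: row-major over quadrants 1-4 (1 upper right, 2 upper left, 3 lower
#' left, 4 lower right) and positions 1-8 (central incisor to third molar).
#' Class 1 is FDI 11, class 32 is FDI 48.
#'
#' @return integer vector of the 32 FDI codes, in class-index order.
#' @export
fdi_codes <- function() {
  as.integer(outer(1:8, c(10L, 20L, 30L, 40L), "+")) # 11..18, 21..28, 31..38, 41..48
}

#' @rdname fdi_codes
#' @param class_index integer in 1..32.
#' @export
class_to_fdi <- function(class_index) {
  stopifnot(all(class_index >= 1L & class_index <= 32L))
  q <- (class_index - 1L) %/% 8L + 1L
  p <- (class_index - 1L) %% 8L + 1L
  as.integer(10L * q + p)
}

#' @rdname fdi_codes
#' @param fdi two-digit FDI code (11-48).
#' @export
fdi_to_class <- function(fdi) {
  q <- fdi %/% 10L
  p <- fdi %% 10L
  if (any(q < 1L | q > 4L | p < 1L | p > 8L)) stopf("invalid FDI code")
  as.integer((q - 1L) * 8L + p)
}
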