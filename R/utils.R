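#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- Rle runValue runLength queryHits subjectHits
#' @importFrom stats density rnorm runif rlnorm rbinom cor.test setNames
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentage rounding used throughout reporting: `round()` in base R rounds
#' half to even; figures in the field report half away from zero.
#' @param x numeric vector
#' @param digits integer
#' @return rounded numeric
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

msg_log <- function(...) message("[markstates] ", sprintf(...))

#' Timepoint vocabulary of the differentiation time course
#'
#' Default labels for the undifferentiated (D0), 2-day (D2) and 6-day (D6)
#' differentiated samples.
#' @export
TIMEPOINTS <- c("D0", "D2", "D6")
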