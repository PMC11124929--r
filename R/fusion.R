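#' Fuse the verdicts of the two sensor modules
#'
#' Each handheld device carries two NIR sensor modules measuring two
#' different spots of the sample; their individual PLS-DA verdicts are
#' combined into the single outcome shown on the RGB LED. Precedence is
#' red > yellow > green: the sample is flagged suspicious (red) if
#' either module flags it, otherwise uncertain (yellow) if either
#' module is uncertain, otherwise unsuspicious (green). The function is
#' symmetric in its arguments and idempotent.
#'
#' Verdicts are accepted in either vocabulary -- LED colors
#' (`green`/`yellow`/`red`) or classifier terms
#' (`unsuspicious`/`uncertain`/`suspicious`) -- and returned in the one
#' the first argument uses.
#'
#' @param v1,v2 module verdicts.
#' @return The fused device verdict (character scalar).
#' @examples
#' fuse_verdicts("green", "red")        # "red"
#' fuse_verdicts("unsuspicious", "uncertain")  # "uncertain"
#' @export
fuse_verdicts <- function(v1, v2) {
  color <- c(unsuspicious = "green", uncertain = "yellow",
             suspicious = "red", green = "green", yellow = "yellow",
             red = "red")
  if (!v1 %in% names(color) || !v2 %in% names(color)) {
    stop("unknown verdict")
  }
  rank <- c(green = 1, yellow = 2, red = 3)
  fused <- names(rank)[max(rank[color[[v1]]], rank[color[[v2]]])]
  if (v1 %in% c("green", "yellow", "red")) {
    fused
  } else {
    c(green = "unsuspicious", yellow = "uncertain", red = "suspicious")[[fused]]
  }
}
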