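#' Vertebral level utilities
#'
#' Vertebral levels are named `"T1"`..`"T12"`, `"L1"`..`"L5"` and ordered
#' cranio-caudally. `vertebral_levels()` expands an inclusive range, e.g.
#' `vertebral_levels("T12", "L4")`, the default eligibility window for
#' volumetric bone measures; areal (virtual DXA) measures use `"L1"`..`"L4"`.
#'
#' @param from,to Level names bounding the range (inclusive).
#' @return Character vector of level names in anatomical order.
#' @examples
#' vertebral_levels("T12", "L4")
#' @export
vertebral_levels <- function(from = "T1", to = "L5") {
  all <- c(paste0("T", 1:12), paste0("L", 1:5))
  i <- match(from, all)
  j <- match(to, all)
  if (is.na(i) || is.na(j) || i > j) {
    abort("invalid vertebral level range", class = "qct_data_error")
  }
  all[i:j]
}

level_rank <- function(levels) {
  match(levels, vertebral_levels("T1", "L5"))
}
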