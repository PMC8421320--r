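#' AHA 17-segment model and coronary territories
#'
#' The standard American Heart Association left-ventricular segmentation with
#' the conventional assignment of segments to coronary artery territories
#' (LAD, RCA, LCx). Weights default to equal (1/17); a volume-weighted
#' variant can be supplied wherever weights are accepted.
#'
#' @return A data.frame with columns `segment` (1:17), `territory` and
#'   `weight` (equal, summing to 1).
#' @export
aha_segments <- function() {
  territory <- character(17)
  territory[c(1, 2, 7, 8, 13, 14, 17)] <- "LAD"
  territory[c(3, 4, 9, 10, 15)] <- "RCA"
  territory[c(5, 6, 11, 12, 16)] <- "LCx"
  data.frame(segment = 1:17, territory = territory, weight = 1 / 17)
}

#' Coronary territory of an AHA segment
#'
#' @param segment_id Integer segment id(s) in 1:17.
#' @return Character vector of `"LAD"`, `"RCA"` or `"LCx"`.
#' @export
territory_of <- function(segment_id) {
  seg <- aha_segments()
  if (any(!(segment_id %in% seg$segment)))
    stop("unknown AHA segment id: must be in 1:17", call. = FALSE)
  seg$territory[match(segment_id, seg$segment)]
}
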