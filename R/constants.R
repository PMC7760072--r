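#' @keywords internal
"_PACKAGE"

#' Marker and ethogram vocabularies
#'
#' The three anatomical keypoints tracked on the horse and the four
#' behaviour classes of the ethogram. `markers()` returns
#' `c("nose", "withers", "tail")`; `ethogram_classes()` returns the four
#' behaviour states in their conventional coding order (1 = standing
#' observation, 2 = sleeping/rest, 3 = feeding, 4 = moving);
#' `visibility_classes()` returns the five annotation visibility levels.
#'
#' @return A character vector of permitted names.
#' @export
markers <- function() c("nose", "withers", "tail")

#' @rdname markers
#' @export
ethogram_classes <- function() {
  c("standing_observation", "rest", "feeding", "moving")
}

#' @rdname markers
#' @export
visibility_classes <- function() {
  c("visible", "occluded25", "occluded50", "occluded75", "not_visible")
}
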