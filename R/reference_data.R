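#' Reference stain-station validation counts
#'
#' Confusion counts recorded when the sorting prototype's two stain cameras
#' were validated on a physical cocoon set (stained is the positive class:
#' top view 287/785/67/85 and bottom view 294/808/51/77 for Tp/Tn/Fp/Fn).
#' Shipped with the package so the metric layer can be exercised against the
#' machine's operating figures: overall accuracy 87.6% with recall 0.77 on
#' the top view, 89.6% with 0.79 on the bottom view.
#'
#' @return data frame with columns `view`, `tp`, `tn`, `fp`, `fn`.
#' @export
stain_validation_counts <- function() {
  utils::read.csv(system.file("extdata", "stain_validation_counts.csv",
                              package = "cocoonsort"),
                  stringsAsFactors = FALSE)
}
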