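# Published confusion matrices (training/testing, binary and multiclass)
# for the original 97 processed training and 49 processed testing photos,
# in rows = predicted, columns = true orientation.

#' Published tier confusion matrices
#'
#' The reported confusion matrices: binary and multiclass, training and
#' testing, plus the combined multiclass matrix (element-wise sum of the
#' multiclass training and testing matrices).
#'
#' @param which One of `"binary_training"`, `"binary_testing"`,
#'   `"multiclass_training"`, `"multiclass_testing"`, `"combined"`.
#' @return A `tier_confusion`.
#' @export
published_confusion <- function(which = c("binary_training", "binary_testing",
                                          "multiclass_training",
                                          "multiclass_testing", "combined")) {
  which <- match.arg(which)
  switch(which,
    binary_training = as_tier_confusion(c(46, 9,
                                          1, 41), "binary"),
    binary_testing = as_tier_confusion(c(23, 1,
                                         2, 23), "binary"),
    multiclass_training = as_tier_confusion(c(22, 2, 0,
                                              8, 14, 1,
                                              0, 9, 41), "multiclass"),
    multiclass_testing = as_tier_confusion(c(9, 1, 0,
                                             2, 11, 1,
                                             0, 2, 23), "multiclass"),
    combined = as_tier_confusion(
      unclass(published_confusion("multiclass_training")) +
        unclass(published_confusion("multiclass_testing")), "multiclass")
  )
}
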