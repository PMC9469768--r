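# End-to-end orchestration: photo in, tier report out.
#
# The processing order is: gray-world balance (whole photo) -> fiducial
# detection -> perspective alignment -> black-rectangle detection -> strip
# crop -> white-reference balance (strip crop) -> pad localization ->
# inscribed-circle extraction -> concentration prediction -> tier binning.
# Content failures never raise; they are recorded with the failing stage.

#' Pipeline configuration
#'
#' Gathers every tunable of the processing chain. Defaults are validated on
#' construction.
#'
#' @param layout A [scene_layout()] defining the target geometry.
#' @param white_threshold Minimum-channel threshold for white-reference
#'   pixel selection.
#' @param wb_variant White-reference variant, `"gain"` or `"reciprocal"`.
#' @param blur_sigma Gaussian blur sigma for fiducial detection.
#' @param scheme Default binning scheme for reports.
#' @param min_pad_pixels Minimum pixels inside the pad circle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(layout = scene_layout(), white_threshold = 200,
                            wb_variant = "gain", blur_sigma = 1,
                            scheme = "multiclass", min_pad_pixels = 9) {
  stopifnot(white_threshold > 0, white_threshold < 255,
            wb_variant %in% c("gain", "reciprocal"),
            blur_sigma >= 0,
            scheme %in% c("binary", "multiclass"),
            min_pad_pixels >= 1)
  structure(list(layout = layout, white_threshold = white_threshold,
                 wb_variant = wb_variant, blur_sigma = blur_sigma,
                 scheme = scheme, min_pad_pixels = min_pad_pixels),
            class = "pipeline_config")
}

photo_result <- function(file, status, stage = NA_character_,
                         pads = NULL, concentration = NA_real_,
                         model_family = NA_character_) {
  free <- if (!is.null(pads)) pads[pads$pad == "free", ] else NULL
  total <- if (!is.null(pads)) pads[pads$pad == "total", ] else NULL
  val <- function(x, col) if (!is.null(x) && nrow(x)) x[[col]][1] else NA_real_
  tibble::tibble(
    file = file, status = status, stage = stage,
    free_r = val(free, "r"), free_g = val(free, "g"), free_b = val(free, "b"),
    total_r = val(total, "r"), total_g = val(total, "g"),
    total_b = val(total, "b"),
    concentration = concentration,
    tier_binary = if (is.na(concentration)) NA_character_ else
      as.character(bin_concentration(concentration, "binary")),
    tier_multiclass = if (is.na(concentration)) NA_character_ else
      as.character(bin_concentration(concentration, "multiclass")),
    model = model_family
  )
}

#' Process one photo end to end
#'
#' Runs the full chain and returns a one-row tibble. Content failures (no
#' fiducial, no rectangle, ...) yield `status = "failed"` with the failing
#' stage; only an unreadable file raises.
#'
#' @param path PNG file path, or an image array.
#' @param model A `chlorine_calibration` used for prediction, or `NULL` to
#'   extract colors only.
#' @param config A [pipeline_config()].
#' @return One-row tibble: file, status, stage, extracted free/total pad
#'   RGB, predicted concentration, binary and multiclass tiers, model
#'   family.
#' @export
process_photo <- function(path, model = NULL, config = pipeline_config()) {
  img <- if (is.character(path)) read_image(path) else path
  file <- if (is.character(path)) basename(path) else NA_character_
  fail <- function(f) photo_result(file, "failed", f$stage)

  img <- tryCatch(gray_world_balance(img), error = function(e) e)
  if (inherits(img, "error")) {
    return(photo_result(file, "failed", "fiducial"))
  }
  fid <- detect_fiducial(img, blur_sigma = config$blur_sigma)
  if (is_failure(fid)) return(fail(fid))
  aligned <- align_photo(img, fid, config$layout)
  rect <- detect_black_rectangle(aligned)
  if (is_failure(rect)) return(fail(rect))
  strip <- crop_strip(aligned, rect)
  if (is_failure(strip)) return(fail(strip))

  wb <- tryCatch({
    mask <- select_white_pixels(strip$image, config$white_threshold)
    ref <- white_reference(strip$image, mask)
    white_reference_balance(strip$image, ref, config$wb_variant)
  }, error = function(e) e)
  if (inherits(wb, "error")) {
    return(photo_result(file, "failed", "strip"))
  }

  pads <- locate_pads(strip, config$layout)
  if (is_failure(pads)) return(fail(pads))
  samples <- purrr::map(pads, function(p) {
    circ <- inscribe_circle(p)
    # circle center in strip-crop coordinates
    circ$center <- circ$center - c(strip$bbox["xmin"], strip$bbox["ymin"])
    extract_mean_rgb(wb, circ, config$min_pad_pixels, pad_id = p$id,
                     source = file)
  })
  bad <- purrr::detect(samples, is_failure)
  if (!is.null(bad)) return(fail(bad))
  samples <- dplyr::bind_rows(samples)

  conc <- NA_real_
  fam <- NA_character_
  if (!is.null(model)) {
    free <- samples[samples$pad == "free", ]
    conc <- predict_concentration(model, free)
    fam <- model$family
  }
  photo_result(file, "ok", NA_character_, samples, conc, fam)
}

#' Process a directory (or list) of photos
#'
#' @param paths Directory containing PNGs, or a character vector of files.
#' @param model Optional `chlorine_calibration`.
#' @param config A [pipeline_config()].
#' @return List with `results` (one row per photo) and `summary` (per-stage
#'   failure counts and percentages).
#' @export
process_batch <- function(paths, model = NULL, config = pipeline_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.png$", full.names = TRUE)
  }
  if (length(paths) == 0) stop("no images to process", call. = FALSE)
  results <- dplyr::bind_rows(lapply(paths, process_photo, model = model,
                                     config = config))
  n <- nrow(results)
  failed <- results[results$status == "failed", ]
  by_stage <- if (nrow(failed)) table(failed$stage) else table(character())
  summary <- tibble::tibble(
    n_photos = n,
    n_ok = sum(results$status == "ok"),
    n_failed = nrow(failed),
    failure_pct = 100 * nrow(failed) / n
  )
  stage_tbl <- tibble::tibble(stage = names(by_stage),
                              n = as.integer(by_stage),
                              pct = 100 * as.integer(by_stage) / n)
  list(results = results, summary = summary, by_stage = stage_tbl)
}

#' Train the toolchain on a rendered dataset
#'
#' Processes every photo in the manifest, joins the extracted free-pad
#' colors with the known concentrations, splits train/test stratified on
#' the concentration group, fits the chosen calibration family on the
#' training rows and evaluates both binnings on the held-out rows.
#'
#' @param manifest Manifest tibble from [make_dataset()] (or the path of a
#'   manifest CSV).
#' @param dir Directory holding the images.
#' @param family Calibration family.
#' @param train_fraction Training fraction (default 0.67).
#' @param seed Split seed.
#' @param config A [pipeline_config()].
#' @return List: `model`, `metrics` (binary and multiclass
#'   `tier_metrics` on the held-out set), `split` sizes, `calibration`
#'   (processed rows), `batch` (processing report).
#' @export
train_toolchain <- function(manifest, dir, family = "polynomial_sq",
                            train_fraction = 0.67, seed = 1L,
                            config = pipeline_config()) {
  if (is.character(manifest)) {
    manifest <- tibble::as_tibble(read.csv(manifest))
  }
  batch <- process_batch(file.path(dir, manifest$file), config = config)
  ok <- batch$results[batch$results$status == "ok", ]
  cal <- dplyr::inner_join(
    dplyr::transmute(ok, file = .data$file, r = .data$free_r,
                     g = .data$free_g, b = .data$free_b),
    dplyr::select(manifest, "file", "concentration", "group"),
    by = "file")
  sp <- stratified_split(cal, train_fraction, seed = seed)
  fitter <- switch(family, linear_sum = fit_linear_sum,
                   multiple_rg = fit_multiple_rg,
                   polynomial_sq = fit_polynomial_sq)
  mod <- fitter(sp$train)
  pred <- predict_concentration(mod, sp$test)
  mts <- lapply(c(binary = "binary", multiclass = "multiclass"),
                function(sc) {
    metrics(confusion(bin_concentration(sp$test$concentration, sc),
                      bin_concentration(pred, sc), sc))
  })
  list(model = mod, metrics = mts,
       split = c(train = nrow(sp$train), test = nrow(sp$test)),
       calibration = cal, batch = batch)
}

#' Evaluate a confusion matrix (or labeled predictions)
#'
#' @param x A `tier_confusion`, or a data frame with `true` and `predicted`
#'   tier columns.
#' @param scheme Required when `x` is a data frame.
#' @param bayes_cases Also compute the three sequence-case probabilities
#'   (multiclass matrices only).
#' @return List with `metrics` and optionally `cases` (tibble of Case
#'   labels, assumptions and probabilities).
#' @export
evaluate_confusion <- function(x, scheme = NULL, bayes_cases = FALSE) {
  cm <- if (inherits(x, "tier_confusion")) x
        else confusion(x$true, x$predicted, scheme)
  out <- list(metrics = metrics(cm))
  if (bayes_cases && attr(cm, "scheme") == "multiclass") {
    case_def <- list(
      list(label = "Case 1", present = c("le_0.2", "mid_0.2_0.5"),
           prior = "gt_0.5"),
      list(label = "Case 2", present = "le_0.2", prior = "gt_0.5"),
      list(label = "Case 3", present = "gt_0.5",
           prior = c("le_0.2", "mid_0.2_0.5"))
    )
    out$cases <- purrr::map_dfr(case_def, function(cd) {
      # for a two-sided prior set, condition on the first listed class
      sq <- sequence_case_probability(cm, cd$prior[1], n_prior = 2,
                                      present_predicted_set = cd$present)
      tibble::tibble(case = cd$label,
                     prior_class = cd$prior[1],
                     present_set = paste(cd$present, collapse = "|"),
                     assumption = "shared_true_class",
                     probability = sq$probability)
    })
  }
  out
}
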