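# Optional driver for a directory of real photographs (e.g. a downloaded
# field-image corpus): calibrate, crop, extract signatures in both
# pathways, and tabulate pairwise distinguishability. Requires external
# images; nothing in the package's tests depends on it.

#' Analyze a directory of labeled photographs
#'
#' End-to-end runner for users with their own image corpus: each image is
#' loaded, white-standard calibrated against `ref`, cropped (per-image
#' boxes from `crops`, if given), downscaled, and encoded as visual
#' signatures; pairwise distinguishability is then computed for the
#' requested mode. Labels come from a CSV with columns `filename` and
#' `class`; crop boxes from an optional CSV with columns `filename`,
#' `row0`, `col0`, `row1`, `col1` (0-based, half-open).
#'
#' @param image_dir Directory containing the images.
#' @param labels_csv Path to the labels CSV.
#' @param ref A [ref_region()] covering the white standard (same frame
#'   position in every image), or `NULL` to skip calibration.
#' @param crops_csv Optional path to the per-image crop-box CSV.
#' @param mode `"color"` or `"grayscale"`.
#' @param n_permutations,seed,... Passed to
#'   [pairwise_distinguishability()] and [build_signature_matrix()].
#' @return A list: `table` (the pairwise results data.frame),
#'   `signatures`, `labels`.
#' @export
analyze_image_corpus <- function(image_dir, labels_csv, ref = NULL,
                                 crops_csv = NULL,
                                 mode = c("color", "grayscale"),
                                 n_permutations = 999L, seed = 1L, ...) {
  mode <- match.arg(mode)
  if (!dir.exists(image_dir))
    stop("image directory not found: ", image_dir, call. = FALSE)
  if (!file.exists(labels_csv))
    stop("labels CSV not found: ", labels_csv, call. = FALSE)
  lab <- utils::read.csv(labels_csv)
  if (!all(c("filename", "class") %in% names(lab)))
    stop_validation("labels CSV needs columns filename, class")
  crops <- NULL
  if (!is.null(crops_csv)) {
    crops <- utils::read.csv(crops_csv)
    if (!all(c("filename", "row0", "col0", "row1", "col1") %in% names(crops)))
      stop_validation("crops CSV needs columns filename, row0, col0, row1, col1")
  }
  images <- lapply(seq_len(nrow(lab)), function(i) {
    path <- file.path(image_dir, lab$filename[i])
    img <- load_image(path)
    cal <- if (is.null(ref)) as_calibrated_image(img$pixels)
           else calibrate_white(img, ref)
    if (!is.null(crops)) {
      cr <- crops[crops$filename == lab$filename[i], ]
      if (nrow(cr) == 1L)
        cal <- crop_body(cal, crop_box(cr$row0, cr$col0, cr$row1, cr$col1))
    }
    cal
  })
  run <- build_signature_matrix(images, mode = mode, seed = seed,
                                ids = lab$filename, ...)
  ds <- signature_dataset(run$signatures, lab$class, ids = lab$filename,
                          mode = mode)
  list(table = pairwise_distinguishability(ds, n_permutations = n_permutations,
                                           seed = seed),
       signatures = run$signatures, labels = lab)
}
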