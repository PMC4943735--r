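# Run configuration and template-set persistence.

#' Load a flat YAML configuration file
#'
#' Reads a flat key-value YAML file of pipeline parameters (bank,
#' opponent, template and similarity settings) and merges it over the
#' package defaults, returning an argument list suitable for
#' `do.call(build_signature_matrix, c(list(images = ...), cfg))`.
#' Unknown keys are rejected, so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of [build_signature_matrix()] arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("mode", "n_templates", "size_classes", "center_sigma",
               "surround_sigma", "max_side", "seed", "n_scales",
               "n_orientations", "aspect_ratio", "pool_sizes")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop_validation("unknown config key(s): ", paste(bad, collapse = ", "),
                    " (allowed: ", paste(allowed, collapse = ", "), ")")
  bank_keys <- intersect(names(cfg), c("n_scales", "n_orientations",
                                       "aspect_ratio", "pool_sizes"))
  out <- cfg[setdiff(names(cfg), bank_keys)]
  if (length(bank_keys)) out$bank <- do.call(gabor_bank, cfg[bank_keys])
  out
}

#' Save and load template dictionaries
#'
#' A template set is written as an RDS archive next to a human-readable
#' JSON manifest (`<path>.manifest.json`) recording mode, seed, counts
#' and size classes, so dictionaries can be reused across sessions and
#' audited without deserializing.
#'
#' @param templates A [sample_templates()] object.
#' @param path Archive path (".rds").
#' @return `save_template_set` returns `path` invisibly;
#'   `load_template_set` returns the `template_set`.
#' @export
save_template_set <- function(templates, path) {
  if (!inherits(templates, "template_set"))
    stop_validation("templates must be a template_set")
  saveRDS(templates, path)
  write_run_log(list(mode = templates$mode, seed = templates$seed,
                     n_templates = templates$n_templates,
                     size_classes = templates$size_classes,
                     channels = templates$channels),
                paste0(path, ".manifest.json"))
  invisible(path)
}

#' @rdname save_template_set
#' @export
load_template_set <- function(path) {
  if (!file.exists(path)) stop("template archive not found: ", path, call. = FALSE)
  ts <- readRDS(path)
  if (!inherits(ts, "template_set"))
    stop_validation("file does not contain a template_set")
  ts
}
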