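#' Default pipeline configuration
#'
#' One nested list holding every stage's parameters: colour space white
#' point, segmentation, exclusion thresholds, checker layout and reference
#' values, TDCH grid and V1-V7 mapping, statistics routing and classifier
#' settings. Serialisable to/from YAML via [write_config()] /
#' [read_config()].
#'
#' @param seed global seed; per-stage seeds are derived from it (see
#'   [stage_seed()]).
#' @return a `tdch_config` nested list.
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    schema_version = 1L,
    seed = as.integer(seed),
    colorspace = list(white_point = "D65"),
    segmentation = segmentation_params(),
    exclusion = list(dark_threshold = 30, bright_threshold = 85,
                     apply_to = "corrected"),
    correction = list(mode = "per_coordinate",
                      reference = as.data.frame(checker_reference())),
    tdch = list(L_lower = c(30, 35, 40, 45), L_width = 5,
                a_lower = c(6, 12, 18, 24), a_width = 6,
                mapping = as.list(default_variable_mapping()),
                denominator = "post_exclusion"),
    stats = list(route_by_normality = TRUE, alpha = 0.05, p_adjust = "none",
                 n_sim_lilliefors = 10000),
    classify = list(folds = 10, k = 5, kernel = "radial", cost = 1)
  )
  structure(cfg, class = c("tdch_config", "list"))
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic offset from a character hash of the stage name, so each
#' stage is independently reproducible from the one global seed.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()]: a validated `tdch_config`;
#'   [write_config()]: `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config a `tdch_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Field-level checks with named error messages; returns the config.
#'
#' @param config a `tdch_config` list.
#' @return the validated config, invisibly classed.
#' @export
validate_config <- function(config) {
  ex <- config$exclusion
  if (!(ex$dark_threshold >= 0 && ex$dark_threshold < ex$bright_threshold &&
        ex$bright_threshold <= 100))
    stop("config$exclusion: need 0 <= dark_threshold < bright_threshold <= 100",
         call. = FALSE)
  if (!ex$apply_to %in% c("corrected", "raw"))
    stop("config$exclusion$apply_to must be 'corrected' or 'raw'", call. = FALSE)
  g <- config$tdch
  grid <- tdch_grid(g$L_lower, g$L_width, g$a_lower, g$a_width)
  validate_variable_mapping(unlist(g$mapping), grid)
  if (!g$denominator %in% c("post_exclusion", "pre_exclusion"))
    stop("config$tdch$denominator must be 'post_exclusion' or 'pre_exclusion'",
         call. = FALSE)
  if (!config$correction$mode %in% c("per_coordinate", "cross_channel"))
    stop("config$correction$mode must be 'per_coordinate' or 'cross_channel'",
         call. = FALSE)
  if (config$classify$folds < 2)
    stop("config$classify$folds must be >= 2", call. = FALSE)
  structure(config, class = c("tdch_config", "list"))
}

#' Analyse one tongue image through the full pipeline
#'
#' Convert to Lab, segment (or take a supplied mask), fit and apply the
#' checker correction (when checker regions are supplied), exclude dark and
#' specular pixels on the corrected `L*`, histogram, and extract V1-V7 and
#' VR.
#'
#' @param image an [rgb_raster] or image file path.
#' @param config a `tdch_config`.
#' @param mask optional manual [tongue_mask] (skips automatic segmentation).
#' @param checker_regions optional patch-rectangle data frame for
#'   [sample_checker()]; when `NULL` no colour correction is applied.
#' @param center optional segmentation centre `(row, col)`.
#' @return a list: `variables` (one-row tibble V1..V7, VR), `histogram`
#'   (`tdch_result`), `exclusion_report`, `correction` (model or `NULL`),
#'   `mask` (the valid-pixel [tongue_mask]).
#' @export
analyze_image <- function(image, config = default_config(), mask = NULL,
                          checker_regions = NULL, center = NULL) {
  config <- validate_config(config)
  if (is.character(image)) image <- read_rgb_image(image)
  lab <- srgb_to_lab(image)

  if (is.null(mask)) {
    # the bright checker would bias the bright-region initialisation, so
    # segmentation sees the image with the checker area flattened to the
    # background level; correction still samples the original Lab values
    lab_seg <- lab
    if (!is.null(checker_regions)) {
      arr <- unclass(lab)
      bg_L <- stats::quantile(arr[, , 1], 0.05)
      for (i in seq_len(nrow(checker_regions))) {
        r <- checker_regions[i, ]
        arr[r$row0:r$row1, r$col0:r$col1, 1] <- bg_L
        arr[r$row0:r$row1, r$col0:r$col1, 2] <- 0
        arr[r$row0:r$row1, r$col0:r$col1, 3] <- 0
      }
      lab_seg <- lab_raster(arr)
    }
    mask <- segment_tongue(lab_seg, center = center,
                           params = config$segmentation)
  }

  model <- NULL
  lab_corr <- lab
  if (!is.null(checker_regions)) {
    reference <- tibble::as_tibble(config$correction$reference)
    cs <- sample_checker(lab, checker_regions, reference = reference)
    model <- fit_correction(cs, mode = config$correction$mode)
    lab_corr <- apply_correction(lab, model)
  }

  ex_params <- exclusion_params(config$exclusion$dark_threshold,
                                config$exclusion$bright_threshold)
  lab_for_exclusion <-
    if (config$exclusion$apply_to == "corrected") lab_corr else lab
  valid <- valid_pixel_mask(lab_for_exclusion, mask, ex_params)

  grid <- tdch_grid(config$tdch$L_lower, config$tdch$L_width,
                    config$tdch$a_lower, config$tdch$a_width)
  hist <- compute_histogram(lab_corr, valid, grid)
  if (config$tdch$denominator == "pre_exclusion") {
    n_pre <- sum(unclass(mask))
    hist$proportion <- hist$count / n_pre
    attr(hist, "denominator") <- n_pre
  }
  vars <- extract_variables(hist, unlist(config$tdch$mapping))

  list(variables = vars, histogram = hist,
       exclusion_report = attr(valid, "exclusion_report"),
       correction = model, mask = valid)
}

#' Analyse a batch of images into a cohort table
#'
#' Applies [analyze_image()] to each input; unreadable or failing images are
#' skipped with a logged message and the pipeline continues.
#'
#' @param images character vector of file paths, or a list of
#'   [rgb_raster] objects.
#' @param config a `tdch_config`.
#' @param groups optional group label per image.
#' @param subject_ids optional subject id per image (defaults to the file
#'   name or list index).
#' @param ... passed to [analyze_image()] (e.g. `checker_regions`, `center`).
#' @return a tibble with one row per successfully analysed image
#'   (`subject_id`, `visit`, `group`, V1..V7, VR); skipped images are
#'   recorded in attribute `skipped`.
#' @export
run_analyze <- function(images, config = default_config(), groups = NULL,
                        subject_ids = NULL, ...) {
  config <- validate_config(config)
  n <- length(images)
  if (is.null(subject_ids)) {
    subject_ids <- if (is.character(images))
      tools::file_path_sans_ext(basename(images)) else sprintf("img%03d", seq_len(n))
  }
  if (is.null(groups)) groups <- rep(NA_character_, n)
  skipped <- character()
  rows <- purrr::map(seq_len(n), function(i) {
    res <- tryCatch(
      analyze_image(if (is.character(images)) images[[i]] else images[[i]],
                    config = config, ...),
      error = function(e) {
        message("skipping ", subject_ids[i], ": ", conditionMessage(e))
        skipped <<- c(skipped, subject_ids[i])
        NULL
      })
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(subject_id = subject_ids[i], visit = "first",
                     group = groups[i]),
      res$variables)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Run the statistical battery on a cohort table
#'
#' @param cohort cohort tibble (or CSV path) with `group` and V1..V7.
#' @param config a `tdch_config`.
#' @return a `group_comparison` (see [group_compare()]).
#' @export
run_stats <- function(cohort, config = default_config()) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  st <- config$stats
  group_compare(cohort, route_by_normality = st$route_by_normality,
                alpha = st$alpha, p_adjust = st$p_adjust,
                n_sim_lilliefors = st$n_sim_lilliefors)
}

#' Generate phantom images and/or a synthetic cohort to disk
#'
#' @param out_dir output directory (created if needed).
#' @param n_images number of phantom images to write as PNG (with PNG
#'   ground-truth masks and a JSON truth file each).
#' @param cohort logical: also write `cohort.csv` from [generate_cohort()].
#' @param seed global seed.
#' @return invisible list of written paths.
#' @export
run_simulate <- function(out_dir, n_images = 0, cohort = TRUE, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (n_images > 0) {
    for (i in seq_len(n_images)) {
      ph <- generate_tongue_image(
        tongue_phantom_spec(seed = stage_seed(seed, "simulate") + i))
      base <- file.path(out_dir, sprintf("phantom_%03d", i))
      write_rgb_image(ph$image, paste0(base, ".png"))
      write_mask(ph$tongue, paste0(base, "_tongue.png"))
      write_mask(tongue_mask(ph$excluded, "manual"), paste0(base, "_excluded.png"))
      jsonlite::write_json(list(proportions = as.list(ph$proportions),
                                seed = ph$spec$seed),
                           paste0(base, "_truth.json"), auto_unbox = TRUE)
      paths[[length(paths) + 1]] <- paste0(base, ".png")
    }
  }
  if (cohort) {
    co <- generate_cohort(cohort_spec(seed = stage_seed(seed, "cohort")))
    p <- file.path(out_dir, "cohort.csv")
    utils::write.csv(co, p, row.names = FALSE)
    paths$cohort <- p
  }
  invisible(paths)
}
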