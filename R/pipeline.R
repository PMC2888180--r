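#' Pipeline configuration
#'
#' Collects every tunable parameter of the simulate / extract / measure /
#' compare chain, keyed by module. Unknown keys are rejected; every value is
#' validated against its documented range.
#'
#' @param synthetic Named list of overrides for [synthetic_image_spec()].
#' @param extraction Named list: `gaussian_sigma` (px), `low_threshold`,
#'   `high_threshold` (absolute, or `NULL` for quantile defaults),
#'   `threshold_quantiles`, `closing_radius` (px), `prune_spurs_shorter_than`
#'   (px), `min_segment_length` (px), `mode` (`"canny"` or `"otsu"`).
#' @param morphometry Named list: `estimator`, `bending_method`,
#'   `max_arc_fraction`, `bin_width` (px), `tangent_window` (px).
#' @param stats Named list: `alpha`, `pairwise`.
#' @param seed Integer global seed; per-stage seeds are derived from it with
#'   [derive_seed()].
#' @param pixel_scale Optional nm per pixel, applied to measured lengths.
#' @return An object of class `pipeline_config` with all defaults
#'   materialized.
#' @export
pipeline_config <- function(synthetic = list(), extraction = list(),
                            morphometry = list(), stats = list(),
                            seed = 1L, pixel_scale = NULL) {
  merge_section <- function(defaults, overrides, section) {
    if (length(overrides) == 0L) return(defaults)
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop_invalid("unknown %s config key(s): %s", section,
                   paste(bad, collapse = ", "))
    }
    utils::modifyList(defaults, overrides)
  }
  synth_defaults <- formals(synthetic_image_spec)
  synth_defaults <- lapply(synth_defaults[setdiff(names(synth_defaults), "seed")],
                           eval)
  extraction_defaults <- list(gaussian_sigma = 1.0,
                              low_threshold = NULL,
                              high_threshold = NULL,
                              threshold_quantiles = c(0.70, 0.90),
                              closing_radius = 2,
                              prune_spurs_shorter_than = 5,
                              min_segment_length = 10,
                              mode = "canny")
  ## tangent_correlation is the default on traced pixel chains: its chord
  ## window suppresses the king-move lattice inflation of arc length that
  ## biases the end-to-end fit low on extracted (as opposed to continuous)
  ## chains
  morph_defaults <- list(estimator = "tangent_correlation",
                         bending_method = "ratio_of_means",
                         max_arc_fraction = 0.5,
                         bin_width = 2,
                         tangent_window = 5)
  stats_defaults <- list(alpha = 0.05, pairwise = "welch_t")

  cfg <- list(
    synthetic = merge_section(synth_defaults, synthetic, "synthetic"),
    extraction = merge_section(extraction_defaults, extraction, "extraction"),
    morphometry = merge_section(morph_defaults, morphometry, "morphometry"),
    stats = merge_section(stats_defaults, stats, "stats"),
    seed = as.integer(seed),
    pixel_scale = pixel_scale
  )
  ## validate ranges by constructing the underlying objects / checking enums
  do.call(synthetic_image_spec, cfg$synthetic)
  with(cfg$extraction, {
    assert_positive(gaussian_sigma, "gaussian_sigma")
    assert_number(closing_radius, "closing_radius", lower = 0)
    assert_number(prune_spurs_shorter_than, "prune_spurs_shorter_than", lower = 0)
    assert_number(min_segment_length, "min_segment_length", lower = 0)
    if (!mode %in% c("canny", "otsu")) stop_invalid("extraction mode must be 'canny' or 'otsu'")
  })
  with(cfg$morphometry, {
    assert_fraction(max_arc_fraction, "max_arc_fraction")
    assert_positive(bin_width, "bin_width")
    assert_positive(tangent_window, "tangent_window")
    if (!estimator %in% c("end_to_end_fit", "tangent_correlation")) {
      stop_invalid("estimator must be 'end_to_end_fit' or 'tangent_correlation'")
    }
    if (!bending_method %in% c("ratio_of_means", "mean_of_ratios")) {
      stop_invalid("bending_method must be 'ratio_of_means' or 'mean_of_ratios'")
    }
  })
  assert_fraction(cfg$stats$alpha, "alpha")
  if (!cfg$stats$pairwise %in% c("welch_t", "mann_whitney")) {
    stop_invalid("stats pairwise must be 'welch_t' or 'mann_whitney'")
  }
  if (!is.null(pixel_scale)) assert_positive(pixel_scale, "pixel_scale")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value text file
#'
#' One `section.key = value` assignment per line; `#` starts a comment.
#' Values are parsed as numbers where possible, `true`/`false` as logicals,
#' comma-separated values as vectors, and `null` as `NULL`. Unknown keys are
#' rejected by [pipeline_config()].
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  top <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop_invalid("cannot parse config line: '%s'", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    parse1 <- function(v) {
      if (tolower(v) %in% c("null", "none")) return(NULL)
      if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    parsed <- if (length(parts) > 1L) {
      unlist(lapply(parts, parse1))
    } else parse1(val)
    dotted <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(dotted) == 2L) {
      sections[[dotted[1L]]][[dotted[2L]]] <- parsed
    } else if (length(dotted) == 1L) {
      top[[key]] <- parsed
    } else {
      stop_invalid("config keys must be 'key' or 'section.key': '%s'", key)
    }
  }
  args <- c(sections[intersect(names(sections),
                               c("synthetic", "extraction", "morphometry",
                                 "stats"))],
            top[intersect(names(top), c("seed", "pixel_scale"))])
  extra <- c(setdiff(names(sections),
                     c("synthetic", "extraction", "morphometry", "stats")),
             setdiff(names(top), c("seed", "pixel_scale")))
  if (length(extra)) {
    stop_invalid("unknown config section/key(s): %s", paste(extra, collapse = ", "))
  }
  do.call(pipeline_config, args)
}

#' Extract segments from one grayscale image
#'
#' Runs the extraction chain on a single image: Canny edge detection (or Otsu
#' thresholding), morphological closing, thinning to a skeleton, graph
#' decomposition, spur pruning and segment emission.
#'
#' @param image A [gray_image].
#' @param config A [pipeline_config()] (its `extraction` section is used).
#' @return A list with `edges`, `skeleton` ([binary_image]s), `graph`
#'   (`skeleton_graph`) and `segments` (list of [segment]).
#' @export
extract_image <- function(image, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ex <- config$extraction
  if (ex$mode == "canny") {
    edges <- detect_edges(image, gaussian_sigma = ex$gaussian_sigma,
                          low_threshold = ex$low_threshold,
                          high_threshold = ex$high_threshold,
                          threshold_quantiles = ex$threshold_quantiles)
    skeleton <- close_and_skeletonize(edges, closing_radius = ex$closing_radius)
  } else {
    edges <- threshold_fibrils(image, gaussian_sigma = ex$gaussian_sigma)
    skeleton <- skeletonize_mask(edges)
  }
  graph <- build_skeleton_graph(skeleton)
  segments <- extract_segments(graph,
                               min_segment_length = ex$min_segment_length,
                               prune_spurs_shorter_than = ex$prune_spurs_shorter_than)
  list(edges = edges, skeleton = skeleton, graph = graph, segments = segments)
}

## per-image summary row for the condition table
image_summary_row <- function(condition, image_id, segments, config) {
  mo <- config$morphometry
  if (length(segments) == 0L) {
    return(data.frame(condition = condition, image_id = image_id,
                      n_segments = 0L, bending_ratio = NA_real_,
                      persistence_length = NA_real_,
                      median_segment_length = NA_real_,
                      stringsAsFactors = FALSE))
  }
  sm <- summarize_condition(segments, pixel_scale = config$pixel_scale,
                            estimator = mo$estimator,
                            bending_method = mo$bending_method,
                            max_arc_fraction = mo$max_arc_fraction,
                            bin_width = mo$bin_width,
                            tangent_window = mo$tangent_window)
  data.frame(condition = condition, image_id = image_id,
             n_segments = sm$n_segments,
             bending_ratio = sm$bending_ratio,
             persistence_length = if (sm$estimable) sm$persistence_length else NA_real_,
             median_segment_length = sm$median_segment_length,
             stringsAsFactors = FALSE)
}

compare_summaries <- function(summaries, config) {
  conds <- unique(summaries$condition)
  if (length(conds) < 2L) return(NULL)
  out <- list()
  for (metric in c("bending_ratio", "persistence_length")) {
    vals <- lapply(conds, function(cd) {
      v <- summaries[[metric]][summaries$condition == cd]
      v[is.finite(v)]
    })
    names(vals) <- conds
    ok <- all(lengths(vals) >= 2L)
    out[[metric]] <- if (!ok) {
      NULL
    } else if (length(conds) == 2L) {
      mann_whitney_test(vals[[1L]], vals[[2L]], alpha = config$stats$alpha,
                        labels = conds)
    } else {
      one_way_anova_bonferroni(vals, alpha = config$stats$alpha,
                               pairwise = config$stats$pairwise)
    }
  }
  out
}

#' Run the full morphometry pipeline
#'
#' `simulate_and_measure` generates one synthetic dataset per condition
#' (conditions override the base synthetic spec), extracts and measures every
#' image, and compares conditions (Mann-Whitney for two conditions, one-way
#' ANOVA with Bonferroni post hoc for more). `measure_real` runs extraction
#' and measurement on image files from disk. Per-image summaries use the
#' image as the statistical unit.
#'
#' A single global seed drives everything through stage-salted derived seeds
#' ([derive_seed()]), so runs are fully deterministic. When `out_dir` is
#' given, all artifacts (images, ground-truth paths, segments, summaries,
#' comparisons, resolved config) are written there together with a manifest
#' listing every file and its MD5 content hash.
#'
#' @param config A [pipeline_config()].
#' @param mode `"simulate_and_measure"` or `"measure_real"`.
#' @param conditions For `simulate_and_measure`: named list of synthetic-spec
#'   override lists (default one condition named `"baseline"` with no
#'   overrides).
#' @param n_images Images per condition (`simulate_and_measure`).
#' @param images For `measure_real`: named character vector/list of image file
#'   paths, or a named list of path vectors (one element per condition).
#' @param out_dir Optional output directory; created if missing.
#' @return A list of class `pipeline_result`: `summaries` (per-image
#'   data.frame), `condition_results` (pooled [summarize_condition()] per
#'   condition), `comparisons`, `segments` (per condition, per image),
#'   `manifest` (data.frame of written files, or `NULL`), `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("simulate_and_measure", "measure_real"),
                         conditions = list(baseline = list()),
                         n_images = 1L,
                         images = NULL,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(names(conditions)) && length(conditions)) {
    stop_invalid("`conditions` must be a named list")
  }

  summaries <- list(); condition_results <- list(); all_segments <- list()
  datasets <- list()

  if (mode == "simulate_and_measure") {
    for (cd in names(conditions)) {
      spec <- do.call(synthetic_image_spec,
                      utils::modifyList(config$synthetic, conditions[[cd]]))
      seed_cd <- derive_seed(config$seed, paste0("simulate/", cd))
      ds <- generate_dataset(spec, n_images = n_images, seed = seed_cd)
      datasets[[cd]] <- ds
      segs_cd <- list()
      for (i in seq_along(ds)) {
        ext <- extract_image(ds[[i]]$image, config)
        segs_cd[[i]] <- ext$segments
        summaries[[length(summaries) + 1L]] <-
          image_summary_row(cd, i, ext$segments, config)
      }
      all_segments[[cd]] <- segs_cd
      pooled <- unlist(segs_cd, recursive = FALSE)
      condition_results[[cd]] <- if (length(pooled)) {
        mo <- config$morphometry
        summarize_condition(pooled, pixel_scale = config$pixel_scale,
                            estimator = mo$estimator,
                            bending_method = mo$bending_method,
                            max_arc_fraction = mo$max_arc_fraction,
                            bin_width = mo$bin_width,
                            tangent_window = mo$tangent_window)
      } else NULL
    }
  } else {
    if (is.null(images)) stop_invalid("`measure_real` requires `images`")
    if (!is.list(images)) images <- list(samples = images)
    for (cd in names(images)) {
      segs_cd <- list()
      for (i in seq_along(images[[cd]])) {
        img <- read_gray_image(images[[cd]][[i]],
                               pixel_scale = config$pixel_scale)
        ext <- tryCatch(extract_image(img, config), error = function(e) {
          stop_invalid("stage extract failed on image '%s': %s",
                       images[[cd]][[i]], conditionMessage(e))
        })
        segs_cd[[i]] <- ext$segments
        summaries[[length(summaries) + 1L]] <-
          image_summary_row(cd, i, ext$segments, config)
      }
      all_segments[[cd]] <- segs_cd
      pooled <- unlist(segs_cd, recursive = FALSE)
      condition_results[[cd]] <- if (length(pooled)) {
        mo <- config$morphometry
        summarize_condition(pooled, pixel_scale = config$pixel_scale,
                            estimator = mo$estimator,
                            bending_method = mo$bending_method,
                            max_arc_fraction = mo$max_arc_fraction,
                            bin_width = mo$bin_width,
                            tangent_window = mo$tangent_window)
      } else NULL
    }
  }

  summaries <- do.call(rbind, summaries)
  comparisons <- compare_summaries(summaries, config)

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_pipeline_artifacts(out_dir, config, mode, datasets,
                                         all_segments, summaries,
                                         condition_results, comparisons)
  }
  structure(list(summaries = summaries,
                 condition_results = condition_results,
                 comparisons = comparisons,
                 segments = all_segments,
                 manifest = manifest,
                 config = config,
                 seed = config$seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d condition(s), %d image summaries\n",
              length(x$condition_results), nrow(x$summaries)))
  for (cd in names(x$condition_results)) {
    r <- x$condition_results[[cd]]
    if (is.null(r)) next
    cat(sprintf("  %s: %d segments, bending ratio %.4f, Lp %s px\n",
                cd, r$n_segments, r$bending_ratio,
                if (is.finite(r$persistence_length))
                  sprintf("%.1f", r$persistence_length) else "non-estimable"))
  }
  if (!is.null(x$comparisons)) {
    for (metric in names(x$comparisons)) {
      cmp <- x$comparisons[[metric]]
      if (is.null(cmp)) next
      cat(sprintf("  %s: %s p = %.4g\n", metric, cmp$test_name, cmp$p_value))
    }
  }
  invisible(x)
}
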