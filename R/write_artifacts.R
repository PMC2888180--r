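## formatting used for every CSV the package writes: 9 significant digits
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

write_csv_9sig <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-segment metrics and a condition summary
#'
#' Writes one CSV of per-segment metrics (columns `segment_id`, `n_points`,
#' `contour_length_px`, `end_to_end_px`; floating point with 9 significant
#' digits) and one JSON file with the [summarize_condition()] fields. An empty
#' segment list yields a header-only CSV and a summary flagged non-estimable.
#'
#' @param segments List of [segment] objects (possibly empty).
#' @param result A `morphometry_result` from [summarize_condition()], or
#'   `NULL` for an empty segment list.
#' @param csv_path,json_path Output file paths.
#' @return Invisibly, a character vector of the written paths.
#' @export
write_segment_table <- function(segments, result, csv_path, json_path) {
  tab <- segments_table(segments)
  write_csv_9sig(tab, csv_path)
  summary <- if (is.null(result)) {
    list(n_segments = 0L, estimable = FALSE)
  } else {
    r <- unclass(result)
    r$persistence_length <- if (is.finite(r$persistence_length)) {
      r$persistence_length
    } else NULL  # JSON has no Inf; absence plus estimable=FALSE encodes it
    r[!vapply(r, is.null, logical(1))]
  }
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}

## ground-truth paths of one dataset as a flat data.frame
paths_table <- function(dataset) {
  rows <- list()
  for (i in seq_along(dataset)) {
    paths <- dataset[[i]]$paths
    for (j in seq_along(paths)) {
      p <- paths[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = i, path_id = j,
        parent_id = if (is.na(p$parent_index)) NA_integer_ else p$parent_index,
        point_index = seq_len(nrow(p$points)) - 1L,
        row = p$points[, 1L], col = p$points[, 2L])
    }
  }
  do.call(rbind, rows)
}

## segment chains of one condition as a flat data.frame
segment_points_table <- function(segs_by_image) {
  rows <- list()
  sid <- 0L
  for (i in seq_along(segs_by_image)) {
    for (s in segs_by_image[[i]]) {
      sid <- sid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = i, segment_id = sid,
        point_index = seq_len(nrow(s$chain)) - 1L,
        row = s$chain[, 1L], col = s$chain[, 2L])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(image_id = integer(), segment_id = integer(),
                      point_index = integer(), row = numeric(),
                      col = numeric()))
  }
  do.call(rbind, rows)
}

comparison_to_list <- function(cmp) {
  if (is.null(cmp)) return(NULL)
  out <- unclass(cmp)
  if (!is.null(out$pairwise)) out$pairwise <- out$pairwise
  out$statistic <- if (is.finite(out$statistic)) out$statistic else
    as.character(out$statistic)
  out
}

write_pipeline_artifacts <- function(out_dir, config, mode, datasets,
                                     all_segments, summaries,
                                     condition_results, comparisons) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  add <- function(p) written[length(written) + 1L] <<- p

  ## resolved config + seed: sufficient to regenerate everything
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  add(cfg_path)

  for (cd in names(datasets)) {
    ds <- datasets[[cd]]
    cdir <- file.path(out_dir, cd)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(ds)) {
      ipath <- file.path(cdir, sprintf("image_%03d.tif", i))
      write_gray_image(ds[[i]]$image, ipath)
      add(ipath)
    }
    gt <- paths_table(ds)
    gt_path <- file.path(cdir, "ground_truth_paths.csv")
    write_csv_9sig(gt, gt_path)
    add(gt_path)
    sidecar <- file.path(cdir, "ground_truth_spec.json")
    jsonlite::write_json(
      list(condition = cd, spec = unclass(attr(ds, "spec")),
           seed = attr(ds, "seed")),
      sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    add(sidecar)
  }

  for (cd in names(all_segments)) {
    cdir <- file.path(out_dir, cd)
    dir.create(cdir, showWarnings = FALSE)
    sp_path <- file.path(cdir, "segment_points.csv")
    write_csv_9sig(segment_points_table(all_segments[[cd]]), sp_path)
    add(sp_path)
    pooled <- unlist(all_segments[[cd]], recursive = FALSE)
    write_segment_table(pooled, condition_results[[cd]],
                        file.path(cdir, "segments.csv"),
                        file.path(cdir, "morphometry.json"))
    add(file.path(cdir, "segments.csv"))
    add(file.path(cdir, "morphometry.json"))
  }

  sum_path <- file.path(out_dir, "image_summaries.csv")
  write_csv_9sig(summaries, sum_path)
  add(sum_path)

  if (!is.null(comparisons)) {
    cmp_path <- file.path(out_dir, "comparisons.json")
    jsonlite::write_json(lapply(comparisons, comparison_to_list), cmp_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    add(cmp_path)
  }

  prefix <- paste0(sub("/+$", "", out_dir), "/")
  rel <- ifelse(startsWith(written, prefix),
                substring(written, nchar(prefix) + 1L), written)
  manifest <- data.frame(
    file = rel,
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(mode = mode, seed = config$seed, files = manifest),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
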