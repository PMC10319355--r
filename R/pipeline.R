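#' Boxplot-statistics summary of values by condition
#'
#' Per condition: n, minimum, 25th/50th/75th percentiles and maximum (the
#' boxplot convention: box at the quartiles, whiskers at the extremes),
#' plus the mean. Quantiles are computed by linear interpolation between
#' order statistics (R type 7); the rule is echoed in output CSV headers.
#'
#' @param values Numeric vector.
#' @param condition Condition label per value.
#' @return Data frame: `condition`, `n`, `mean`, `min`, `q25`, `median`,
#'   `q75`, `max`.
#' @export
group_summary <- function(values, condition) {
  if (length(values) == 0) stop("no values to summarize")
  if (length(values) != length(condition))
    stop("values and condition lengths differ")
  if (any(!is.finite(values))) stop("values must be finite")
  out <- do.call(rbind, lapply(split(values, condition), function(v) {
    q <- box_quantiles(v)
    data.frame(n = length(v), mean = mean(v), min = min(v),
               q25 = q[1], median = q[2], q75 = q[3], max = max(v))
  }))
  out <- cbind(condition = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

QUANTILE_NOTE <- "# quantiles: linear interpolation between order statistics (R type 7)"

write_csv_noted <- function(df, path, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(note)) writeLines(note, con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run a pipeline subcommand over a batch of inputs
#'
#' Batch front-end around the package's measurement functions, as used by
#' the `wormpheno` command-line script. Every run writes per-item CSVs, a
#' per-condition boxplot-statistics summary where conditions are known,
#' and a JSON run manifest recording the configuration, package version,
#' seeds, per-item errors and every output file. Per-item failures are
#' logged and excluded from the tables, never silently dropped:
#' `items_in = items_out + items_failed` in every manifest.
#'
#' @param subcommand One of `"simulate"`, `"measure"`, `"lumen"`,
#'   `"defecation"`, `"assay"`.
#' @param config Named list. Common: `out_dir` (required). `simulate`:
#'   `n` (default 10), `seed` (default 1), `calibration` (default 5),
#'   `length_range_um` (default `c(800, 1200)`), `max_radius_range_um`
#'   (default `c(25, 40)`), `bend_amplitude_range_um` (default
#'   `c(20, 60)`), `lumen_width_um` (optional). `measure`/`lumen`:
#'   `in_dir` or `files`, `pixels_per_um` (optional override),
#'   `condition_map` (named vector id -> condition), stage options;
#'   `lumen` additionally `positions` or `manual_widths` (data frame
#'   `id, w1_um, w2_um` replicating the manual two-point workflow).
#'   `defecation`: `input` (BORIS CSV), `n_cycles` (default 10),
#'   `condition_map`. `assay`: `input` (plate CSV), `control_label`
#'   (default `"control"`), `policy`, `construct`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(subcommand = c("simulate", "measure", "lumen",
                                        "defecation", "assay"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(subcommand = subcommand,
                   package_version = as.character(utils::packageVersion("wormpheno")),
                   config = config[vapply(config, function(x)
                     is.atomic(x) || is.null(x), logical(1))],
                   items_in = 0L, items_out = 0L, items_failed = 0L,
                   errors = list(), outputs = character(0))
  add_output <- function(path) manifest$outputs <<- c(manifest$outputs, path)

  if (subcommand == "simulate") {
    n <- config$n %||% 10L
    seed <- config$seed %||% 1L
    cal <- config$calibration %||% 5
    lr <- config$length_range_um %||% c(800, 1200)
    rr <- config$max_radius_range_um %||% c(25, 40)
    br <- config$bend_amplitude_range_um %||% c(20, 60)
    manifest$items_in <- as.integer(n)
    params <- with_seed(seed, data.frame(
      length_um = runif(n, lr[1], lr[2]),
      max_radius_um = runif(n, rr[1], rr[2]),
      bend_amplitude_um = runif(n, br[1], br[2]),
      seed = sample.int(1e6, n)))
    truth_rows <- list()
    for (i in seq_len(n)) {
      id <- sprintf("worm_%03d", i)
      lum <- if (!is.null(config$lumen_width_um))
        list(width_um = config$lumen_width_um) else NULL
      sp <- worm_spec(length_um = params$length_um[i],
                      max_radius_um = params$max_radius_um[i],
                      bend_amplitude_um = params$bend_amplitude_um[i],
                      calibration = cal, lumen = lum,
                      seed = params$seed[i], id = id)
      res <- tryCatch({
        sim <- generate_worm_image(sp)
        files <- write_worm_sim(sim, out_dir, stem = id)
        for (f in files) add_output(f)
        truth_rows[[id]] <- data.frame(id = id,
                                       length_um = sim$truth$length_um,
                                       mid_width_um = sim$truth$mid_width_um,
                                       volume_um3 = sim$truth$volume_um3)
        TRUE
      }, error = function(e) conditionMessage(e))
      if (isTRUE(res)) manifest$items_out <- manifest$items_out + 1L
      else {
        manifest$items_failed <- manifest$items_failed + 1L
        manifest$errors[[id]] <- res
      }
    }
    if (length(truth_rows) > 0) {
      tp <- file.path(out_dir, "truth.csv")
      write_csv_noted(do.call(rbind, truth_rows), tp)
      add_output(tp)
    }
  }

  if (subcommand %in% c("measure", "lumen")) {
    manual <- subcommand == "lumen" && !is.null(config$manual_widths)
    files <- if (manual) character(0) else config$files %||% {
      ind <- config$in_dir
      if (is.null(ind)) stop("config$in_dir or config$files is required")
      list.files(ind, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                 full.names = TRUE)
    }
    if (length(files) == 0 && !manual) stop("no input images found")
    rows <- list()
    if (manual) {
      mw <- config$manual_widths
      manifest$items_in <- nrow(mw)
      for (i in seq_len(nrow(mw))) {
        w <- as.numeric(mw[i, c("w1_um", "w2_um")])
        rows[[i]] <- data.frame(id = mw$id[i], w1_um = w[1], w2_um = w[2],
                                mean_um = average_lumen_width(w))
        manifest$items_out <- manifest$items_out + 1L
      }
    } else {
      manifest$items_in <- length(files)
      for (f in files) {
        id <- tools::file_path_sans_ext(basename(f))
        res <- tryCatch({
          img <- read_calibrated_image(f, config$pixels_per_um)
          if (subcommand == "measure") {
            if (isTRUE(config$overlay)) {
              mask <- segment_worm(img, config)
              ml <- extract_midline(mask, config)
              op <- file.path(out_dir, paste0(img$id, "_overlay.png"))
              write_overlay_png(img, mask, ml, op)
              add_output(op)
            }
            as.data.frame(measure_worm(img, config))
          } else {
            mask <- segment_worm(img, config)
            ml <- extract_midline(mask, config)
            lm <- measure_lumen(img, ml, mask, config)
            data.frame(id = img$id, w1_um = lm$point_widths_um[1],
                       w2_um = lm$point_widths_um[2],
                       mean_um = lm$mean_width_um)
          }
        }, error = function(e) conditionMessage(e))
        if (is.data.frame(res)) {
          rows[[id]] <- res
          manifest$items_out <- manifest$items_out + 1L
        } else {
          manifest$items_failed <- manifest$items_failed + 1L
          manifest$errors[[id]] <- res
        }
      }
    }
    if (length(rows) == 0) stop("all items failed")
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    per_item <- file.path(out_dir, paste0(subcommand, ".csv"))
    write_csv_noted(tab, per_item)
    add_output(per_item)
    cmap <- config$condition_map
    if (!is.null(cmap)) {
      cond <- unname(cmap[tab$id])
      keep <- !is.na(cond)
      metrics <- intersect(c("length_um", "mid_width_um", "volume_um3",
                             "mean_um"), names(tab))
      summ <- do.call(rbind, lapply(metrics, function(mcol) {
        s <- group_summary(tab[[mcol]][keep], cond[keep])
        cbind(statistic = mcol, s)
      }))
      sp <- file.path(out_dir, paste0(subcommand, "_summary.csv"))
      write_csv_noted(summ, sp, QUANTILE_NOTE)
      add_output(sp)
    }
  }

  if (subcommand == "defecation") {
    if (is.null(config$input)) stop("config$input (BORIS CSV) is required")
    logs <- parse_boris_csv(config$input, config)
    manifest$items_in <- length(logs)
    n_cycles <- config$n_cycles %||% 10
    ok <- list()
    for (lg in logs) {
      res <- tryCatch({
        data.frame(animal = lg$animal, condition = lg$condition,
                   n_cycles = n_cycles,
                   mean_cycle_length_s = mean_cycle_length(lg, n_cycles),
                   aboc_frequency = aboc_frequency(lg),
                   expulsion_frequency = expulsion_frequency(lg))
      }, error = function(e) conditionMessage(e))
      if (is.data.frame(res)) {
        ok[[lg$animal]] <- lg
        manifest$items_out <- manifest$items_out + 1L
      } else {
        manifest$items_failed <- manifest$items_failed + 1L
        manifest$errors[[lg$animal]] <- res
      }
    }
    if (length(ok) == 0) stop("all items failed")
    summ <- summarize_group(ok, n_cycles = n_cycles,
                            condition_map = config$condition_map)
    pa <- attr(summ, "per_animal")
    p1 <- file.path(out_dir, "defecation_per_animal.csv")
    write_csv_noted(pa, p1)
    add_output(p1)
    p2 <- file.path(out_dir, "defecation_summary.csv")
    write_csv_noted(summ, p2, QUANTILE_NOTE)
    add_output(p2)
  }

  if (subcommand == "assay") {
    if (is.null(config$input)) stop("config$input (plate CSV) is required")
    wells <- read_plate_csv(config$input)
    manifest$items_in <- nrow(wells)
    resp <- normalize_to_control(wells,
                                 config$control_label %||% "control",
                                 config$policy %||% "mean",
                                 construct = config$construct)
    manifest$items_out <- nrow(resp)
    manifest$items_failed <- manifest$items_in - manifest$items_out
    p1 <- file.path(out_dir, "assay_normalized.csv")
    write_csv_noted(resp, p1)
    add_output(p1)
    p2 <- file.path(out_dir, "assay_summary.csv")
    write_csv_noted(summarize_conditions(resp), p2)
    add_output(p2)
  }

  mp <- file.path(out_dir, "manifest.json")
  manifest$outputs <- c(manifest$outputs, mp)
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
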