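PLATE_COLUMNS <- c("assay", "plate", "well", "condition", "construct",
                   "dose", "read_0s", "read_5s")

#' Specify a synthetic cAMP-reporter plate experiment
#'
#' Emulates the reporter assay design: each condition measured in
#' triplicate wells within each of several independent assays, with
#' multiplicative (log-normal) well noise around `baseline x fold_change`.
#' Exactly one condition is the ligand-free control with true fold
#' change 1 (appended automatically when absent).
#'
#' @param conditions Named numeric vector of true fold changes over the
#'   ligand-free control (names are condition labels).
#' @param wells_per_condition Wells per condition per assay (default 3,
#'   i.e. triplicate).
#' @param n_assays Number of independent assays (default 4).
#' @param control_label Label of the ligand-free control (default
#'   `"control"`).
#' @param cv Coefficient of variation of the multiplicative well noise
#'   (default 0.1).
#' @param baseline Control-well luminescence counts (default 1000).
#' @param basal_fold When non-`NULL`, also generate ligand-free wells for
#'   an empty-vector construct whose mean luminescence is
#'   `baseline / basal_fold`, so the receptor-over-empty-vector basal
#'   activity ratio has this true value.
#' @param seed Integer seed.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(conditions, wells_per_condition = 3, n_assays = 4,
                       control_label = "control", cv = 0.1, baseline = 1000,
                       basal_fold = NULL, seed = 1) {
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named numeric vector of fold changes")
  if (any(conditions < 0)) stop("fold changes must be non-negative")
  if (cv < 0) stop("cv must be non-negative")
  if (baseline <= 0) stop("baseline must be positive")
  if (!is.null(basal_fold) && basal_fold <= 0)
    stop("basal_fold must be positive")
  if (!(control_label %in% names(conditions))) {
    conditions <- c(stats::setNames(1, control_label), conditions)
  } else if (conditions[[control_label]] != 1) {
    stop("the control condition must have true fold change 1")
  }
  structure(list(conditions = conditions,
                 wells_per_condition = as.integer(wells_per_condition),
                 n_assays = as.integer(n_assays),
                 control_label = control_label, cv = cv,
                 baseline = baseline, basal_fold = basal_fold,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

# Log-normal multiplicative noise with unit mean and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(rnorm(n, -sigma2 / 2, sqrt(sigma2)))
}

#' Generate synthetic plate-reader well records with known fold changes
#'
#' Per-well luminescence is `baseline x fold_change x lognormal(cv)`
#' (unit-mean noise), emitted as two identical 5-s reads per well (the
#' duplicate integration windows collapsed by [collapse_reads()]).
#'
#' @param spec A [plate_spec()].
#' @return List with `wells` (data frame in the plate CSV schema) and
#'   `true_folds` (named vector of the generating fold changes).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (a in seq_len(spec$n_assays)) {
      well_i <- 0L
      add_wells <- function(cond, construct, mean_level) {
        noise <- rlnorm_cv(spec$wells_per_condition, spec$cv)
        vals <- mean_level * noise
        data.frame(assay = sprintf("assay%02d", a), plate = "plate1",
                   well = sprintf("W%02d", well_i + seq_along(vals)),
                   condition = cond, construct = construct,
                   dose = NA_real_, read_0s = vals, read_5s = vals,
                   stringsAsFactors = FALSE)
      }
      for (cond in names(spec$conditions)) {
        rows[[length(rows) + 1L]] <-
          add_wells(cond, "receptor",
                    spec$baseline * spec$conditions[[cond]])
        well_i <- well_i + spec$wells_per_condition
      }
      if (!is.null(spec$basal_fold)) {
        rows[[length(rows) + 1L]] <-
          add_wells(spec$control_label, "empty_vector",
                    spec$baseline / spec$basal_fold)
        well_i <- well_i + spec$wells_per_condition
      }
    }
    list(wells = do.call(rbind, rows), true_folds = spec$conditions)
  })
}

#' Write / read plate well records in the assay CSV schema
#'
#' The schema has the header-validated columns `assay, plate, well,
#' condition, construct, dose, read_0s, read_5s`.
#'
#' @param wells Data frame of well records.
#' @param path CSV path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_plate_csv <- function(wells, path) {
  missing_cols <- setdiff(PLATE_COLUMNS, names(wells))
  if (length(missing_cols) > 0)
    stop("missing plate columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(wells[, PLATE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing plate columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' Collapse the two 5-second reads of each well into one value
#'
#' Each well is read twice (at 0 s and 5 s); the reads are combined by the
#' chosen policy: their arithmetic mean (default), the first read, or the
#' maximum.
#'
#' @param wells Data frame with `read_0s` and `read_5s` columns (or a
#'   single-record list with those fields).
#' @param policy `"mean"` (default), `"first"` or `"max"`.
#' @return Numeric vector of collapsed luminescence values.
#' @export
collapse_reads <- function(wells, policy = c("mean", "first", "max")) {
  policy <- match.arg(policy)
  r0 <- wells$read_0s; r5 <- wells$read_5s
  if (is.null(r0) || is.null(r5) || any(is.na(r0)) || any(is.na(r5)))
    stop("both reads (read_0s, read_5s) must be present")
  if (any(r0 < 0) || any(r5 < 0)) stop("luminescence reads must be non-negative")
  switch(policy,
         mean = (r0 + r5) / 2,
         first = r0,
         max = pmax(r0, r5))
}

#' Normalize well luminescence to the ligand-free control, per assay
#'
#' Within each assay, every collapsed well value is divided by the mean of
#' that assay's control wells, so the control mean maps to exactly 1
#' (relative luminescence). Normalization is per assay, never pooled:
#' luminometer gain varies between sessions and the assays are independent
#' experiments.
#'
#' @param wells Data frame of well records (plate CSV schema; `construct`
#'   optional).
#' @param control_label Condition label of the ligand-free control.
#' @param policy Read-collapsing policy, see [collapse_reads()].
#' @param construct When given, only wells of this construct are used
#'   (e.g. `"receptor"`, excluding empty-vector wells).
#' @return Data frame: `assay`, `well`, `condition`,
#'   `relative_luminescence`.
#' @export
normalize_to_control <- function(wells, control_label, policy = "mean",
                                 construct = NULL) {
  if (nrow(wells) == 0) stop("no well records")
  if (!is.null(construct) && "construct" %in% names(wells))
    wells <- wells[wells$construct == construct, , drop = FALSE]
  vals <- collapse_reads(wells, policy)
  out <- lapply(split(seq_len(nrow(wells)), wells$assay), function(ix) {
    ctrl <- vals[ix][wells$condition[ix] == control_label]
    if (length(ctrl) == 0)
      stop(sprintf("assay '%s' has no control wells ('%s')",
                   wells$assay[ix[1]], control_label))
    cm <- mean(ctrl)
    if (cm == 0)
      stop(sprintf("assay '%s' has zero control mean", wells$assay[ix[1]]))
    data.frame(assay = wells$assay[ix], well = wells$well[ix],
               condition = wells$condition[ix],
               relative_luminescence = vals[ix] / cm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize normalized responses per condition across assays
#'
#' Wells are first averaged within each assay (per-assay means); the assay,
#' not the well, is the unit of replication. Reports the across-assay mean,
#' standard deviation (`NA` when a condition appears in a single assay) and
#' the number of assays.
#'
#' @param responses Data frame from [normalize_to_control()].
#' @return Data frame: `condition`, `n_assays`, `mean_relative_luminescence`,
#'   `sd_relative_luminescence`; per-assay means in attribute
#'   `"assay_means"`.
#' @export
summarize_conditions <- function(responses) {
  if (is.null(responses) || nrow(responses) == 0) stop("no responses to summarize")
  am <- stats::aggregate(relative_luminescence ~ condition + assay,
                         data = responses, FUN = mean)
  out <- do.call(rbind, lapply(split(am, am$condition), function(grp) {
    data.frame(condition = grp$condition[1], n_assays = nrow(grp),
               mean_relative_luminescence = mean(grp$relative_luminescence),
               sd_relative_luminescence = if (nrow(grp) > 1)
                 stats::sd(grp$relative_luminescence) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "assay_means") <- am
  out
}

#' Basal receptor activity: receptor over empty-vector luminescence
#'
#' Quantifies ligand-independent signaling as the per-assay ratio of the
#' mean ligand-free receptor-well luminescence to the mean empty-vector
#' luminescence, averaged across assays.
#'
#' @param wells Data frame of well records with a `construct` column.
#' @param receptor_label,empty_label Construct labels (defaults
#'   `"receptor"`, `"empty_vector"`).
#' @param control_label When given, only wells of this (ligand-free)
#'   condition enter the ratio.
#' @param policy Read-collapsing policy.
#' @return Across-assay mean ratio, with per-assay ratios in attribute
#'   `"per_assay"`.
#' @export
basal_activity_ratio <- function(wells, receptor_label = "receptor",
                                 empty_label = "empty_vector",
                                 control_label = NULL, policy = "mean") {
  if (!("construct" %in% names(wells))) stop("wells lack a construct column")
  if (!is.null(control_label))
    wells <- wells[wells$condition == control_label, , drop = FALSE]
  vals <- collapse_reads(wells, policy)
  ratios <- vapply(split(seq_len(nrow(wells)), wells$assay), function(ix) {
    rec <- vals[ix][wells$construct[ix] == receptor_label]
    emp <- vals[ix][wells$construct[ix] == empty_label]
    if (length(rec) == 0 || length(emp) == 0) return(NA_real_)
    em <- mean(emp)
    if (em == 0) stop("empty-vector mean luminescence is zero")
    mean(rec) / em
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0)
    stop("no assay contains both receptor and empty-vector wells")
  structure(mean(ratios), per_assay = ratios)
}
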