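well_df <- function(assay, condition, value, construct = "receptor",
                    value5 = value) {
  data.frame(assay = assay, plate = "p1",
             well = sprintf("W%02d", seq_along(value)),
             condition = condition, construct = construct, dose = NA_real_,
             read_0s = value, read_5s = value5, stringsAsFactors = FALSE)
}

test_that("dual reads collapse under the configured policy", {
  w <- well_df("a1", "c", 100, value5 = 120)
  expect_equal(collapse_reads(w), 110)
  expect_equal(collapse_reads(w, "first"), 100)
  expect_equal(collapse_reads(w, "max"), 120)
  w2 <- well_df("a1", "c", 77)
  expect_equal(collapse_reads(w2), 77)
  w3 <- w; w3$read_5s <- NA_real_
  expect_error(collapse_reads(w3), "both reads")
  w4 <- w; w4$read_0s <- -5
  expect_error(collapse_reads(w4), "non-negative")
})

test_that("normalization maps the per-assay control mean to exactly one", {
  wells <- rbind(well_df("a1", "control", c(100, 100, 100)),
                 well_df("a1", "test", 250))
  resp <- normalize_to_control(wells, "control")
  expect_equal(resp$relative_luminescence[resp$condition == "test"], 2.5)
  expect_identical(mean(resp$relative_luminescence[resp$condition ==
                                                     "control"]), 1)
  # per-assay control contract under unequal gains and noisy controls
  wells2 <- rbind(well_df("a1", "control", c(90, 110, 95)),
                  well_df("a1", "t", c(200, 210, 190)),
                  well_df("a2", "control", c(900, 1100, 950)),
                  well_df("a2", "t", c(2000, 2100, 1900)))
  resp2 <- normalize_to_control(wells2, "control")
  cm <- tapply(resp2$relative_luminescence[resp2$condition == "control"],
               resp2$assay[resp2$condition == "control"], mean)
  expect_equal(as.numeric(cm), c(1, 1))
})

test_that("normalization errors on absent or zero controls", {
  expect_error(normalize_to_control(well_df("a1", "t", 100), "control"),
               "no control wells")
  z <- well_df("a1", "control", 0)
  expect_error(normalize_to_control(z, "control"), "zero control mean")
})

test_that("relative luminescence is exactly invariant to assay gain", {
  pl <- generate_plate(plate_spec(c(lo = 2, hi = 3), cv = 0.1, seed = 21))
  resp1 <- normalize_to_control(pl$wells, "control")
  scaled <- pl$wells
  a1 <- scaled$assay == "assay01"
  scaled$read_0s[a1] <- scaled$read_0s[a1] * 8  # exact in floating point
  scaled$read_5s[a1] <- scaled$read_5s[a1] * 8
  resp2 <- normalize_to_control(scaled, "control")
  expect_identical(resp1$relative_luminescence, resp2$relative_luminescence)
})

test_that("normalizing already-normalized data changes nothing", {
  pl <- generate_plate(plate_spec(c(lo = 2), cv = 0.1, seed = 22))
  resp <- normalize_to_control(pl$wells, "control")
  renorm_wells <- pl$wells
  renorm_wells$read_0s <- renorm_wells$read_5s <- resp$relative_luminescence
  # idempotent only because the control mean is already exactly 1
  resp2 <- normalize_to_control(renorm_wells, "control")
  expect_equal(resp2$relative_luminescence, resp$relative_luminescence)
})

test_that("condition summaries treat the assay as the replication unit", {
  resp <- data.frame(assay = rep(c("a1", "a2", "a3", "a4"), each = 3),
                     well = "w", condition = "t",
                     relative_luminescence = rep(c(2, 2, 3, 3), each = 3))
  s <- summarize_conditions(resp)
  expect_equal(s$mean_relative_luminescence, 2.5)
  expect_equal(s$n_assays, 4)
  one <- summarize_conditions(resp[resp$assay == "a1", ])
  expect_equal(one$n_assays, 1)
  expect_true(is.na(one$sd_relative_luminescence))
  expect_error(summarize_conditions(resp[0, ]), "no responses")
})

test_that("generated fold changes are recovered within three standard errors", {
  pl <- generate_plate(plate_spec(c(double = 2, triple = 3), cv = 0.1,
                                  wells_per_condition = 3, n_assays = 4,
                                  seed = 23))
  s <- summarize_conditions(normalize_to_control(pl$wells, "control",
                                                 construct = "receptor"))
  for (cond in c("double", "triple")) {
    rowc <- s[s$condition == cond, ]
    se <- rowc$sd_relative_luminescence / sqrt(rowc$n_assays)
    expect_lt(abs(rowc$mean_relative_luminescence -
                    pl$true_folds[[cond]]), 3 * se + 1e-12)
  }
})

test_that("monotone true folds keep their rank order after aggregation", {
  folds <- c(d1 = 1.5, d2 = 2.5, d3 = 4, d4 = 6)
  pl <- generate_plate(plate_spec(folds, cv = 0.05, seed = 24))
  s <- summarize_conditions(normalize_to_control(pl$wells, "control"))
  s <- s[s$condition != "control", ]
  expect_identical(s$condition[order(s$mean_relative_luminescence)],
                   names(sort(folds)))
})

test_that("basal activity is the receptor over empty-vector ratio", {
  wells <- rbind(well_df("a1", "control", c(400, 400)),
                 well_df("a1", "control", c(100, 100),
                         construct = "empty_vector"))
  expect_equal(as.numeric(basal_activity_ratio(wells)), 4)
  same <- rbind(well_df("a1", "control", c(150, 150)),
                well_df("a1", "control", c(150, 150),
                        construct = "empty_vector"))
  expect_equal(as.numeric(basal_activity_ratio(same)), 1)
  zero <- rbind(well_df("a1", "control", 100),
                well_df("a1", "control", 0, construct = "empty_vector"))
  expect_error(basal_activity_ratio(zero), "zero")
  expect_error(basal_activity_ratio(well_df("a1", "control", 100)[, -5]),
               "construct")
})

test_that("a generated basal fold is recovered within three standard errors", {
  pl <- generate_plate(plate_spec(c(t = 2), cv = 0.1, basal_fold = 2,
                                  seed = 25))
  r <- basal_activity_ratio(pl$wells, control_label = "control")
  per <- attr(r, "per_assay")
  se <- sd(per) / sqrt(length(per))
  expect_lt(abs(as.numeric(r) - 2), 3 * se + 1e-12)
})

test_that("plate CSVs round-trip with header validation", {
  pl <- generate_plate(plate_spec(c(x = 2), seed = 26))
  f <- tempfile(fileext = ".csv")
  write_plate_csv(pl$wells, f)
  back <- read_plate_csv(f)
  expect_equal(back$read_0s, pl$wells$read_0s)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(pl$wells[, 1:4], bad, row.names = FALSE)
  expect_error(read_plate_csv(bad), "missing plate columns")
})
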