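toy_csv <- function(text) {
  f <- tempfile(fileext = ".csv")
  writeLines(text, f)
  f
}

test_that("BORIS point-event CSVs parse into ordered event logs", {
  f <- toy_csv(c("Observation id,Time,Behavior",
                 "wormA,100.5,pboc",
                 "wormA,50.0,pBoc",
                 "wormA,60.2,aboc"))
  logs <- parse_boris_csv(f)
  expect_length(logs, 1)
  expect_equal(logs[["wormA"]]$events$time_s, c(50.0, 60.2, 100.5))
  expect_equal(logs[["wormA"]]$events$label, c("pBoc", "aBoc", "pBoc"))
})

test_that("multiple observation ids yield one log each", {
  f <- toy_csv(c("Observation id,Time,Behavior",
                 "w1,0,pBoc", "w1,50,pBoc",
                 "w2,1,posterior body contraction", "w2,46,pBoc"))
  logs <- parse_boris_csv(f)
  expect_setequal(names(logs), c("w1", "w2"))
  expect_equal(cycle_lengths(logs[["w2"]]), 45)
})

test_that("unknown labels are skipped with a count and states collapsed", {
  f <- toy_csv(c("Observation id,Time,Behavior,Behavior type",
                 "w,0,pBoc,POINT",
                 "w,10,grooming,POINT",
                 "w,20,pBoc,STATE START",
                 "w,25,pBoc,STATE STOP"))
  expect_warning(expect_warning(logs <- parse_boris_csv(f),
                                "state event"),
                 "skipped 1 event")
  expect_equal(logs[["w"]]$events$time_s, c(0, 20))
})

test_that("malformed CSVs are rejected with informative errors", {
  f <- toy_csv(c("obs,Time,Behavior", "w,0,pBoc"))
  expect_error(parse_boris_csv(f), "Observation id")
  f2 <- toy_csv(c("Observation id,Time,Behavior", "w,0,pBoc",
                  "w,abc,pBoc"))
  expect_error(parse_boris_csv(f2), "row 2")
})

test_that("generated logs round-trip through the BORIS writer", {
  g <- generate_event_log(event_log_spec(45, 5, 12, 0.7, 0.9, seed = 3,
                                         animal = "rt"))
  f <- tempfile(fileext = ".csv")
  write_boris_csv(g$log, f)
  back <- parse_boris_csv(f)[["rt"]]
  expect_equal(back$events$time_s, g$log$events$time_s)
  expect_identical(back$events$label, g$log$events$label)
})

test_that("cycle lengths are successive pBoc differences", {
  lg <- event_log(c(0, 50, 100), rep("pBoc", 3))
  expect_equal(cycle_lengths(lg), c(50, 50))
  lg2 <- event_log(c(0, 45, 100), rep("pBoc", 3))
  expect_equal(cycle_lengths(lg2), c(45, 55))
  expect_error(cycle_lengths(event_log(5, "pBoc")), "two pBoc")
  g <- generate_event_log(event_log_spec(50, 8, 15, seed = 6))
  expect_equal(cycle_lengths(g$log), g$true_intervals)
})

test_that("mean cycle length averages the first ten cycles only", {
  lg <- event_log(cumsum(c(0, 40:49, 200, 300)), rep("pBoc", 13))
  expect_equal(mean_cycle_length(lg), mean(40:49))
  expect_equal(mean_cycle_length(lg), 44.5)
  # events after the 11th pBoc cannot change the 10-cycle average
  lg_trunc <- event_log(cumsum(c(0, 40:49)), rep("pBoc", 11))
  expect_equal(mean_cycle_length(lg_trunc), mean_cycle_length(lg))
  expect_error(mean_cycle_length(event_log(c(0, 50), c("pBoc", "pBoc"))),
               "1 cycle\\(s\\) available; 10 required")
})

test_that("aBoc and expulsion frequencies are count ratios", {
  tt <- seq(0, 500, by = 50)
  lg <- event_log(c(tt, tt[1:10] + 20), c(rep("pBoc", 11), rep("aBoc", 10)))
  expect_equal(aboc_frequency(lg), 10 / 11)
  lg2 <- event_log(c(tt, tt[1:5] + 20, tt[1:3] + 30),
                   c(rep("pBoc", 11), rep("aBoc", 5), rep("Exp", 3)))
  expect_equal(aboc_frequency(lg2), 5 / 11)
  expect_equal(expulsion_frequency(lg2), 3 / 11)
})

test_that("frequencies are invariant under uniform time shifts", {
  g <- generate_event_log(event_log_spec(45, 6, 12, 0.6, 0.8, seed = 9))
  lg <- g$log
  shifted <- event_log(lg$events$time_s + 1234.5, lg$events$label,
                       lg$animal)
  expect_identical(aboc_frequency(shifted), aboc_frequency(lg))
  expect_identical(expulsion_frequency(shifted), expulsion_frequency(lg))
  expect_equal(cycle_lengths(shifted), cycle_lengths(lg))
})

test_that("interval sums conserve the pBoc time span exactly", {
  for (seed in 1:10) {
    g <- generate_event_log(event_log_spec(50, 10, 12, 0.5, 0.5,
                                           seed = seed))
    pb <- g$log$events$time_s[g$log$events$label == "pBoc"]
    expect_equal(sum(cycle_lengths(g$log)), max(pb) - min(pb),
                 tolerance = 1e-12)
  }
})

test_that("sampling recovers the generating aBoc probability", {
  g <- generate_event_log(event_log_spec(50, 5, 200, aboc_probability = 0.8,
                                         expulsion_probability = 0, seed = 13))
  se <- sqrt(0.8 * 0.2 / 200)
  expect_lt(abs(aboc_frequency(g$log) - 0.8 * 200 / 201), 3 * se)
})

test_that("group summaries follow the boxplot percentile convention", {
  mk <- function(mean_s, animal, cond)
    generate_event_log(event_log_spec(mean_s, 0, 10, 1, 1, animal = animal,
                                      condition = cond, seed = 1))$log
  logs <- lapply(1:5, function(i) mk(i * 10, paste0("a", i), "wt"))
  s <- summarize_group(logs)
  mcl <- s[s$statistic == "mean_cycle_length_s", ]
  expect_equal(mcl$n, 5)
  expect_equal(mcl[, c("min", "q25", "median", "q75", "max")],
               data.frame(min = 10, q25 = 20, median = 30, q75 = 40,
                          max = 50),
               ignore_attr = TRUE)
  one <- summarize_group(list(mk(42, "solo", "wt")))
  one_mcl <- one[one$statistic == "mean_cycle_length_s", ]
  expect_true(all(one_mcl[, c("min", "q25", "median", "q75", "max")] == 42))
  expect_error(summarize_group(list()), "no event logs")
})

test_that("condition maps relabel animals only at summary time", {
  logs <- lapply(1:4, function(i) generate_event_log(
    event_log_spec(50, 2, 10, 1, 1, animal = paste0("b", i),
                   condition = "blinded", seed = i))$log)
  s <- summarize_group(logs, condition_map = c(b1 = "wt", b2 = "wt",
                                               b3 = "mut", b4 = "mut"))
  expect_setequal(unique(s$condition), c("wt", "mut"))
})
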