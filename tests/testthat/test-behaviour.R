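design <- experiment_design()

test_that("event validation enforces the ethogram rules", {
  ev <- clean_events(design)
  expect_silent(validate_events(ev, design))

  bad <- ev; bad$group_size[1] <- 3  # Iref is an individual metric
  expect_error(validate_events(bad, design), "individual metric")

  bad <- ev; bad$metric[8] <- "Gref"; bad$group_size[8] <- 3  # row 8 is R0HP
  expect_error(validate_events(bad, design), "structure-use metric .* R0")

  bad <- ev; bad$group_size[4] <- 9  # above school size
  expect_error(validate_events(bad, design), "group metric")

  bad <- ev; bad$start_time_s[2] <- 3000  # beyond the 2400 s event
  expect_error(validate_events(bad, design), "outside the flow event")

  bad <- ev; bad$metric[1] <- "Ijump"
  expect_error(validate_events(bad, design), "unknown behaviour metric")

  bad <- ev; bad$replicate[1] <- 6L
  expect_error(validate_events(bad, design), "replicate")

  # offending rows are indexed
  bad <- ev; bad$group_size[c(1, 3)] <- 2
  expect_error(validate_events(bad, design), "rows 1, 3")
})

test_that("zone assignment uses the start position with upstream tie-break", {
  b <- seq(0, 6.5, by = 1.3)  # five 1.3 m zones
  # a sprint starting in C1 belongs to C1 wherever it ends
  expect_equal(assign_zone(0.5, b), "C1")
  expect_equal(assign_zone(6.0, b), "C5")
  expect_equal(assign_zone(0, b), "C1")
  # boundary starts go to the upstream (lower-indexed) zone
  expect_equal(assign_zone(1.3, b), "C1")
  expect_equal(assign_zone(2.6, b), "C2")
  expect_equal(assign_zone(6.5, b), "C5")
  expect_error(assign_zone(7, b), "outside the flume")
  expect_error(assign_zone(-0.1, b), "outside the flume")
})

test_that("frequency tabulation counts, zero-fills and marks absences", {
  ev <- clean_events(design)
  tab <- tabulate_frequencies(ev, design)
  expect_s3_class(tab, "frequency_table")
  expect_equal(nrow(tab), 10 * 5 * 5)
  pick <- function(tr, rep, m)
    tab$count[tab$treatment == tr & tab$replicate == rep & tab$metric == m]
  expect_equal(pick("R1HP", 1, "Iref"), 3L)
  expect_equal(pick("R1HP", 2, "Gdrift"), 2L)
  expect_equal(pick("R2BF", 1, "Gref"), 1L)
  expect_equal(pick("R1BF", 1, "Iref"), 0L)        # unobserved -> 0
  expect_true(is.na(pick("R0HP", 1, "Iref")))      # absent by design -> NA
  # total in = total out
  expect_equal(sum(tab$count, na.rm = TRUE), nrow(ev))

  # empty log: all zeros (except absences)
  empty <- ev[0, ]
  tab0 <- tabulate_frequencies(empty, design)
  expect_true(all(tab0$count[!is.na(tab0$count)] == 0))

  # permutation invariance of the log order
  shuf <- ev[sample.int(nrow(ev)), ]
  expect_equal(tabulate_frequencies(shuf, design), tab)
})

test_that("per-zone marginals recover per-replicate totals", {
  set.seed(14)
  design2 <- experiment_design()
  # random synthetic log over allowed combinations
  n <- 200
  treatments <- sample(design2$treatments, n, replace = TRUE)
  sets <- behaviour_metric_sets()
  metric <- vapply(treatments, function(tr) {
    pool <- if (treatment_configuration(tr) == "R0") sets$activity else sets$all
    sample(pool, 1)
  }, character(1))
  ev <- data.frame(
    treatment = treatments,
    replicate = sample(5L, n, replace = TRUE),
    metric = metric,
    start_time_s = runif(n, 0, 2400),
    start_zone = sample(paste0("C", 1:5), n, replace = TRUE),
    group_size = ifelse(grepl("^I", metric), 1L, sample(2:5, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  byz <- tabulate_frequencies(ev, design2, by_zone = TRUE)
  tot <- tabulate_frequencies(ev, design2)
  agg <- aggregate(count ~ treatment + replicate + metric, data = byz,
                   FUN = sum, na.action = stats::na.pass)
  key <- function(d) paste(d$treatment, d$replicate, d$metric)
  agg <- agg[match(key(tot), key(agg)), ]
  expect_equal(agg$count, tot$count)
})

test_that("frequency tables round-trip through synthetic events", {
  counts <- generate_behaviour_counts(design, effect_spec(), seed = 55)
  ev <- events_from_frequencies(counts, design)
  expect_silent(validate_events(ev, design))
  back <- tabulate_frequencies(ev, design)
  key <- function(d) paste(d$treatment, d$replicate, d$metric)
  back <- back[match(key(counts), key(back)), ]
  expect_equal(back$count, counts$count)
})

test_that("CA aggregation produces the two analysis tables", {
  counts <- generate_behaviour_counts(design, effect_spec(), seed = 7)
  st <- aggregate_for_ca(counts, "structure", "treatment")
  expect_equal(dim(st), c(4, 6))       # R0 excluded x 6 structure metrics
  expect_false("R0HP" %in% rownames(st))
  ac <- aggregate_for_ca(counts, "activity", "treatment")
  expect_equal(dim(ac), c(5, 4))       # all treatments x 4 activity metrics

  # treatment rows are sums over replicate rows
  st_rep <- aggregate_for_ca(counts, "structure", "replicate")
  expect_equal(dim(st_rep), c(20, 6))
  expect_equal(unname(st["R1HP", ]),
               unname(colSums(st_rep[grepl("^R1HP", rownames(st_rep)), ])))

  # equal replicate counts: treatment row = 5 x replicate row
  eq <- counts
  eq$count[!is.na(eq$count)] <- 3L
  st_eq <- aggregate_for_ca(eq, "structure", "treatment")
  expect_true(all(st_eq == 15))

  # zero margins are flagged for CA handling
  z <- counts
  z$count[z$metric == "Gwall"] <- 0L
  zt <- aggregate_for_ca(z, "structure", "treatment")
  expect_equal(attr(zt, "zero_margins")$cols, "Gwall")
})
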