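# detection-history loading, summaries, filters, alignment, and the
# group-relative phenotype transformations

test_that("load_detections deduplicates, sorts, and flags unknown sites", {
  st <- toy_sites()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag_id,site_code,river_km,date",
               "t1,BON,234,2016-06-01",
               "t1,TRA,430,2016-06-20",
               "t1,BON,234,2016-06-01",        # exact duplicate
               "t2,XXX,300,2016-07-01",        # unknown site
               "t3,BON,234,not-a-date"), f)    # bad date
  expect_warning(expect_warning(ev <- load_detections(f, st),
                                "unparseable"), "site code")
  expect_equal(sum(ev$tag_id == "t1"), 2L)     # dedup
  expect_equal(attr(ev, "unknown_sites"), "XXX")
  expect_true(ev$unknown_site[ev$tag_id == "t2"])
  expect_equal(nrow(attr(ev, "bad_rows")), 1L)
  # events sorted by date within fish
  expect_false(is.unsorted(ev$date[ev$tag_id == "t1"]))
  # empty file errors
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("tag_id,site_code,river_km,date", f2)
  expect_error(load_detections(f2, st), "empty")
})

test_that("summarize_history finds upstream site, ties to latest date, and
           is invariant to row order", {
  h <- toy_history("f1", list(BON = 150, TRA = 200))
  expect_equal(h$upstream_site, "TRA")
  expect_equal(h$upstream_km, 430)
  expect_equal(.subset2(h, "bonneville_first_date"),
               as.Date("2016-01-01") + 149)
  # tie at the same maximal km resolved to the later date
  h2 <- toy_history("f2", list(BON = 150, TRA = 180, TRA = 220))
  expect_equal(h2$upstream_date, as.Date("2016-01-01") + 219)
  # permutation invariance
  st <- toy_sites()
  ev <- data.frame(tag_id = "f3", site_code = c("BON", "DAM1", "TRB"),
                   river_km = c(234, 347, 520),
                   date = as.Date("2016-01-01") + c(149, 159, 199))
  h_a <- summarize_history(ev, st)
  h_b <- summarize_history(ev[c(3, 1, 2), ], st)
  expect_equal(h_a[names(h_a) != "events"], h_b[names(h_b) != "events"])
})

test_that("apply_filters classifies each failure branch and retains clean
           fish (hand-enumerated 12-history fixture)", {
  rules <- filter_rules("bonaff")
  fixture <- list(
    # 7 fail branches
    list(h = toy_history("m1", list(BON = 150, DAM1 = 160)),
         reason = "mainstem_last"),
    list(h = toy_history("m2", list(BON = 150)),         # Bonneville-last
         reason = "mainstem_last"),
    list(h = toy_history("m3", list(BON = 150, LOWD = 170)),
         reason = "lower_distribution_last"),
    list(h = toy_history("m4", list(BON = 150, REF1 = 158)),
         reason = "thermal_refuge_last"),
    list(h = toy_history("m5", list(BON = 40, TRA = 100, BON = 360)),
         reason = "repeat_migrant"),
    list(h = toy_history("m6", list(BON = 100, TRA = 445)),  # lag 345
         reason = "lag_over_330"),
    list(h = toy_history("m7", list(BON = 120, TRA = 150)),  # early winter
         reason = "early_winter_overlap"),
    # 5 clean histories
    list(h = toy_history("c1", list(BON = 150, TRA = 165)), reason = "ok"),
    list(h = toy_history("c2", list(BON = 170, DAM1 = 180, TRB = 210)),
         reason = "ok"),
    list(h = toy_history("c3", list(BON = 200, TRC = 240)), reason = "ok"),
    list(h = toy_history("c4", list(BON = 250, TRA = 400)), reason = "ok"),
    list(h = toy_history("c5", list(BON = 134, TRB = 170)), reason = "ok"))
  out <- lapply(fixture, function(x) apply_filters(x$h, rules))
  expect_equal(vapply(out, `[[`, character(1), "reason"),
               vapply(fixture, `[[`, character(1), "reason"))
  expect_equal(sum(vapply(out, `[[`, logical(1), "retained")), 5L)
  # retained <-> reason ok
  for (o in out) expect_equal(o$retained, o$reason == "ok")
})

test_that("filter outcomes are invariant to event row order", {
  rules <- filter_rules("bonaff")
  st <- toy_sites()
  ev <- data.frame(tag_id = "f", site_code = c("BON", "DAM1", "TRA", "BON"),
                   river_km = c(234, 347, 430, 234),
                   date = as.Date("2016-01-01") + c(149, 155, 175, 150))
  base <- apply_filters(summarize_history(ev, st), rules)
  set.seed(7)
  for (i in 1:10) {
    perm <- ev[sample.int(nrow(ev)), ]
    expect_equal(apply_filters(summarize_history(perm, st), rules), base)
  }
})

test_that("hood mode retains repeat migrants' arrival and drops passage", {
  rules <- filter_rules("hood")
  h <- toy_history("r1", list(BON = 150, TRA = 170, TRA = 500))
  o <- apply_filters(h, rules)
  expect_true(o$retained)
  expect_true(o$passage_dropped)
  expect_true(is.na(o$passage_day))
  expect_false(is.na(o$arrival_day))
  # same history in bonaff mode is removed outright
  o2 <- apply_filters(h, filter_rules("bonaff"))
  expect_equal(o2$reason, "repeat_migrant")
})

test_that("spawn-year alignment shifts early pairs jointly and is
           idempotent", {
  expect_equal(spawn_year_align(1, 32), list(passage = 366L, arrival = 397L))
  expect_equal(spawn_year_align(200, 250),
               list(passage = 200L, arrival = 250L))
  # arrival below threshold drags passage along (joint rule)
  expect_equal(spawn_year_align(130, 139),
               list(passage = 495L, arrival = 504L))
  # idempotence on already-aligned values
  al <- spawn_year_align(366, 397)
  expect_equal(al, list(passage = 366L, arrival = 397L))
  expect_equal(spawn_year_align(495, 504),
               list(passage = 495L, arrival = 504L))
  # NA passage (repeat migrant) still aligns arrival
  expect_equal(spawn_year_align(NA, 100)$arrival, 465L)
  expect_error(spawn_year_align(0, 32), "1..731")
  expect_error(spawn_year_align(1, 800), "1..731")
})

test_that("compound statistics follow the zero-lag convention", {
  expect_equal(compound_stats(150, 160, 100),
               list(lag_days = 10L, migration_rate = 10))
  expect_equal(compound_stats(150, 150, 80),
               list(lag_days = 0L, migration_rate = 80))
  expect_error(compound_stats(150, 160, -5), "negative")
  expect_error(compound_stats(160, 150, 10), "arrival before passage")
})

test_that("relative statistics use the even-group median convention and the
           last reference is never positive", {
  d <- c(100, 110, 120)
  g <- rep("a", 3)
  expect_equal(relative_stat(d, g, period = "all_years")[2], 0)
  expect_equal(relative_stat(d, g, reference = "last",
                             period = "all_years")[3], 0)
  d4 <- c(100, 110, 120, 130)
  out <- relative_stat(d4, rep("a", 4), period = "all_years")
  expect_equal(out[1], -15)               # median = mean of middle two
  expect_true(all(relative_stat(d4, rep("a", 4), reference = "last",
                                period = "all_years") <= 0))
  expect_warning(relative_stat(c(5, 7), c("a", "b"), period = "all_years"),
                 "singleton")
  # brute-force oracle: within-group values match direct recomputation
  set.seed(11)
  dd <- sample(100:300, 40, replace = TRUE)
  gg <- sample(c("x", "y", "z"), 40, replace = TRUE)
  yy <- sample(2015:2016, 40, replace = TRUE)
  got <- relative_stat(dd, gg, yy, "median", "year")
  for (i in seq_along(dd)) {
    cell <- dd[gg == gg[i] & yy == yy[i]]
    expect_equal(got[i], dd[i] - median(cell))
  }
})

test_that("derive_phenotypes emits 20 phenotype columns per retained fish
           with exact lag identity", {
  cfg <- scenario_config("coastal", n = 60, seed = 21)
  sim <- simulate_scenario(cfg)
  res <- derive_phenotypes(sim$events, sim$sites, filter_rules("bonaff"))
  ph <- res$phenotypes
  pheno_cols <- setdiff(names(ph), c("tag_id", "spawn_year", "upstream_km",
                                     "huc", "sub_basin", "lineage"))
  expect_length(pheno_cols, 20L)
  expect_equal(ph$lag_days, ph$arrival_day - ph$passage_day)
  expect_false(any(is.na(ph[, pheno_cols])))
  # audit covers every fish exactly once
  expect_setequal(res$audit$tag_id, unique(sim$events$tag_id))
})
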