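# Migration-timing phenotypes from PIT-tag detection histories: loading and
# deduplication, per-fish history summaries, quality filters (mortalities,
# dip-ins, repeat migrants, season overlap), spawn-year alignment, compound
# statistics, and group-relative transformations.

#' Construct a detection-site metadata table
#'
#' @param site_code Unique site (array) codes.
#' @param river_km Distance from the river mouth in km (>= 0).
#' @param site_class One of `"bonneville"`, `"mainstem_dam"`,
#'   `"lower_distribution"`, `"thermal_refuge"`, `"tributary"`.
#' @param huc Hydrological-unit grouping label.
#' @param sub_basin Sub-basin grouping label.
#' @param lineage `"coastal"`, `"intermediate"` or `"inland"`; required for
#'   tributary sites, `NA` allowed elsewhere.
#' @return A validated `data.frame`.
#' @export
site_metadata <- function(site_code, river_km, site_class, huc = NA,
                          sub_basin = NA, lineage = NA) {
  cls <- c("bonneville", "mainstem_dam", "lower_distribution",
           "thermal_refuge", "tributary")
  site_class <- as.character(site_class)
  if (!all(site_class %in% cls)) stop("invalid site_class")
  if (anyDuplicated(site_code)) stop("duplicated site_code")
  if (any(river_km < 0)) stop("river_km must be >= 0")
  lineage <- as.character(rep_len(lineage, length(site_code)))
  bad <- site_class == "tributary" & (is.na(lineage) |
    !lineage %in% c("coastal", "intermediate", "inland"))
  if (any(bad)) stop("lineage required for tributary sites")
  data.frame(site_code = as.character(site_code),
             river_km = as.numeric(river_km),
             site_class = site_class,
             huc = as.character(rep_len(huc, length(site_code))),
             sub_basin = as.character(rep_len(sub_basin, length(site_code))),
             lineage = lineage,
             stringsAsFactors = FALSE)
}

#' Load a detection-history table
#'
#' Reads a delimited PTAGIS-style detection file (tag id, site code, river
#' kilometer, ISO-8601 date), deduplicates on (tag, site, date) and sorts
#' each fish's events by date.  Rows whose date cannot be parsed are dropped
#' with a warning (collected in the `"bad_rows"` attribute); events at sites
#' absent from the site table are retained but flagged.
#'
#' @param path File path.
#' @param site_table A [site_metadata()] table.
#' @param col_map Named character vector mapping the canonical names
#'   `tag_id`, `site_code`, `river_km`, `date` to the file's column names.
#' @param sep Field separator (default `","`).
#' @return Data frame `tag_id`, `site_code`, `river_km`, `date` (`Date`),
#'   `unknown_site` (logical), sorted by tag and date; attributes
#'   `"unknown_sites"` and `"bad_rows"`.
#' @export
load_detections <- function(path, site_table,
                            col_map = c(tag_id = "tag_id",
                                        site_code = "site_code",
                                        river_km = "river_km",
                                        date = "date"),
                            sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(tab)) stop("empty detection file: ", path)
  need <- c("tag_id", "site_code", "river_km", "date")
  if (!all(need %in% names(col_map))) stop("col_map must name all of: ",
                                           paste(need, collapse = ", "))
  miss <- setdiff(unname(col_map[need]), names(tab))
  if (length(miss)) stop("columns not in file: ", paste(miss, collapse = ", "))
  ev <- data.frame(tag_id = as.character(tab[[col_map["tag_id"]]]),
                   site_code = as.character(tab[[col_map["site_code"]]]),
                   river_km = as.numeric(tab[[col_map["river_km"]]]),
                   date_raw = as.character(tab[[col_map["date"]]]),
                   stringsAsFactors = FALSE)
  ev$date <- as.Date(ev$date_raw, format = "%Y-%m-%d")
  bad <- is.na(ev$date)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable dates dropped")
  }
  bad_rows <- ev[bad, , drop = FALSE]
  ev <- ev[!bad, c("tag_id", "site_code", "river_km", "date")]
  ev <- ev[!duplicated(ev[, c("tag_id", "site_code", "date")]), ]
  ev <- ev[order(ev$tag_id, ev$date, ev$river_km), ]
  ev$unknown_site <- !(ev$site_code %in% site_table$site_code)
  if (any(ev$unknown_site)) {
    warning("events at ", length(unique(ev$site_code[ev$unknown_site])),
            " site code(s) missing from the site table; flagged")
  }
  rownames(ev) <- NULL
  attr(ev, "unknown_sites") <- unique(ev$site_code[ev$unknown_site])
  attr(ev, "bad_rows") <- bad_rows
  ev
}

#' Summarize one fish's detection history
#'
#' Reduces a fish's events to the quantities the filters and phenotypes
#' need: first detection at the Bonneville array, the most upstream
#' detection (maximal river km; km ties broken by the latest date, a proxy
#' for the final approach), and all dates at the Bonneville and upstream
#' sites.  River kilometers are taken from the site table where the site is
#' known, from the event record otherwise.
#'
#' @param events Event data frame for a single tag (any row order).
#' @param site_table A [site_metadata()] table.
#' @return An object of class `"fish_history"`.
#' @export
summarize_history <- function(events, site_table) {
  if (!nrow(events)) stop("no events for fish; insufficient_detections")
  if (length(unique(events$tag_id)) != 1L) stop("events span multiple tags")
  ev <- events[order(events$date, events$river_km), , drop = FALSE]
  m <- match(ev$site_code, site_table$site_code)
  km <- ifelse(is.na(m), ev$river_km, site_table$river_km[m])
  cls <- ifelse(is.na(m), NA_character_, site_table$site_class[m])
  bon <- which(!is.na(cls) & cls == "bonneville")
  up_i <- which(km == max(km))
  up_i <- up_i[which.max(as.numeric(ev$date[up_i]))]   # tie -> latest date
  up_site <- ev$site_code[up_i]
  structure(list(
    tag_id = ev$tag_id[1],
    n_events = nrow(ev),
    bonneville_first_date = if (length(bon)) min(ev$date[bon]) else
      as.Date(NA),
    bonneville_dates = ev$date[bon],
    upstream_site = up_site,
    upstream_km = km[up_i],
    upstream_date = ev$date[up_i],
    upstream_class = cls[up_i],
    upstream_dates = ev$date[ev$site_code == up_site],
    huc = if (!is.na(m[up_i])) site_table$huc[m[up_i]] else NA_character_,
    sub_basin = if (!is.na(m[up_i])) site_table$sub_basin[m[up_i]] else
      NA_character_,
    lineage = if (!is.na(m[up_i])) site_table$lineage[m[up_i]] else
      NA_character_,
    events = ev), class = "fish_history")
}

#' @export
print.fish_history <- function(x, ...) {
  cat(sprintf("fish %s: %d events; Bonneville %s; upstream %s (km %.0f) %s\n",
              x$tag_id, x$n_events,
              format(x$bonneville_first_date), x$upstream_site,
              x$upstream_km, format(x$upstream_date)))
  invisible(x)
}

#' Filtering rules for detection histories
#'
#' Bundles the thresholds of [apply_filters()].  In `"bonaff"` mode a
#' Bonneville detection is mandatory, repeat migrants lose the whole
#' record, and the early-winter overlap rule applies (records with both
#' passage before `early_passage_ord`, mid-May by default, and arrival
#' before `early_arrival_ord`, mid-June by default, are removed).  In
#' `"hood"` mode repeat migrants keep their arrival day (passage dropped)
#' and the overlap is handled by [spawn_year_align()] instead.
#'
#' @param mode `"bonaff"` or `"hood"`.
#' @param lag_max Maximum days between passage and arrival (default 330).
#' @param repeat_gap_days Gap between two Bonneville or two upstream
#'   detections that marks a repeat migrant (default 300).
#' @param early_passage_ord,early_arrival_ord Early-winter overlap ordinals
#'   (defaults 135 and 166).
#' @param apply_early_winter Whether the overlap rule is active (default:
#'   only in bonaff mode).
#' @param bonneville_km River km of the Bonneville array (default 234).
#' @param align_passage_threshold,align_arrival_threshold Hood spawn-year
#'   alignment ordinals (defaults 121 and 141).
#' @param spawn_turnover_ord Arrival ordinal from which a fish is assigned
#'   to the following spring's spawn year (default 182, July 1).
#' @return A list of class `"filter_rules"`.
#' @export
filter_rules <- function(mode = c("bonaff", "hood"), lag_max = 330,
                         repeat_gap_days = 300, early_passage_ord = 135,
                         early_arrival_ord = 166,
                         apply_early_winter = NULL, bonneville_km = 234,
                         align_passage_threshold = 121,
                         align_arrival_threshold = 141,
                         spawn_turnover_ord = 182) {
  mode <- match.arg(mode)
  if (is.null(apply_early_winter)) apply_early_winter <- mode == "bonaff"
  structure(list(mode = mode, lag_max = lag_max,
                 repeat_gap_days = repeat_gap_days,
                 early_passage_ord = early_passage_ord,
                 early_arrival_ord = early_arrival_ord,
                 apply_early_winter = apply_early_winter,
                 bonneville_km = bonneville_km,
                 align_passage_threshold = align_passage_threshold,
                 align_arrival_threshold = align_arrival_threshold,
                 spawn_turnover_ord = spawn_turnover_ord),
            class = "filter_rules")
}

# ordinal day relative to January 1 of anchor_year (day 1 = Jan 1)
.ordinal_day <- function(date, anchor_year) {
  as.integer(date - as.Date(sprintf("%d-01-01", anchor_year))) + 1L
}

#' Apply the detection-history quality filters
#'
#' Classifies a summarized history by the first failing rule, in fixed
#' order: insufficient detections; most upstream array a mainstem dam (or
#' Bonneville itself: pre-arrival mortality); most upstream array a
#' lower-distribution site (destination ambiguous); most upstream array a
#' thermal-refuge mouth (dip-in); repeat migrant (two Bonneville or two
#' upstream-site detections more than `repeat_gap_days` apart); lag from
#' passage to arrival above `lag_max`; early-winter overlap (both passage
#' and arrival before the season thresholds, bonaff mode).  Hood mode
#' retains repeat migrants' arrival day and drops the passage phenotype,
#' and applies [spawn_year_align()] to the day pair before the lag rule.
#'
#' @param history A `"fish_history"` from [summarize_history()].
#' @param rules A [filter_rules()] object.
#' @return List of class `"filter_outcome"`: `tag_id`, `retained`, `reason`
#'   (one of `ok`, `mainstem_last`, `lower_distribution_last`,
#'   `thermal_refuge_last`, `repeat_migrant`, `lag_over_330`,
#'   `early_winter_overlap`, `insufficient_detections`), `passage_dropped`,
#'   and for retained fish `passage_day`, `arrival_day` (aligned in hood
#'   mode), `anchor_year`, `spawn_year`.
#' @export
apply_filters <- function(history, rules) {
  stopifnot(inherits(history, "fish_history"), inherits(rules, "filter_rules"))
  out <- function(reason, passage_dropped = FALSE, passage = NA_integer_,
                  arrival = NA_integer_, anchor = NA_integer_) {
    # spawn year from the actual arrival date: arrivals from July onwards
    # belong to the following spring's spawn year
    spawn <- if (!is.na(arrival)) {
      ud <- history$upstream_date
      u_year <- as.integer(format(ud, "%Y"))
      u_year + as.integer(.ordinal_day(ud, u_year) >=
                            rules$spawn_turnover_ord)
    } else NA_integer_
    structure(list(tag_id = history$tag_id, retained = reason == "ok",
                   reason = reason, passage_dropped = passage_dropped,
                   passage_day = passage, arrival_day = arrival,
                   anchor_year = anchor, spawn_year = spawn),
              class = "filter_outcome")
  }
  has_bon <- !is.na(history$bonneville_first_date)
  if (history$n_events == 0L || (rules$mode == "bonaff" && !has_bon)) {
    return(out("insufficient_detections"))
  }
  cls <- history$upstream_class
  if (!is.na(cls) && cls %in% c("bonneville", "mainstem_dam")) {
    return(out("mainstem_last"))
  }
  if (!is.na(cls) && cls == "lower_distribution") {
    return(out("lower_distribution_last"))
  }
  if (!is.na(cls) && cls == "thermal_refuge") {
    return(out("thermal_refuge_last"))
  }
  gap <- function(d) if (length(d) < 2L) 0 else
    max(as.numeric(diff(range(d))))
  is_repeat <- gap(history$bonneville_dates) >= rules$repeat_gap_days ||
    gap(history$upstream_dates) >= rules$repeat_gap_days
  passage_dropped <- FALSE
  if (is_repeat) {
    if (rules$mode == "bonaff") return(out("repeat_migrant"))
    passage_dropped <- TRUE            # hood: keep arrival, drop passage
  }
  anchor <- as.integer(format(if (has_bon && !passage_dropped)
    history$bonneville_first_date else history$upstream_date, "%Y"))
  passage <- if (has_bon && !passage_dropped) {
    .ordinal_day(history$bonneville_first_date, anchor)
  } else NA_integer_
  arrival <- .ordinal_day(history$upstream_date, anchor)
  if (rules$mode == "hood") {
    al <- spawn_year_align(passage, arrival,
                           rules$align_passage_threshold,
                           rules$align_arrival_threshold)
    passage <- al$passage; arrival <- al$arrival
  }
  if (!is.na(passage) && arrival - passage > rules$lag_max) {
    return(out("lag_over_330"))
  }
  if (rules$apply_early_winter && !is.na(passage) &&
      passage < rules$early_passage_ord &&
      arrival < rules$early_arrival_ord) {
    return(out("early_winter_overlap"))
  }
  out("ok", passage_dropped, passage, arrival, anchor)
}

#' Spawn-year alignment of Hood River day pairs
#'
#' Late-arriving winter-run fish and very early summer-run fish from
#' consecutive spawn years overlap in the same calendar spring; to keep
#' genotype order monotone in ordinal days, fish passing Bonneville before
#' `passage_threshold` (May 1) or arriving before `arrival_threshold`
#' (May 21) have 365 days added to both values.  The rule is joint: one
#' early day shifts the pair.  Already-aligned values (>= 366) never
#' re-trigger the rule, so the operation is idempotent.
#'
#' @param passage_day,arrival_day Ordinal days (vectors; `NA` passage
#'   allowed for repeat migrants that kept only arrival).  Values must lie
#'   in 1..731 (raw 1..366 or previously aligned).
#' @param passage_threshold,arrival_threshold Alignment ordinals (defaults
#'   121 and 141).
#' @return List `passage`, `arrival` of adjusted days.
#' @examples
#' spawn_year_align(1, 32)      # -> 366, 398
#' spawn_year_align(200, 250)   # unchanged
#' @export
spawn_year_align <- function(passage_day, arrival_day,
                             passage_threshold = 121,
                             arrival_threshold = 141) {
  p <- as.integer(passage_day); a <- as.integer(arrival_day)
  chk <- c(p[!is.na(p)], a[!is.na(a)])
  if (any(chk < 1L | chk > 731L)) {
    stop("ordinal days must lie in 1..731")
  }
  shift <- (!is.na(p) & p < passage_threshold) |
    (!is.na(a) & a < arrival_threshold)
  p[shift & !is.na(p)] <- p[shift & !is.na(p)] + 365L
  a[shift & !is.na(a)] <- a[shift & !is.na(a)] + 365L
  list(passage = p, arrival = a)
}

#' Compound migration statistics
#'
#' Lag (days from Bonneville passage to tributary arrival) and migration
#' rate (km/day over the distance from Bonneville to the most upstream
#' array).  A same-day arrival (lag 0) uses a one-day divisor so the rate
#' stays finite.
#'
#' @param passage_day,arrival_day Ordinal days with `arrival >= passage`.
#' @param distance_km Distance upstream of Bonneville (> 0; a negative
#'   distance indicates an inconsistent site table and is an error).
#' @return List `lag_days`, `migration_rate`.
#' @export
compound_stats <- function(passage_day, arrival_day, distance_km) {
  if (any(!is.na(distance_km) & distance_km < 0)) {
    stop("negative migration distance; check the site table")
  }
  lag <- as.integer(arrival_day) - as.integer(passage_day)
  if (any(!is.na(lag) & lag < 0)) stop("arrival before passage")
  list(lag_days = lag,
       migration_rate = distance_km / pmax(lag, 1L))
}

#' Group-relative phenotype transformation
#'
#' Transforms each fish's day relative to the median or the last (maximum)
#' day of its group cell, where cells are a grouping label optionally
#' crossed with spawn year.  Even-sized group medians are the mean of the
#' two central values; "last"-referenced values are always <= 0.
#'
#' @param days Ordinal days (NA allowed, propagated).
#' @param group Grouping label per fish (HUC or sub-basin).
#' @param year Spawn year per fish; used when `period = "year"`.
#' @param reference `"median"` or `"last"`.
#' @param period `"year"` (within spawn year) or `"all_years"` (pooled).
#' @return Numeric vector `day - reference(group cell)`; singleton cells
#'   give 0 with a warning.
#' @export
relative_stat <- function(days, group, year = NULL,
                          reference = c("median", "last"),
                          period = c("year", "all_years")) {
  reference <- match.arg(reference)
  period <- match.arg(period)
  days <- as.numeric(days)
  cell <- if (period == "year") {
    if (is.null(year)) stop("year required for period = 'year'")
    paste(group, year, sep = "\r")
  } else as.character(group)
  cell[is.na(days)] <- NA
  refv <- rep(NA_real_, length(days))
  singleton <- FALSE
  for (g in unique(cell[!is.na(cell)])) {
    ix <- which(!is.na(cell) & cell == g)
    if (length(ix) == 1L) singleton <- TRUE
    refv[ix] <- if (reference == "median") stats::median(days[ix]) else
      max(days[ix])
  }
  if (singleton) warning("singleton group cell(s): relative value 0")
  days - refv
}

#' Derive the migration-timing phenotype table
#'
#' Runs the full phenotype pipeline over a detection table: per-fish
#' history summaries, quality filters, (hood-mode) spawn-year alignment,
#' the two raw phenotypes (Bonneville passage and tributary arrival day),
#' the two compound phenotypes (lag, migration rate), and the 16
#' group-relative phenotypes (passage/arrival relative to the median/last
#' day by HUC/sub-basin within spawn year or across years) — 20 phenotype
#' columns per retained fish.
#'
#' @param detections Event table from [load_detections()].
#' @param site_table A [site_metadata()] table.
#' @param rules A [filter_rules()] object.
#' @return List with `phenotypes` (one row per retained fish) and `audit`
#'   (`tag_id`, `retained`, `reason` for every fish).
#' @export
derive_phenotypes <- function(detections, site_table, rules = filter_rules()) {
  tags <- unique(detections$tag_id)
  outcomes <- lapply(tags, function(tg) {
    h <- summarize_history(detections[detections$tag_id == tg, , drop = FALSE],
                           site_table)
    c(apply_filters(h, rules),
      list(upstream_km = h$upstream_km, huc = h$huc,
           sub_basin = h$sub_basin, lineage = h$lineage))
  })
  audit <- data.frame(
    tag_id = vapply(outcomes, `[[`, character(1), "tag_id"),
    retained = vapply(outcomes, `[[`, logical(1), "retained"),
    reason = vapply(outcomes, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  keep <- outcomes[audit$retained]
  if (!length(keep)) {
    return(list(phenotypes = NULL, audit = audit))
  }
  ph <- data.frame(
    tag_id = vapply(keep, `[[`, character(1), "tag_id"),
    passage_day = vapply(keep, `[[`, integer(1), "passage_day"),
    arrival_day = vapply(keep, `[[`, integer(1), "arrival_day"),
    spawn_year = vapply(keep, `[[`, integer(1), "spawn_year"),
    upstream_km = vapply(keep, `[[`, numeric(1), "upstream_km"),
    huc = vapply(keep, `[[`, character(1), "huc"),
    sub_basin = vapply(keep, `[[`, character(1), "sub_basin"),
    lineage = vapply(keep, `[[`, character(1), "lineage"),
    stringsAsFactors = FALSE)
  cs <- compound_stats(ph$passage_day, ph$arrival_day,
                       ph$upstream_km - rules$bonneville_km)
  ph$lag_days <- cs$lag_days
  ph$migration_rate <- cs$migration_rate
  for (pheno in c("passage", "arrival")) {
    d <- if (pheno == "passage") ph$passage_day else ph$arrival_day
    for (ref in c("median", "last")) {
      for (grp in c("huc", "sub_basin")) {
        for (per in c("year", "all_years")) {
          nm <- paste(pheno, "rel", ref, grp, per, sep = "_")
          ph[[nm]] <- suppressWarnings(
            relative_stat(d, ph[[grp]], ph$spawn_year, ref, per))
        }
      }
    }
  }
  list(phenotypes = ph, audit = audit)
}
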