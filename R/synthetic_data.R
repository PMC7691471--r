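# Synthetic-data generator: genotypes drawn from the packaged haplotype
# pools, run-timing and age/length phenotypes under the study system's
# assumed effect structure, and PTAGIS-like detection histories, all with
# complete truth labels.  Scenario noise parameters are solved at
# configuration time by moment matching so that the population variance
# share of the causal marker equals the scenario's configured target.

# ---- calibration: run timing -------------------------------------------

# mean/variance of arrival day per causal-dosage class, with the
# overwinter mixture handled through truncated-normal moments
.runtiming_class_moments <- function(rt, sigma_p) {
  d <- 0:2
  mu <- rt$baseline + rt$effect * d
  shift <- ifelse(d == 1L, rt$het_arrival_shift, 0)
  if (!rt$overwinter) {
    m <- mu + rt$lag0 + shift
    v <- rep(sigma_p^2 + rt$sigma_lag^2, 3)
    return(list(m = m, v = v))
  }
  thr <- rt$overwinter_threshold
  z <- (thr - mu) / sigma_p
  S <- 1 - stats::pnorm(z)              # P(overwinter)
  phi <- stats::dnorm(z)
  EtI <- mu * S + sigma_p * phi
  Et2I <- (mu^2 + sigma_p^2) * S + sigma_p * (thr + mu) * phi
  Et1 <- mu - EtI                        # E[t (1-I)]
  Et21 <- mu^2 + sigma_p^2 - Et2I
  c1 <- 365 + rt$spring_base - rt$spring_slope * thr
  ss <- rt$spring_slope
  m <- (Et1 + rt$lag0 * (1 - S)) + c1 * S + ss * EtI + shift
  Ea2 <- Et21 + 2 * rt$lag0 * Et1 + rt$lag0^2 * (1 - S) +
    c1^2 * S + 2 * c1 * ss * EtI + ss^2 * Et2I
  v <- Ea2 - (m - shift)^2 +
    (1 - S) * rt$sigma_lag^2 + S * rt$sigma_winter^2
  list(m = m, v = v)
}

# population R2 of the causal dosage on arrival day
.runtiming_r2 <- function(rt, p_mature, sigma_p) {
  d <- 0:2
  q <- stats::dbinom(d, 2, p_mature)
  cm <- .runtiming_class_moments(rt, sigma_p)
  mbar <- sum(q * cm$m)
  v_arr <- sum(q * (cm$v + cm$m^2)) - mbar^2
  dbar <- 2 * p_mature
  v_d <- 2 * p_mature * (1 - p_mature)
  cv <- sum(q * d * cm$m) - dbar * mbar
  cv^2 / (v_d * v_arr)
}

.solve_runtiming_sigma <- function(rt, p_mature) {
  if (p_mature <= 1e-6 || p_mature >= 1 - 1e-6) {
    # degenerate pool: no dosage variance, nothing to calibrate
    return(15)
  }
  f <- function(lsig) .runtiming_r2(rt, p_mature, exp(lsig)) - rt$target_r2
  lo <- log(0.5); hi <- log(500)
  if (f(lo) < 0) {
    stop("run-timing target R2 unreachable: raise the haplotype effect")
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

# ---- calibration: age / length -----------------------------------------

# ocean-age class probabilities for one dosage/sex cell (probit thresholds;
# homozygous-short fish can never reach the oldest class)
.age_class_probs <- function(al, b, d, male) {
  eta <- b * d + al$beta_sex * male
  p1 <- stats::pnorm(al$tau1 - eta)
  p3 <- if (d > 0) 1 - stats::pnorm(al$tau2 - eta) else 0
  c(p1, 1 - p1 - p3, p3)
}

# population R2 of chr25 dosage on fork length within one sex
.agelen_r2 <- function(al, p_long, b, sigma_len, male) {
  d <- 0:2
  q <- stats::dbinom(d, 2, p_long)
  m <- numeric(3); v <- numeric(3)
  for (i in 1:3) {
    pk <- .age_class_probs(al, b, d[i], male)
    m[i] <- sum(pk * al$age_means)
    v[i] <- sum(pk * al$age_means^2) - m[i]^2 + sigma_len^2
  }
  mbar <- sum(q * m)
  v_len <- sum(q * (v + m^2)) - mbar^2
  v_d <- 2 * p_long * (1 - p_long)
  cv <- sum(q * d * m) - 2 * p_long * mbar
  cv^2 / (v_d * v_len)
}

# The base (female) latent effect is fixed by the scenario; the length
# noise SD is solved from the female variance-share target and the male
# effect multiplier from the male target (the sexes differ by an
# amplification of the locus effect, not just the threshold shift).
.solve_age_length <- function(al, p_long) {
  if (p_long <= 1e-6 || p_long >= 1 - 1e-6) {
    return(list(sigma_len = 6, male_mult = 1))   # degenerate pool
  }
  b <- al$beta_base
  f <- function(ls) {
    .agelen_r2(al, p_long, b, exp(ls), 0) - al$target_r2_female
  }
  if (f(log(0.25)) < 0) {
    stop("female length-variance target unreachable: raise beta_base")
  }
  sigma_len <- exp(stats::uniroot(f, c(log(0.25), log(60)),
                                  tol = 1e-10)$root)
  g <- function(m) {
    .agelen_r2(al, p_long, b * m, sigma_len, 1) - al$target_r2_male
  }
  lo <- 0.3; hi <- 1
  while (g(hi) < 0 && hi < 6) { lo <- hi; hi <- hi + 0.25 }
  if (g(lo) * g(hi) > 0) stop("male length-variance target unreachable")
  male_mult <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  list(sigma_len = sigma_len, male_mult = male_mult)
}

# ---- scenario configuration --------------------------------------------

.default_arrays <- function() {
  site_metadata(
    site_code = c("BON", "TDA", "JDA", "MCN",
                  "KLIM", "JDAM",
                  "WENL",
                  "WINT", "HOOT", "KLIT",
                  "JDT", "UMAT", "WALT", "YAKT", "GRNT", "CLWT", "SALT"),
    river_km = c(234, 308, 347, 470,
                 290, 351,
                 830,
                 249, 272, 302,
                 430, 511, 560, 580, 640, 750, 800),
    site_class = c("bonneville", rep("mainstem_dam", 3),
                   rep("thermal_refuge", 2),
                   "lower_distribution",
                   rep("tributary", 10)),
    huc = c("BONN", "TDA", "JDA", "MCN", "KLIK", "JDAY", "WENA",
            "WIND", "HOOD", "KLIK",
            "LJDAY", "UMAT", "WALL", "LYAK", "LGRD", "LCLE", "SSAL"),
    sub_basin = c("Bonneville", "TheDalles", "JohnDayDam", "McNary",
                  "Klickitat", "JohnDay", "Wenatchee",
                  "Wind", "Hood", "Klickitat",
                  "JohnDay", "Umatilla", "WallaWalla", "Yakima",
                  "GrandeRonde", "Clearwater", "Salmon"),
    lineage = c(rep(NA, 7),
                "coastal", "coastal", "intermediate",
                rep("inland", 7)))
}

#' Configure a synthetic scenario
#'
#' Builds the full parameter set of one simulation scenario and solves its
#' calibrated noise parameters.  The packaged scenarios are:
#' \describe{
#'   \item{`"coastal"`}{One coastal-lineage population (Hood-style chromosome
#'     28 haplotype pool); the chromosome 28 region explains 51% of the
#'     variance in tributary arrival day.}
#'   \item{`"inland"`}{One inland population (interior chromosome 28 pool)
#'     with overwintering-driven bimodal arrival; the region explains 8% of
#'     arrival variance.}
#'   \item{`"hood"`}{Coastal pool with a larger day effect so that mature
#'     homozygotes arrive across the calendar-year boundary; exercises
#'     spawn-year alignment.}
#'   \item{`"age25"`}{Inland population with the chromosome 25 ocean-age /
#'     fork-length model active; the top marker explains 17.0% (males) and
#'     11.1% (females) of fork-length variance.}
#'   \item{`"bonaff"`}{Mixed-run sample drawn from the full Bonneville-style
#'     chromosome 28 pool; used for haplotype-frequency recovery.}
#'   \item{`"two_lineage"`}{Half coastal, half inland; used for population
#'     structure (kinship, PCA, FST) checks.}
#' }
#' Noise SDs (`sigma_passage`, `sigma_len`) and the latent chromosome 25
#' effect are solved deterministically from the configured variance-share
#' targets by moment matching (see the package vignette).
#'
#' @param scenario Scenario name.
#' @param n Number of fish (default 400; 2000 for `"age25"`, 1538 for
#'   `"bonaff"`).
#' @param seed Default seed stored in the config (used by
#'   [simulate_scenario()] when no seed is passed).
#' @param ... Named overrides patched into the config before calibration
#'   (e.g. `n_neutral`, `run_timing = list(target_r2 = ...)`; list values
#'   are merged element-wise).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("coastal", "inland", "hood",
                                         "age25", "bonaff", "two_lineage"),
                            n = NULL, seed = 1L, ...) {
  scenario <- match.arg(scenario)
  n <- if (!is.null(n)) n else switch(scenario, age25 = 2000L,
                                      bonaff = 1538L, 400L)
  pool28_col <- switch(scenario,
                       coastal = "hood_hs", hood = "hood_hs",
                       inland = "bon_hv_int", age25 = "bon_hv_int",
                       bonaff = "bon_hv_all", two_lineage = "bon_hv_all")
  cfg <- list(
    scenario = scenario, n = as.integer(n), seed = as.integer(seed),
    lineages = switch(scenario,
                      coastal = c(coastal = 1), hood = c(coastal = 1),
                      two_lineage = c(coastal = 0.5, inland = 0.5),
                      c(inland = 1)),
    chr28_pool = haplotype_pool("chr28", pool28_col),
    chr25_pool = haplotype_pool("chr25", "bon_hs"),
    n_neutral = 230L,
    neutral_freq_range = c(0.1, 0.9),
    neutral_divergence = 1.0,      # SD of the between-lineage logit shift
    p_male = 1 / 2.67,             # females outnumber males 1.67:1
    missing_rate = 0,
    run_timing = list(
      causal_index = 6L,           # chromosome 28 region marker
      baseline = switch(scenario, coastal = 180, hood = 150, 130),
      effect = switch(scenario, coastal = 55, hood = 90, 30),
      lag0 = 7, sigma_lag = 2,
      het_arrival_shift = switch(scenario, coastal = 20, hood = 20, 10),
      target_r2 = switch(scenario, coastal = 0.51, hood = 0.51, 0.08),
      overwinter = scenario %in% c("inland", "age25", "bonaff",
                                   "two_lineage"),
      overwinter_threshold = 175,
      spring_base = 75, spring_slope = 0.15, sigma_winter = 12),
    age_length = list(
      causal_index = 5L,           # chromosome 25 region marker
      tau1 = stats::qnorm(0.25),   # female hom-short: 25% one-ocean
      beta_sex = stats::qnorm(0.25), # male shift: hom-short males 50%
      tau2 = 3.2,
      beta_base = 1.5,             # female latent effect per long copy
      age_means = c(57, 72, 82),   # cm at ocean ages 1, 2, 3+
      sex_len_offset = 4.9,        # males larger at same genotype
      target_r2_male = 0.170, target_r2_female = 0.111),
    detection = list(
      p_mortality = 0.05, p_dip_in = 0.03, p_repeat = 0.02,
      detection_prob = 1, anchor_year = 2016L),
    arrays = .default_arrays())
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]) &&
        !is.data.frame(dots[[nm]]) && !is.data.frame(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]   # element-wise patch
    } else {
      cfg[[nm]] <- dots[[nm]]                      # whole-object override
    }
  }
  # allele frequencies of the causal alleles implied by the pools
  cm28 <- cfg$run_timing$causal_index
  mature <- substr(cfg$chr28_pool$string[cfg$chr28_pool$label == "I"],
                   cm28, cm28)
  cfg$run_timing$mature_allele <- mature
  cfg$run_timing$p_mature <- sum(cfg$chr28_pool$freq[
    substr(cfg$chr28_pool$string, cm28, cm28) == mature])
  cm25 <- cfg$age_length$causal_index
  long <- substr(cfg$chr25_pool$string[cfg$chr25_pool$label == "I"],
                 cm25, cm25)
  cfg$age_length$long_allele <- long
  cfg$age_length$p_long <- sum(cfg$chr25_pool$freq[
    substr(cfg$chr25_pool$string, cm25, cm25) == long])
  # calibrate noise parameters to the configured variance shares
  cfg$run_timing$sigma_passage <-
    .solve_runtiming_sigma(cfg$run_timing, cfg$run_timing$p_mature)
  sol <- .solve_age_length(cfg$age_length, cfg$age_length$p_long)
  cfg$age_length$sigma_len <- sol$sigma_len
  cfg$age_length$male_mult <- sol$male_mult
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config '%s': n = %d, lineages = %s\n", x$scenario,
              x$n, paste(names(x$lineages), collapse = "+")))
  cat(sprintf("  run timing: effect %.0f d, sigma %.1f d (target R2 %.2f)\n",
              x$run_timing$effect, x$run_timing$sigma_passage,
              x$run_timing$target_r2))
  cat(sprintf(paste0("  age/length: beta %.2f (male x%.2f), sigma_len ",
                     "%.1f cm (targets %.3f/%.3f)\n"),
              x$age_length$beta_base, x$age_length$male_mult,
              x$age_length$sigma_len,
              x$age_length$target_r2_male, x$age_length$target_r2_female))
  invisible(x)
}

# seed scoping helper: runs expr under set.seed(seed), restoring RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# ---- genotype generation -----------------------------------------------

#' Generate genotypes from the scenario's haplotype pools
#'
#' Draws, per fish, a lineage, a sex, two independent chromosome 28 and two
#' chromosome 25 haplotypes from the lineage's pools, and neutral-marker
#' genotypes binomially from lineage-specific allele frequencies (logit
#' divergence between lineages).  The sdY-style sex marker carries dosage 2
#' for males.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to the config's seed).
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth` (per
#'   fish: lineage, sex, haplotype labels and causal dosages).
#' @export
gen_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(seed, {
    n <- config$n
    ids <- sprintf("F%04d", seq_len(n))
    lin <- sample(names(config$lineages), n, replace = TRUE,
                  prob = config$lineages)
    male <- stats::rbinom(n, 1, config$p_male)
    draw_pool <- function(pool) {
      i1 <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$freq)
      i2 <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$freq)
      list(h1 = pool$string[i1], h2 = pool$string[i2],
           l1 = pool$label[i1], l2 = pool$label[i2])
    }
    h28 <- draw_pool(config$chr28_pool)
    h25 <- draw_pool(config$chr25_pool)
    hap_dosage <- function(h, k, allele) {
      (substr(h$h1, k, k) == allele) + (substr(h$h2, k, k) == allele)
    }
    d28 <- hap_dosage(h28, config$run_timing$causal_index,
                      config$run_timing$mature_allele)
    d25 <- hap_dosage(h25, config$age_length$causal_index,
                      config$age_length$long_allele)
    # candidate-region dosage matrices (alt allele = non-reference state)
    mk28 <- region_markers("chr28")
    mk25 <- region_markers("chr25")
    hap_to_dos <- function(h, mk) {
      a1 <- do.call(rbind, strsplit(h$h1, ""))
      a2 <- do.call(rbind, strsplit(h$h2, ""))
      alt <- matrix(mk$alt_allele, nrow(a1), ncol(a1), byrow = TRUE)
      (a1 == alt) + (a2 == alt)
    }
    dos28 <- hap_to_dos(h28, mk28)
    dos25 <- hap_to_dos(h25, mk25)
    # neutral markers: lineage-specific frequencies, logit-divergent
    nn <- config$n_neutral
    p_base <- stats::runif(nn, config$neutral_freq_range[1],
                           config$neutral_freq_range[2])
    lns <- names(config$lineages)
    shifts <- stats::rnorm(nn * length(lns), 0, config$neutral_divergence)
    p_lin <- matrix(stats::plogis(stats::qlogis(p_base) + shifts),
                    nn, length(lns), dimnames = list(NULL, lns))
    dosN <- matrix(0L, n, nn)
    for (l in lns) {
      sel <- lin == l
      dosN[sel, ] <- matrix(stats::rbinom(sum(sel) * nn, 2,
                                          rep(p_lin[, l], each = sum(sel))),
                            sum(sel), nn)
    }
    mkN <- marker_table(sprintf("neut_%03d", seq_len(nn)),
                        chrom = rep("1", nn),
                        pos = seq_len(nn) * 10000L,
                        ref_allele = rep("A", nn), alt_allele = rep("G", nn),
                        panel_class = "neutral_candidate")
    mkS <- marker_table("sdY", "Y", 1000L, "X", "Y", panel_class = "sex")
    dos <- cbind(dosN, dos28, dos25, matrix(2L * male, n, 1))
    mk <- rbind(mkN, mk28, mk25, mkS)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow(dos))
      dos[mask] <- NA_integer_
    }
    G <- genotype_matrix(dos, ids, mk)
    truth <- data.frame(sample_id = ids, lineage = lin,
                        male = male, sex = ifelse(male == 1, "M", "F"),
                        chr28_hap1 = h28$l1, chr28_hap2 = h28$l2,
                        chr25_hap1 = h25$l1, chr25_hap2 = h25$l2,
                        d28 = d28, d25 = d25,
                        stringsAsFactors = FALSE)
    list(genotypes = G, truth = truth)
  })
}

# ---- phenotype generation ----------------------------------------------

#' Generate run-timing phenotypes
#'
#' Bonneville passage day is the lineage baseline plus the additive
#' mature-haplotype effect plus Gaussian noise (the calibrated
#' `sigma_passage`).  Fish that do not overwinter arrive `lag0` days later
#' (heterozygotes shifted toward the mature homozygotes by
#' `het_arrival_shift`); in overwintering scenarios, fish passing after the
#' threshold day hold over winter and arrive in a next-spring window
#' (ordinal > 365) whose date rises weakly with passage date.
#'
#' @param config A [scenario_config()].
#' @param truth Truth table from [gen_genotypes()].
#' @param seed Integer seed.
#' @return `truth` with `passage_day`, `arrival_day`, `overwintered` added.
#' @export
gen_run_timing <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "scenario_config"))
  rt <- config$run_timing
  .with_seed(seed, {
    n <- nrow(truth)
    t_lat <- rt$baseline + rt$effect * truth$d28 +
      stats::rnorm(n, 0, rt$sigma_passage)
    shift <- ifelse(truth$d28 == 1L, rt$het_arrival_shift, 0)
    ow <- rt$overwinter & t_lat > rt$overwinter_threshold
    arr <- ifelse(ow,
                  365 + rt$spring_base +
                    rt$spring_slope * (t_lat - rt$overwinter_threshold) +
                    shift + stats::rnorm(n, 0, rt$sigma_winter),
                  t_lat + rt$lag0 + shift + stats::rnorm(n, 0, rt$sigma_lag))
    truth$passage_day <- pmax(round(t_lat), 1L)
    truth$arrival_day <- pmax(round(arr), truth$passage_day)
    truth$overwintered <- ow
    truth
  })
}

#' Generate ocean-age and fork-length phenotypes
#'
#' Ocean age follows a latent probit threshold model:
#' `eta = beta * d25 + beta_sex * male + N(0,1)` cut at `tau1`/`tau2` into
#' ages 1 / 2 / 3+, where the locus effect `beta` is the base (female)
#' effect amplified by `male_mult` in males, with the hard constraint that
#' homozygous-short fish never reach age 3+.  Fork length is the age-class
#' mean plus the sex offset plus Gaussian noise (the calibrated
#' `sigma_len`).
#'
#' @inheritParams gen_run_timing
#' @return `truth` with `ocean_age` and `fork_length` added.
#' @export
gen_age_length <- function(config, truth, seed = config$seed + 2L) {
  stopifnot(inherits(config, "scenario_config"))
  al <- config$age_length
  .with_seed(seed, {
    n <- nrow(truth)
    b_eff <- al$beta_base * ifelse(truth$male == 1, al$male_mult, 1)
    eta <- b_eff * truth$d25 + al$beta_sex * truth$male + stats::rnorm(n)
    age <- ifelse(eta < al$tau1, 1L, ifelse(eta < al$tau2, 2L, 3L))
    age[truth$d25 == 0L & age == 3L] <- 2L   # hom-short never 3+ ocean
    truth$ocean_age <- age
    truth$fork_length <- al$age_means[age] +
      al$sex_len_offset * truth$male + stats::rnorm(n, 0, al$sigma_len)
    truth
  })
}

# ---- detection histories -----------------------------------------------

#' Generate PTAGIS-like detection histories
#'
#' Emits one detection table for the cohort.  Each fish is assigned a home
#' tributary array within its lineage and a history category: clean fish
#' produce Bonneville, en-route mainstem and tributary detections at their
#' true days; mainstem mortalities truncate at a mainstem dam; dip-in-only
#' fish end at a thermal-refuge mouth; repeat spawners duplicate the whole
#' migration about a year later.  Every emitted detection is kept with
#' probability `detection_prob` (default 1).
#'
#' @inheritParams gen_run_timing
#' @param truth Truth table containing `passage_day`/`arrival_day`.
#' @return List with `events` (detection data frame: `tag_id`, `site_code`,
#'   `river_km`, `date`), `sites` (the array table), and `truth` with
#'   `home_site` and `history_category` added.
#' @export
gen_detection_histories <- function(config, truth, seed = config$seed + 3L) {
  stopifnot(inherits(config, "scenario_config"))
  det <- config$detection
  sites <- config$arrays
  .with_seed(seed, {
    n <- nrow(truth)
    trib <- sites[sites$site_class == "tributary", ]
    home <- vapply(truth$lineage, function(l) {
      cand <- trib$site_code[trib$lineage == l]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    cat_probs <- c(clean = 1 - det$p_mortality - det$p_dip_in - det$p_repeat,
                   mainstem_mortality = det$p_mortality,
                   dip_in_only = det$p_dip_in,
                   repeat_spawner = det$p_repeat)
    category <- sample(names(cat_probs), n, replace = TRUE, prob = cat_probs)
    origin <- as.Date(sprintf("%d-01-01", det$anchor_year))
    day_to_date <- function(d) origin + (d - 1)
    km_of <- function(code) sites$river_km[match(code, sites$site_code)]
    ev <- vector("list", n)
    for (i in seq_len(n)) {
      tid <- truth$sample_id[i]
      p_day <- truth$passage_day[i]
      a_day <- truth$arrival_day[i]
      h_km <- km_of(home[i])
      dams <- sites[sites$site_class == "mainstem_dam" &
                      sites$river_km < h_km, ]
      mig <- function(offset = 0) {
        # en-route dam days interpolated along the mainstem course
        frac <- (dams$river_km - 234) / max(h_km - 234, 1)
        span <- min(a_day - p_day, 60)
        rows <- data.frame(
          tag_id = tid,
          site_code = c("BON", dams$site_code, home[i]),
          river_km = c(234, dams$river_km, h_km),
          date = day_to_date(c(p_day, round(p_day + frac * span), a_day) +
                               offset),
          stringsAsFactors = FALSE)
        rows
      }
      rows <- switch(category[i],
        clean = mig(),
        repeat_spawner = rbind(mig(), mig(offset = 365 + sample(0:6, 1))),
        mainstem_mortality = {
          # die en route at a mainstem site; with no dam below the home
          # tributary the last detection is Bonneville itself
          die_site <- if (nrow(dams)) {
            dams[sample.int(nrow(dams), 1), c("site_code", "river_km")]
          } else {
            data.frame(site_code = "BON", river_km = 234)
          }
          data.frame(tag_id = tid,
                     site_code = c("BON", die_site$site_code),
                     river_km = c(234, die_site$river_km),
                     date = day_to_date(c(p_day, p_day + sample(2:10, 1))),
                     stringsAsFactors = FALSE)
        },
        dip_in_only = {
          ref <- sites[sites$site_class == "thermal_refuge", ]
          ref <- ref[sample.int(nrow(ref), 1), , drop = FALSE]
          data.frame(tag_id = tid,
                     site_code = c("BON", ref$site_code),
                     river_km = c(234, ref$river_km),
                     date = day_to_date(c(p_day, p_day + sample(2:10, 1))),
                     stringsAsFactors = FALSE)
        })
      ev[[i]] <- rows
    }
    events <- do.call(rbind, ev)
    if (det$detection_prob < 1) {
      events <- events[stats::runif(nrow(events)) < det$detection_prob, ]
    }
    events <- events[order(events$tag_id, events$date), ]
    rownames(events) <- NULL
    truth$home_site <- home
    truth$history_category <- category
    list(events = events, sites = sites, truth = truth)
  })
}

#' Write a detection table as CSV
#'
#' @param events Detection data frame from [gen_detection_histories()].
#' @param path Output path.
#' @export
write_detections <- function(events, path) {
  ev <- events
  ev$date <- format(ev$date, "%Y-%m-%d")
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a full synthetic scenario
#'
#' Convenience wrapper chaining [gen_genotypes()], [gen_run_timing()],
#' [gen_age_length()] and [gen_detection_histories()], all derived from one
#' seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return List `config`, `genotypes`, `truth`, `events`, `sites`.
#' @export
simulate_scenario <- function(config, seed = config$seed) {
  gg <- gen_genotypes(config, seed)
  truth <- gen_run_timing(config, gg$truth, seed + 1L)
  truth <- gen_age_length(config, truth, seed + 2L)
  dh <- gen_detection_histories(config, truth, seed + 3L)
  list(config = config, genotypes = gg$genotypes, truth = dh$truth,
       events = dh$events, sites = dh$sites)
}
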