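# Synthetic allele-spectrum, sample, cohort and longitudinal generators.

test_that("degenerate spectra concentrate all reads where they must", {
  # no noise, no tumour: every read is the reference allele
  sp <- simulate_spectrum(clean_marker(), tumour_fraction = 0, depth = 1000,
                          seed = 1)
  expect_equal(sp$offsets, 0L)
  expect_equal(sp$counts, 1000)

  # pure tumour, fixed 4-nt deletion, no stutter: every read at offset -4
  sp <- simulate_spectrum(clean_marker(mean_del = 4, sd_del = 0),
                          tumour_fraction = 1, depth = 1000, seed = 2)
  expect_equal(sp$offsets, -4L)
  expect_equal(sp$counts, 1000)
})

test_that("spectrum counts sum to depth and frequencies to one", {
  for (tf in c(0, 0.17, 0.8)) {
    sp <- simulate_spectrum(mini_panel()$m3, tf, depth = 1234, seed = 5)
    expect_equal(sp$depth, 1234)
    expect_equal(sum(sp$counts), 1234)
    expect_equal(sum(sp$counts / sp$depth), 1)
  }
})

test_that("spectrum input validation rejects bad depth and fraction", {
  m <- mini_panel()$m1
  expect_error(simulate_spectrum(m, 0.5, depth = 0), "depth")
  expect_error(simulate_spectrum(m, 0.5, depth = -10), "depth")
  expect_error(simulate_spectrum(m, -0.1, depth = 100), "tumour_fraction")
  expect_error(simulate_spectrum(m, 1.2, depth = 100), "tumour_fraction")
})

# independent oracle: mixture pmf by direct enumeration with plain loops
brute_force_pmf <- function(marker, tf, max_step = 8L) {
  s <- marker$stutter_rate
  pk <- (1 - s) * s^(0:max_step)
  pk <- pk / sum(pk)
  acc <- new.env()
  add <- function(off, p) {
    key <- as.character(off)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  stutter <- function(base_off, w) {
    add(base_off, w * pk[1])
    for (k in 1:max_step) {
      add(base_off - k, w * pk[k + 1] * 0.75)
      add(base_off + k, w * pk[k + 1] * 0.25)
    }
  }
  stutter(0L, 1 - tf)
  dmax <- ceiling(marker$mmrd_deletion_mean + 4 * marker$mmrd_deletion_sd)
  wd <- dnorm(1:dmax, marker$mmrd_deletion_mean, marker$mmrd_deletion_sd)
  wd <- wd / sum(wd)
  for (d in 1:dmax) stutter(-d, tf * wd[d])
  offs <- sort(as.integer(ls(acc)))
  setNames(vapply(as.character(offs), function(k) acc[[k]], numeric(1)), offs)
}

test_that("simulated spectra match the analytic mixture pmf", {
  m <- default_panel()[["AKMmono02"]]
  tf <- 0.5
  oracle <- brute_force_pmf(m, tf)
  pmf <- spectrum_pmf(m, tf)
  expect_equal(setNames(pmf$prob, pmf$offset), oracle, tolerance = 1e-12)

  # empirical frequencies at depth 1e5 within 3 standard errors
  depth <- 1e5
  sp <- simulate_spectrum(m, tf, depth, seed = 99)
  emp <- setNames(rep(0, length(oracle)), names(oracle))
  emp[as.character(sp$offsets)] <- sp$counts / depth
  se <- sqrt(oracle * (1 - oracle) / depth)
  expect_true(all(abs(emp - oracle) <= 3 * se + 1e-12))
  # mixture weight on the two components recovered near 0.5/0.5: reads at
  # or above offset -1 are overwhelmingly background for this marker
  expect_lt(abs(sum(emp[as.integer(names(emp)) <= -3]) -
                  sum(oracle[as.integer(names(oracle)) <= -3])), 0.01)
})

test_that("simulate_sample covers the panel once, deterministically", {
  panel <- mini_panel()
  p <- simulate_sample(panel, 0.2, depth = 500, seed = 42)
  expect_named(p$spectra, names(panel))
  expect_s3_class(p, "sample_profile")

  # same seed -> identical; different seed -> different
  p2 <- simulate_sample(panel, 0.2, depth = 500, seed = 42)
  expect_identical(p, p2)
  p3 <- simulate_sample(panel, 0.2, depth = 500, seed = 43)
  expect_false(identical(p$spectra, p3$spectra))

  # duplicate marker ids rejected
  bad <- list(panel$m1, panel$m1)
  expect_error(simulate_sample(bad, 0.2, depth = 100, seed = 1), "duplicate")

  # zero tumour fraction with zero stutter: background only
  clean <- list(a = clean_marker(), b = clean_marker())
  clean$a$marker_id <- "a"; clean$b$marker_id <- "b"
  p0 <- simulate_sample(clean, 0, depth = 200, seed = 7)
  for (sp in p0$spectra) expect_equal(sp$offsets, 0L)
})

test_that("non-reference frequency increases with tumour fraction", {
  panel <- mini_panel()
  mean_vaf <- function(tf, seed) {
    p <- simulate_sample(panel, tf, depth = 300, seed = seed)
    mean(vapply(p$spectra, variant_allele_frequency, numeric(1)))
  }
  hi <- vapply(1:100, function(s) mean_vaf(0.2, s), numeric(1))
  lo <- vapply(1:100, function(s) mean_vaf(0.02, 500 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
  # analytic mixture means are monotone in tf as well
  m <- panel$m2
  vaf_expected <- function(tf) {
    pmf <- spectrum_pmf(m, tf)
    1 - pmf$prob[pmf$offset == 0]
  }
  grid <- vapply(seq(0, 1, by = 0.1), vaf_expected, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("cohort simulation matches its binomial design", {
  tiny_panel <- structure(list(m = marker_def("m", 20, stutter_rate = 0.1)),
                          class = "msi_panel")
  # symptomatic design, prevalence 0: never any MMRd subject
  cfg0 <- cohort_config(20, "symptomatic_utuc", mmrd_prevalence = 0,
                        depth_per_marker = 20, panel = tiny_panel, seed = 3)
  expect_false(any(vapply(simulate_cohort(cfg0), `[[`, logical(1),
                          "truth_mmrd_cancer")))

  # reproducibility: identical config -> identical cohort
  cfg <- cohort_config(15, "symptomatic_utuc", mmrd_prevalence = 0.084,
                       depth_per_marker = 20, panel = tiny_panel, seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  # n=50 at prevalence 8.4%: fraction of cohorts with >= 3 MMRd subjects
  # approximates the exact binomial tail 0.802 (the >80% design claim)
  n_rep <- 600
  counts <- vapply(seq_len(n_rep), function(r) {
    cfg <- cohort_config(50, "symptomatic_utuc", mmrd_prevalence = 0.084,
                         depth_per_marker = 20, panel = tiny_panel, seed = r)
    sum(vapply(simulate_cohort(cfg), `[[`, logical(1), "truth_mmrd_cancer"))
  }, numeric(1))
  frac3 <- mean(counts >= 3)
  exact <- binomial_design_at_least(50, 0.084, 3)
  expect_gt(exact, 0.80)
  expect_lt(abs(frac3 - exact), 3.5 * sqrt(exact * (1 - exact) / n_rep))
})

test_that("screening-design cohorts compound incidence over lead time", {
  tiny_panel <- structure(list(m = marker_def("m", 20, stutter_rate = 0.1)),
                          class = "msi_panel")
  p_eff <- 1 - (1 - 0.0075)^4
  n_rep <- 800
  hits <- vapply(seq_len(n_rep), function(r) {
    cfg <- cohort_config(70, "lynch_screening", annual_incidence = 0.0075,
                         lead_time_years = 4, depth_per_marker = 20,
                         panel = tiny_panel, seed = 10000 + r)
    any(vapply(simulate_cohort(cfg), `[[`, logical(1), "truth_mmrd_cancer"))
  }, logical(1))
  closed_form <- 1 - (1 - p_eff)^70
  expect_lt(abs(mean(hits) - closed_form),
            3.5 * sqrt(closed_form * (1 - closed_form) / n_rep))
  # config validation: the two designs take disjoint parameter sets
  expect_error(cohort_config(10, "lynch_screening", mmrd_prevalence = 0.1),
               "lynch_screening")
  expect_error(cohort_config(10, "symptomatic_utuc",
                             annual_incidence = 0.01, lead_time_years = 2),
               "symptomatic_utuc")
  expect_error(cohort_config(0, "symptomatic_utuc", mmrd_prevalence = 0.1),
               "n_subjects")
})

test_that("longitudinal trajectories respond to resection and recurrence", {
  tiny_panel <- structure(list(m = marker_def("m", 20, stutter_rate = 0.1)),
                          class = "msi_panel")
  cfg <- cohort_config(6, "lynch_screening", annual_incidence = 0.0075,
                       lead_time_years = 4, depth_per_marker = 100,
                       panel = tiny_panel, fixed_n_affected = 6, seed = 21)
  case <- simulate_cohort(cfg)[[1]]
  expect_gt(case$true_tumour_fraction, 0)

  # resection clears the signal
  ev <- data.frame(day = 10L, event = "resection")
  prof <- simulate_longitudinal(case, ev, c(0L, 20L), depth = 100,
                                panel = tiny_panel)
  expect_gt(prof[[1]]$true_tumour_fraction, 0)
  expect_equal(prof[[2]]$true_tumour_fraction, 0)

  # no events: constant fraction
  prof <- simulate_longitudinal(case, data.frame(day = integer(),
                                                 event = character()),
                                c(0L, 100L, 300L), depth = 100,
                                panel = tiny_panel)
  expect_equal(unique(vapply(prof, `[[`, numeric(1), "true_tumour_fraction")),
               case$true_tumour_fraction)

  # recurrence restores the signal after an earlier resection
  ev <- data.frame(day = c(10L, 500L), event = c("resection", "recurrence"))
  prof <- simulate_longitudinal(case, ev, c(100L, 600L), depth = 100,
                                panel = tiny_panel)
  expect_equal(prof[[1]]$true_tumour_fraction, 0)
  expect_equal(prof[[2]]$true_tumour_fraction, case$true_tumour_fraction)

  # unsorted events rejected
  bad <- data.frame(day = c(500L, 10L), event = c("recurrence", "resection"))
  expect_error(simulate_longitudinal(case, bad, 0L, depth = 100,
                                     panel = tiny_panel), "sorted")
})
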