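# Shared fixtures, built once per test run.

# small noise-free marker for degenerate-case checks
clean_marker <- function(mean_del = 4, sd_del = 0) {
  marker_def("clean", 20, stutter_rate = 0, mmrd_deletion_mean = mean_del,
             mmrd_deletion_sd = sd_del)
}

# four-marker panel for cheap simulations
mini_panel <- function() {
  structure(
    list(
      m1 = marker_def("m1", 20, stutter_rate = 0.06),
      m2 = marker_def("m2", 23, stutter_rate = 0.10),
      m3 = marker_def("m3", 25, stutter_rate = 0.13),
      m4 = marker_def("m4", 27, stutter_rate = 0.16)
    ),
    class = "msi_panel"
  )
}

# training set and classifier on the full 14-marker default panel;
# MSI-H class at log-uniform tumour fractions 0.05-0.5, MSS at 0
.fixture_env <- new.env()

shared_training <- function() {
  if (is.null(.fixture_env$training)) {
    panel <- default_panel()
    tfs <- with_fixed_seed(11, exp(runif(60, log(0.05), log(0.5))))
    msih <- lapply(seq_len(60), function(i) {
      simulate_sample(panel, tfs[i], 2000, "urine", seed = 20000 + i,
                      sample_id = paste0("trainH", i))
    })
    mss <- lapply(seq_len(60), function(i) {
      simulate_sample(panel, 0, 2000, "urine", seed = 30000 + i,
                      sample_id = paste0("trainS", i))
    })
    .fixture_env$training <- list(
      profiles = c(msih, mss),
      labels = rep(c("MSI_H", "MSS"), each = 60),
      tfs = tfs
    )
  }
  .fixture_env$training
}

shared_model <- function() {
  if (is.null(.fixture_env$model)) {
    tr <- shared_training()
    .fixture_env$model <- train_classifier(tr$profiles, tr$labels)
  }
  .fixture_env$model
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# minimal score result for workflow-rule tests
fake_result <- function(score, sample_id = "s") {
  cl <- classify(score)
  structure(
    list(sample_id = sample_id, per_marker_log_ratio = setNames(score, "m1"),
         msi_score = score, call = cl$call, borderline = cl$borderline,
         qc_pass = TRUE, markers_used = 1L),
    class = "msi_score_result"
  )
}

fake_case <- function(outcome, followup = 567L, subject_id = "x",
                      samples = list()) {
  structure(
    list(subject_id = subject_id, cohort = "lynch", samples = samples,
         truth_mmrd_cancer = outcome, outcome_cancer_within_followup = outcome,
         followup_days = as.integer(followup), true_tumour_fraction = NULL,
         marker_instability = NULL, seed = 1L),
    class = "case_record"
  )
}
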