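test_that("phantom parameters are validated", {
  expect_error(phantom_params(pair_distribution = matrix(1 / 8, 3, 3)),
               "sum to 1")
  expect_error(phantom_params(haziness_levels = c(0.5, 0.3, 0.9)),
               "increasing")
  expect_error(phantom_params(image_height_px = 50, image_width_px = 60,
                              pixel_spacing_mm = 1),
               "too small")
})

test_that("subjects are bitwise reproducible from their seed", {
  params <- quiet_phantom_params(noise_sd = 30, asymmetry_jitter_mm = 1)
  a <- generate_subject(params, "s1", seed = 7)
  b <- generate_subject(params, "s1", seed = 7)
  expect_identical(a, b)
  c <- generate_subject(params, "s1", seed = 8)
  expect_false(identical(a$ap_view$pixels, c$ap_view$pixels))
})

test_that("a jitter-free noise-free subject is exactly mirror symmetric", {
  params <- quiet_phantom_params()
  s <- generate_subject(params, "s1", seed = 5, force_pair = c(0L, 0L))
  px <- s$ap_view$pixels
  W <- ncol(px)
  expect_identical(px[, 1:(W / 2)], px[, W:(W / 2 + 1)])
})

test_that("air-cell region intensity increases strictly with category", {
  params <- quiet_phantom_params()
  means <- vapply(0:2, function(cat) {
    s <- generate_subject(params, "s1", seed = 42,
                          force_pair = c(cat, cat))
    crops <- crop_ears(s$ap_view)
    mean(crops$right$pixels)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohorts round-trip through DICOM and match their label table", {
  dir <- withr::local_tempdir()
  params <- phantom_params(n_subjects = 5L, image_height_px = 250L,
                           image_width_px = 200L, pixel_spacing_mm = 2,
                           seed = 3L)
  cohort <- generate_cohort(params, dir = dir)
  tab <- read_label_table(file.path(dir, "labels.csv"))
  expect_equal(nrow(tab), 5)
  for (i in seq_len(5)) {
    truth <- cohort$studies[[i]]$truth
    expect_equal(tab$right[i], truth$right)
    expect_equal(tab$grade[i], truth$grade)
    view <- read_ap_view(file.path(dir, paste0(truth$subject_id, ".dcm")))
    expect_equal(view$row_spacing_mm, 2)
    expect_equal(dim(view$pixels), c(250L, 200L))
    expect_lt(max(abs(view$pixels - cohort$studies[[i]]$ap_view$pixels)), 0.5)
  }
})

test_that("pair frequencies follow the configured joint distribution", {
  params <- phantom_params(n_subjects = 600L, image_height_px = 250L,
                           image_width_px = 200L, pixel_spacing_mm = 2,
                           pair_distribution = matrix(1 / 9, 3, 3), seed = 9L)
  # draw only the category pairs (cheap path: force nothing, small images)
  counts <- matrix(0L, 3, 3)
  for (i in seq_len(600)) {
    set.seed(params$seed + i)
    k <- sample.int(9L, 1L, prob = as.vector(params$pair_distribution))
    r <- (k - 1L) %% 3L; l <- (k - 1L) %/% 3L
    counts[r + 1, l + 1] <- counts[r + 1, l + 1] + 1L
  }
  # multinomial: each cell 600/9 +- 3 sd
  expected <- 600 / 9
  sd3 <- 3 * sqrt(600 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - expected) <= sd3))
  # the drawn pairs match what generate_subject reports for the same seeds
  s <- generate_subject(params, "s1", seed = params$seed + 1L)
  set.seed(params$seed + 1L)
  k <- sample.int(9L, 1L, prob = as.vector(params$pair_distribution))
  expect_equal(s$truth$right, (k - 1L) %% 3L)
  expect_equal(s$truth$left, (k - 1L) %/% 3L)
})

test_that("grade distribution is the pushforward of the pair distribution", {
  pd <- default_pair_distribution()
  grade_prob <- c(sum(diag(pd)),
                  pd[1, 2] + pd[2, 1] + pd[2, 3] + pd[3, 2],
                  pd[1, 3] + pd[3, 1])
  expect_equal(sum(grade_prob), 1)
  params <- phantom_params(n_subjects = 400L, image_height_px = 250L,
                           image_width_px = 200L, pixel_spacing_mm = 2,
                           seed = 13L)
  cohort <- generate_cohort(params)
  grades <- vapply(cohort$studies, function(s) s$truth$grade, integer(1))
  lab_grades <- abs(cohort$labels$right_category - cohort$labels$left_category)
  expect_identical(grades, lab_grades)  # deterministic mapping
  emp <- tabulate(grades + 1L, 3) / 400
  expect_true(all(abs(emp - grade_prob) < 3 * sqrt(grade_prob * (1 - grade_prob) / 400)))
})

test_that("benchmark preset is valid and mild is subtler than severe per ear", {
  params <- default_benchmark_params(n_subjects = 10L)
  expect_s3_class(params, "PhantomParams")
  expect_equal(params$pixel_spacing_mm, 2)
  # Monte-Carlo single-ear separability oracle: mean-intensity threshold
  # classifier over independent subjects
  n <- 300
  m_normal <- numeric(n); m_mild <- numeric(n); m_severe <- numeric(n)
  noisy <- phantom_params(n_subjects = 1L, image_height_px = 250L,
                          image_width_px = 200L, pixel_spacing_mm = 2,
                          anatomy_variation = params$anatomy_variation,
                          asymmetry_jitter_mm = params$asymmetry_jitter_mm,
                          haziness_levels = params$haziness_levels,
                          noise_sd = params$noise_sd)
  for (i in seq_len(n)) {
    cats <- c((i %% 3), ((i + 1) %% 3))
    s <- generate_subject(noisy, "x", seed = 3000 + i,
                          force_pair = c(0L, 0L))
    m_normal[i] <- mean(crop_ears(s$ap_view)$right$pixels)
    s <- generate_subject(noisy, "x", seed = 3000 + i,
                          force_pair = c(1L, 1L))
    m_mild[i] <- mean(crop_ears(s$ap_view)$right$pixels)
    s <- generate_subject(noisy, "x", seed = 3000 + i,
                          force_pair = c(2L, 2L))
    m_severe[i] <- mean(crop_ears(s$ap_view)$right$pixels)
  }
  # per-ear Bayes-style separability via the threshold oracle (AUC of the
  # pixel-mean score); mild must be harder than severe
  auc_mild <- roc_auc(c(m_normal, m_mild), rep(0:1, each = n))
  auc_severe <- roc_auc(c(m_normal, m_severe), rep(0:1, each = n))
  expect_gt(auc_severe, auc_mild)
  expect_lt(auc_mild, 0.95)  # mild is genuinely ambiguous from one side
})
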