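test_that("default group specs carry the calibrated statistics", {
  specs <- default_group_specs()
  expect_equal(unname(specs$ALS$means["left_stride"]), 1.520)
  expect_equal(unname(specs$ALS$sds["left_stride"]), 0.093)
  expect_equal(unname(specs$CO$means["double_support"]), 0.345)
  expect_equal(unname(specs$CO$sds["double_support"]), 0.057)
  ns <- vapply(specs, function(s) s$n_subjects, integer(1))
  expect_equal(unname(ns), c(13L, 15L, 20L, 16L))
  expect_equal(sum(ns), 64L)
})

test_that("separated specs push every disease mean 3 pooled SDs from CO", {
  specs <- separated_group_specs(3)
  co <- specs$CO
  for (g in c("ALS", "PD", "HD")) {
    pooled <- sqrt((specs[[g]]$sds^2 + co$sds^2) / 2)
    gap <- abs(specs[[g]]$means - co$means) / pooled
    expect_true(all(gap >= 3 - 1e-12))
  }
  # ALS stride already exceeded 3 pooled SDs: left untouched
  expect_equal(unname(specs$ALS$means["left_stride"]), 1.520)
})

test_that("degenerate noise collapses strides to the group mean", {
  spec <- group_spec("CO", 1, means = rep(1, 5), sds = rep(0, 5),
                     phi = 0, rho = 0, between_frac = 0, turn_sd_mult = 0)
  rec <- generate_subject(spec, "co01", seed = 1, n_strides = 40)
  expect_true(all(rec$features[, MODEL_FEATURES] == 1))
  expect_equal(rec$time, cumsum(rep(1, 40)))
})

test_that("records are deterministic under a seed and positive-valued", {
  spec <- default_group_specs()$HD
  r1 <- generate_subject(spec, "hd01", seed = 99)
  r2 <- generate_subject(spec, "hd01", seed = 99)
  expect_identical(r1$features, r2$features)
  expect_true(all(r1$features[, MODEL_FEATURES] > 0))
  expect_true(all(diff(r1$time) > 0))
  r3 <- generate_subject(spec, "hd01", seed = 100)
  expect_false(identical(r1$features, r3$features))
})

test_that("large samples recover the spec's mean and SD", {
  spec <- default_group_specs()$ALS
  rec <- generate_subject(spec, "als01", seed = 2024, n_strides = 50000)
  keep <- setdiff(seq_len(50000), attr(rec, "turn_indices"))
  V <- rec$features[keep, MODEL_FEATURES]
  # AR(1) inflates the SE of the mean by sqrt((1+phi)/(1-phi)); the
  # subject's own mean offset adds between_frac * sd on top.
  infl <- sqrt((1 + spec$phi) / (1 - spec$phi))
  for (j in MODEL_FEATURES) {
    se <- spec$sds[j] / sqrt(length(keep)) * infl
    tol <- 3 * se + 3 * spec$between_frac * spec$sds[j]
    expect_lt(abs(mean(V[, j]) - spec$means[j]), tol)
    expect_lt(abs(sd(V[, j]) - spec$sds[j] * sqrt(1 - spec$between_frac^2)),
              0.1 * spec$sds[j])
  }
})

test_that("planted turns are exactly recovered by segmentation", {
  specs <- default_group_specs()
  for (g in names(specs)) {
    rec <- generate_subject(specs[[g]], paste0(tolower(g), "01"),
                            seed = 300 + match(g, names(specs)))
    turns <- attr(rec, "turn_indices")
    expect_true(length(turns) >= 3)
    seg <- longest_turn_free_segment(rec)  # default robust rule
    gaps <- diff(c(0, turns, n_strides(rec) + 1L)) - 1L
    starts <- c(1L, turns + 1L)
    best <- which.max(gaps)
    expect_equal(unname(attr(seg, "segment")),
                 c(starts[best], starts[best] + gaps[best] - 1L))
  }
})

test_that("cohorts are reproducible and land on disk intact", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(default_group_specs(), seed = 5, dir = dir)
  expect_equal(nrow(coh$manifest), 64L)
  expect_equal(unname(table(coh$manifest$group)[GAIT_GROUPS]),
               c(13L, 15L, 20L, 16L), ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(length(list.files(dir, pattern = "\\.ts$")), 64L)

  # severity sampling reproduces the 9-severe strata for PD and HD
  expect_equal(sum(coh$manifest$group == "PD" & coh$manifest$severity >= 3),
               9L)
  expect_equal(sum(coh$manifest$group == "HD" & coh$manifest$severity <= 5),
               9L)

  # regeneration under the same seed is byte-identical on disk
  dir2 <- withr::local_tempdir()
  generate_cohort(default_group_specs(), seed = 5, dir = dir2)
  for (fn in c("als01.ts", "pd07.ts", "co16.ts", "manifest.tsv"))
    expect_identical(readLines(file.path(dir, fn)),
                     readLines(file.path(dir2, fn)))

  # and the files round-trip through the reader
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  recs <- read_cohort(man, dir)
  expect_equal(n_strides(recs$als01), n_strides(coh$records$als01))
  expect_equal(recs$als01$features[, MODEL_FEATURES],
               coh$records$als01$features[, MODEL_FEATURES],
               tolerance = 1e-6)
})

test_that("infeasible correlation settings raise a spec error", {
  spec <- default_group_specs()$CO
  spec$rho <- -0.5  # constructor forbids this; force it to hit the check
  expect_error(generate_subject(spec, "x", seed = 1),
               "positive definite")
  expect_error(group_spec("CO", 1, means = rep(1, 5), sds = rep(1, 5),
                          rho = 1.2))
})
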