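test_that("fraction_bound matches the mass-action bisection root", {
  # closed-form special cases
  expect_equal(fraction_bound(1, 0.5, 0), 0.5)           # stoichiometric limit
  expect_equal(fraction_bound(1, 0, 5), 0)               # no ligand
  expect_equal(fraction_bound(1, 1, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # bisection oracle across regimes
  for (kd in c(0.01, 0.5, 3, 50)) {
    for (et in c(0.05, 1, 10, 100)) {
      expect_equal(fraction_bound(1, et, kd),
                   bisect_fraction_bound(1, et, kd), tolerance = 1e-9)
    }
  }
  expect_error(fraction_bound(-1, 1, 1), class = "raseffector_error_domain")
  expect_error(fraction_bound(1, -1, 1), class = "raseffector_error_domain")
  expect_error(fraction_bound(1, 1, -1), class = "raseffector_error_domain")
})

test_that("fraction_bound is monotone and converges to the hyperbola", {
  et <- exp(seq(log(0.05), log(100), length.out = 50))
  fb <- fraction_bound(1, et, 2)
  expect_true(all(diff(fb) > 0))                          # increasing in E_t
  expect_true(all(fraction_bound(1, et, 5) <= fb + 1e-12))# decreasing in kd
  expect_true(all(fb >= 0 & fb <= pmin(1, et / 1)))
  # hyperbolic (no-depletion) limit for R_t << K_d
  kd <- 10; rt <- kd / 100
  hyp <- et / (et + kd)
  expect_true(all(abs(fraction_bound(rt, et, kd) - hyp) / hyp < 0.01))
})

test_that("model_signal reproduces limits", {
  des <- titration_design()
  # no binding limit
  expect_true(all(abs(model_signal(des, 1e9, 0, 1)) < 1e-4))
  # saturation at kd = 0 for E_t >= R_t
  s <- model_signal(des, 0, 0, 1)
  expect_true(all(s[des$ligand_total >= 1] == 1))
  # anchored derived value
  d1 <- titration_curve(1, receptor_total = 1)
  expect_equal(model_signal(d1, 1, 0, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
})

test_that("noise-free fits recover the generating constants", {
  des <- titration_design()
  # strong binder
  f1 <- fit_titration(titration_curve(des$ligand_total,
                                      model_signal(des, 0.094, 0, 1)))
  expect_lt(abs(f1$kd - 0.094) / 0.094, 1e-3)
  expect_true(f1$converged)
  # weak binder: saturation incomplete over the span
  f2 <- fit_titration(titration_curve(des$ligand_total,
                                      model_signal(des, 204.7, 0, 1)))
  expect_lt(abs(f2$kd - 204.7) / 204.7, 1e-2)
  # round-trip across the dynamic range, arbitrary endpoint signals
  for (kd in c(0.05, 0.5, 5, 50, 200)) {
    cur <- titration_curve(des$ligand_total,
                           model_signal(des, kd, 120, 260))
    f <- fit_titration(cur)
    expect_lt(abs(f$kd - kd) / kd, 1e-2)
    expect_equal(f$p_free, 120, tolerance = 1e-3)
    expect_equal(f$p_bound, 260, tolerance = 1e-3)
    expect_lt(f$residual_norm, 1e-8)
  }
})

test_that("degenerate and undersized curves are rejected", {
  des <- titration_design()
  flat <- titration_curve(des$ligand_total, rep(0.5, nrow(des)))
  expect_error(fit_titration(flat), class = "raseffector_error_degenerate_data")
  small <- titration_curve(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_error(fit_titration(small), class = "raseffector_error_insufficient_data")
  expect_error(titration_curve(c(2, 1), c(0, 1)), class = "raseffector_error_domain")
})

test_that("tidy, glance and autoplot expose the fit", {
  cur <- make_titration(kd_true = 0.5, noise_sd = 0.01, seed = 11)
  f <- fit_titration(cur)
  td <- tidy(f)
  expect_equal(td$term, c("kd", "p_free", "p_bound"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 24)
  expect_true(is.finite(gl$stderr_kd) && gl$stderr_kd > 0)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("replicate summaries use the standard error of the mean", {
  expect_equal(replicate_summary(c(1, 1, 1)),
               tibble::tibble(mean_kd = 1, sem_kd = 0, n = 3L))
  out <- replicate_summary(c(0.9, 1.1))
  expect_equal(out$mean_kd, 1.0)
  expect_equal(out$sem_kd, 0.1, tolerance = 1e-12)
  expect_error(replicate_summary(1.0),
               class = "raseffector_error_insufficient_replicates")
})

test_that("titration TSV reader handles uM and nM units", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cur <- make_titration(kd_true = 2.5, seed = 3)
  readr::write_tsv(tibble::tibble(ligand_total_uM = cur$ligand_total,
                                  polarization = cur$signal), path)
  back <- read_titration_tsv(path)
  expect_equal(back$ligand_total, cur$ligand_total)
  f <- fit_titration(back)
  expect_lt(abs(f$kd - 2.5) / 2.5, 1e-2)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(ligand_total_nM = cur$ligand_total * 1000,
                                  polarization = cur$signal), path2)
  back2 <- read_titration_tsv(path2)
  expect_equal(back2$ligand_total, cur$ligand_total)
})

test_that("the reference affinity table has the published shape", {
  ref <- reference_kd_table()
  expect_equal(nrow(ref), 25)
  expect_equal(length(unique(ref$effector)), 5)
  expect_equal(length(unique(ref$ras)), 5)
  expect_true(all(ref$kd_um > 0))
  expect_equal(min(ref$kd_um), 0.048)  # tightest pair: NRAS / CRAF-RB
  expect_equal(ref$kd_um[ref$ras == "HRAS" & ref$effector == "CRAF-RB"], 0.094)
})
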