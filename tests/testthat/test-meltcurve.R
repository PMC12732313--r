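# Melt-curve smoothing/differentiation, trough detection with
# contaminant exclusion, and paired delta-Tm statistics.

biphasic_truth <- function(noise_sd = 0)
  melt_truth(data.frame(midpoint_C = c(43.8, 52.5), steepness = 0.8,
                        amplitude = c(800, 1500)), noise_sd = noise_sd)

test_that("smoothed derivatives reproduce closed forms", {
  temp <- seq(20, 95, 0.5)
  ramp <- data.frame(temp_C = temp, fluorescence = 3 * temp + 7)
  d1 <- smooth_and_differentiate(ramp, order = 1)
  expect_equal(d1$deriv, rep(-3, length(temp)), tolerance = 1e-9)
  d2 <- smooth_and_differentiate(ramp, order = 2)
  expect_equal(d2$deriv, rep(0, length(temp)), tolerance = 1e-9)
  quad <- data.frame(temp_C = temp, fluorescence = (temp - 50)^2)
  dq <- smooth_and_differentiate(quad, order = 2)
  expect_equal(dq$deriv, rep(-2, length(temp)), tolerance = 1e-6)
  expect_error(smooth_and_differentiate(ramp[1:5, ], window = 7),
               "shorter")
  expect_error(smooth_and_differentiate(ramp, window = 6), "window")
})

test_that("biphasic curves yield both reference melting temperatures", {
  cur <- gen_melt_curve(biphasic_truth(), seed = 1)
  tms <- melt_tms(cur)
  expect_equal(nrow(tms), 2)
  expect_equal(tms$tm[1], 43.8, tolerance = 0.5)
  expect_equal(tms$tm[2], 52.5, tolerance = 0.5)
  expect_lt(tms$tm[1], tms$tm[2])
  # parabolic refinement keeps noiseless error below half a grid step
  expect_lt(max(abs(tms$tm - c(43.8, 52.5))), 0.25)
})

test_that("the contaminant exclusion window removes the ~68 C trough", {
  tri <- melt_truth(data.frame(midpoint_C = c(43.8, 52.5, 68),
                               steepness = 0.8,
                               amplitude = c(800, 1500, 1200)))
  cur <- gen_melt_curve(tri, seed = 1)
  # without exclusion the 68 C contaminant competes for the two slots
  raw <- melt_tms(cur, max_peaks = 3)
  expect_equal(nrow(raw), 3)
  kept <- melt_tms(cur, max_peaks = 2, exclusion_window = c(66, 70))
  expect_equal(nrow(kept), 2)
  expect_equal(kept$tm, c(43.8, 52.5), tolerance = 0.5)
})

test_that("monophasic curves report a single Tm", {
  mono <- gen_melt_curve(melt_truth(data.frame(
    midpoint_C = 50, steepness = 1, amplitude = 1000)), seed = 2)
  tms <- melt_tms(mono, max_peaks = 2)
  expect_equal(nrow(tms), 1)
  expect_equal(tms$tm, 50, tolerance = 0.5)
})

test_that("Tm extraction is shift-equivariant and amplitude-invariant", {
  cur <- gen_melt_curve(biphasic_truth(), seed = 3)
  base <- melt_tms(cur)
  shifted <- cur
  shifted$temp_C <- cur$temp_C + 2.5
  expect_equal(melt_tms(shifted)$tm, base$tm + 2.5, tolerance = 1e-9)
  scaled <- cur
  scaled$fluorescence <- cur$fluorescence * 7
  expect_equal(melt_tms(scaled)$tm, base$tm, tolerance = 1e-9)
})

test_that("weak shoulders fall back to the second derivative", {
  # two transitions only ~4.4 C apart (the R597A-variant pattern): the
  # first derivative merges them into one trough, the second
  # derivative resolves the shoulder, mirroring melting tables that
  # flag Tm1 as second-derivative-called
  shoulder <- melt_truth(data.frame(midpoint_C = c(44, 48.4),
                                    steepness = 0.8,
                                    amplitude = c(800, 1500)))
  cur <- gen_melt_curve(shoulder, seed = 4)
  d1 <- smooth_and_differentiate(cur, order = 1)
  expect_equal(nrow(suppressWarnings(find_tms(d1, max_peaks = 2))), 1)
  tms <- melt_tms(cur, max_peaks = 2)
  expect_equal(nrow(tms), 2)
  # the shoulder is a second-derivative call, the dominant transition a
  # first-derivative call
  expect_setequal(tms$deriv_order, c(2, 1))
  expect_lt(tms$tm[1], tms$tm[2])
  expect_equal(tms$tm[2], 48.4, tolerance = 0.5)
  # second-derivative shoulder calls sit below the true midpoint by
  # about 1.3 / steepness degrees
  expect_equal(tms$tm[1], 44 - 1.317 / 0.8, tolerance = 0.8)
})

test_that("replicate analysis and paired delta-Tm follow the pairing", {
  reps <- function(truth, n, cond, seed0)
    do.call(rbind, lapply(seq_len(n), function(r)
      gen_melt_curve(truth, seed = seed0 + r, replicate = r,
                     condition = cond)))
  apo <- analyze_melt(reps(biphasic_truth(noise_sd = 4), 3, "apo", 10))
  expect_s3_class(apo, "melt_result")
  expect_equal(nrow(apo$summary), 2)
  expect_equal(apo$summary$mean, c(43.8, 52.5), tolerance = 0.5)
  # identical paired curves: delta 0 +/- 0
  d0 <- delta_tm(apo, apo)
  expect_equal(d0$mean_dtm, c(0, 0))
  expect_equal(d0$sd_dtm, c(0, 0))
  # ligand stabilizes the second transition by 1.8 C
  lig_truth <- melt_truth(data.frame(midpoint_C = c(43.8, 54.3),
                                     steepness = 0.8,
                                     amplitude = c(800, 1500)),
                          noise_sd = 4)
  lig <- analyze_melt(reps(lig_truth, 3, "ligand", 20))
  dtm <- delta_tm(apo, lig)
  expect_equal(dtm$mean_dtm[2], 1.8, tolerance = 0.3)
  expect_equal(dtm$mean_dtm[1], 0, tolerance = 0.3)
  # hand-checked paired arithmetic
  fake <- function(tms_by_rep) {
    per <- do.call(rbind, lapply(seq_along(tms_by_rep), function(r)
      data.frame(replicate = as.character(r), tm_index = 1,
                 tm = tms_by_rep[[r]], deriv_order = 1)))
    structure(list(per_replicate = per, summary = NULL),
              class = "melt_result")
  }
  d <- delta_tm(fake(list(52.5, 52.5, 52.5)),
                fake(list(54.3, 54.1, 54.5)))
  expect_equal(d$mean_dtm, 1.8, tolerance = 1e-12)
  expect_equal(d$sd_dtm, 0.2, tolerance = 1e-12)
  # unpaired replicates are an error
  expect_error(delta_tm(fake(list(52, 52)), fake(list(54))), "unpaired")
})

test_that("mean paired difference equals difference of means when balanced", {
  a <- list(52.5, 52.7, 52.3); b <- list(54.3, 54.0, 54.6)
  fake <- function(x) {
    per <- do.call(rbind, lapply(seq_along(x), function(r)
      data.frame(replicate = as.character(r), tm_index = 1, tm = x[[r]],
                 deriv_order = 1)))
    structure(list(per_replicate = per, summary = NULL),
              class = "melt_result")
  }
  d <- delta_tm(fake(a), fake(b))
  expect_equal(d$mean_dtm,
               mean(unlist(b)) - mean(unlist(a)), tolerance = 1e-12)
})
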