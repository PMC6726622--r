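test_that("plate_readout validates structure and matched controls", {
  pl <- make_plates(generator_config(1, "cells"))
  expect_s3_class(pl$readout, "plate_readout")
  df <- as.data.frame(pl$readout)
  # drop the no-PS dose-0 control of one experiment: must be caught
  broken <- df[!(df$experiment_id == "E1" & df$dose_Gy == 0 &
                   !df$ps_present & !df$is_blank), ]
  expect_error(plate_readout(broken), "matched dose-0 control")
  expect_error(plate_readout(df[, -2]), "missing column")
  too_few <- df[-(which(df$experiment_id == "E1" & df$dose_Gy == 2 &
                          df$ps_present)[1]), ]
  expect_error(plate_readout(too_few), "fewer than 3")
})

test_that("a condition compared to itself has viability exactly 1", {
  pl <- make_plates(generator_config(2, "cells"))
  vr <- compute_viability(pl$readout)
  controls <- vr[vr$dose_Gy == 0, ]
  expect_true(all(controls$viability == 1))
  expect_true(all(vr$n_wells >= 3))
})

test_that("programmed viability is recovered within 2 SEM in >= 95% of seeded runs", {
  # true sampling SEM of the viability ratio for 3 wells at 5% noise in both
  # the dose arm and its matched control
  sem_true <- 0.6 * 0.05 * sqrt(2 / 3)
  hits <- 0L
  n_runs <- 200L
  for (s in seq_len(n_runs)) {
    set.seed(s)
    vr <- compute_viability(make_mini_plate(0.6))
    row <- vr[vr$dose_Gy == 2, ]
    hits <- hits + (abs(row$viability - 0.6) <= 2 * sem_true)
  }
  # nominal coverage of a 2-SEM interval is 95.4%; allow the binomial
  # sampling margin of a 200-run check
  expect_gte(hits / n_runs, 0.95 - 2 * sqrt(0.95 * 0.05 / n_runs))
})

test_that("blank-level wells give near-zero viability", {
  set.seed(8)
  df <- rbind(
    data.frame(well = paste0("c", 1:3), absorbance = 1.0 + rnorm(3, 0, 0.01),
               dose_Gy = 0, ps_present = FALSE, ps_uM = 0,
               experiment_id = "E1", is_blank = FALSE),
    data.frame(well = paste0("d", 1:3),
               absorbance = 0.08 + rnorm(3, 0, 0.001),
               dose_Gy = 5, ps_present = FALSE, ps_uM = 0,
               experiment_id = "E1", is_blank = FALSE),
    data.frame(well = paste0("b", 1:3), absorbance = rep(0.08, 3),
               dose_Gy = 0, ps_present = FALSE, ps_uM = 0,
               experiment_id = "E1", is_blank = TRUE))
  vr <- compute_viability(plate_readout(df))
  expect_lt(abs(vr$viability[vr$dose_Gy == 5]), 0.02)
})

test_that("differential gain is zero for identical arms and aggregates permutation-invariantly", {
  pl <- make_plates(generator_config(3, "cells"))
  vr <- compute_viability(pl$readout)
  # force identical +-PS viabilities
  vr_eq <- vr
  for (i in which(vr_eq$ps_present)) {
    j <- which(vr_eq$experiment_id == vr_eq$experiment_id[i] &
                 vr_eq$dose_Gy == vr_eq$dose_Gy[i] & !vr_eq$ps_present)
    vr_eq$viability[i] <- vr_eq$viability[j]
  }
  dg <- differential_gain(vr_eq)
  expect_true(all(abs(dg$gains$gain_points) < 1e-12))

  dg1 <- differential_gain(vr)
  # permuting experiment order leaves the pooled aggregate unchanged
  perm <- vr[order(rev(as.character(vr$experiment_id)), vr$dose_Gy), ]
  attr(perm, "wells") <- attr(vr, "wells")
  class(perm) <- class(vr)
  dg2 <- differential_gain(perm)
  expect_equal(sort(dg1$gains$gain_points), sort(dg2$gains$gain_points))
  expect_equal(dg1$mean_gain, dg2$mean_gain)
  expect_equal(dg1$median_gain, dg2$median_gain)
})

test_that("a dose tested once only yields no p-value", {
  set.seed(12)
  mk <- function(dose, ps, n, surv)
    data.frame(well = paste0(dose, ps, seq_len(n)),
               absorbance = 0.08 + surv * (1 + 0.03 * rnorm(n)),
               dose_Gy = dose, ps_present = ps, ps_uM = 0,
               experiment_id = "E1", is_blank = FALSE)
  df <- rbind(mk(0, FALSE, 3, 1), mk(0, TRUE, 3, 1),
              mk(15, FALSE, 3, 0.4), mk(15, TRUE, 3, 0.25),
              data.frame(well = paste0("b", 1:3), absorbance = rep(0.08, 3),
                         dose_Gy = 0, ps_present = FALSE, ps_uM = 0,
                         experiment_id = "E1", is_blank = TRUE))
  ro <- plate_readout(df)
  vr <- compute_viability(ro)
  # single-well arms (tested once only): shrink to n = 1 per side
  wells <- attr(vr, "wells")
  keep <- !(wells$dose_Gy == 15) |
    !duplicated(wells[, c("dose_Gy", "ps_present")])
  attr(vr, "wells") <- wells[keep, ]
  dg <- differential_gain(vr)
  expect_true(is.na(dg$gains$p_value[dg$gains$dose_Gy == 15]))
  # with full replicates the test runs
  dg_full <- differential_gain(compute_viability(ro))
  expect_false(is.na(dg_full$gains$p_value[dg_full$gains$dose_Gy == 15]))
})

test_that("LQ survival with proton-dynamic term behaves as designed", {
  expect_equal(simulate_survival(c(0, 2, 5), 0, 0), rep(1, 3))
  d <- seq(0, 20, by = 2)
  s <- simulate_survival(d, 0.08, 0.006, 2e4, 6e-6)
  expect_true(all(diff(s) < 0))
  cgrid <- seq(0, 1e-5, length.out = 6)
  sc <- vapply(cgrid, function(cc)
    simulate_survival(5, 0.08, 0.006, 2e4, cc), 0)
  expect_true(all(diff(sc) < 0))
  # reduces to pure LQ at c = 0
  expect_equal(simulate_survival(d, 0.08, 0.006, 2e4, 0),
               exp(-0.08 * 1.1 * d - 0.006 * (1.1 * d)^2))
  expect_error(simulate_survival(-1, 0.1, 0.01), ">= 0")
})

test_that("a ~20-point programmed gain at a mid dose survives the full round trip", {
  # choose the proton-dynamic coefficient so S(no PS) - S(PS) = 0.20 at 5 Gy
  s0 <- simulate_survival(5, 0.08, 0.006, 0, 0)
  pd <- uniroot(function(pd) s0 - simulate_survival(5, 0.08, 0.006, pd,
                                                    6e-6) - 0.20,
                c(0, 1e7))$root
  gains <- vapply(1:20, function(s) {
    set.seed(s)
    mk <- function(ps, surv)
      data.frame(well = paste0(ps, 1:4, "d"),
                 absorbance = 0.08 + surv * (1 + 0.04 * rnorm(4)),
                 dose_Gy = 5, ps_present = ps, ps_uM = 6,
                 experiment_id = "E1", is_blank = FALSE)
    mk0 <- function(ps)
      data.frame(well = paste0(ps, 1:4, "c"),
                 absorbance = 0.08 + 1 * (1 + 0.04 * rnorm(4)),
                 dose_Gy = 0, ps_present = ps, ps_uM = 6,
                 experiment_id = "E1", is_blank = FALSE)
    df <- rbind(mk0(FALSE), mk0(TRUE), mk(FALSE, s0),
                mk(TRUE, simulate_survival(5, 0.08, 0.006, pd, 6e-6)),
                data.frame(well = paste0("b", 1:3),
                           absorbance = rep(0.08, 3), dose_Gy = 0,
                           ps_present = FALSE, ps_uM = 0,
                           experiment_id = "E1", is_blank = TRUE))
    differential_gain(compute_viability(plate_readout(df)))$mean_gain
  }, 0)
  expect_equal(mean(gains), 20, tolerance = 0.15)
})
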