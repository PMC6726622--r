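# MTT viability against matched controls, the differential proton-dynamic
# gain statistic, and the linear-quadratic survival simulator.

#' Construct a plate readout
#'
#' Validates an MTT plate table: blank wells per experiment, >= 3 replicate
#' wells per condition, and a matched unirradiated control (same
#' photosensitiser status, dose 0) for every irradiated condition.
#'
#' @param data Data frame with columns `well`, `absorbance` (OD at the
#'   formazan wavelength), `dose_Gy`, `ps_present` (logical), `ps_uM`,
#'   `experiment_id` and `is_blank` (logical).
#' @param min_replicates Minimum wells per non-blank condition (default 3).
#' @return Object of class `plate_readout` (the validated data frame).
#' @export
plate_readout <- function(data, min_replicates = 3L) {
  req <- c("well", "absorbance", "dose_Gy", "ps_present", "ps_uM",
           "experiment_id", "is_blank")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  cells <- data[!data$is_blank, , drop = FALSE]
  if (!any(data$is_blank)) stop("no blank wells found")
  key <- interaction(cells$experiment_id, cells$dose_Gy, cells$ps_present,
                     drop = TRUE)
  counts <- table(key)
  if (any(counts < min_replicates))
    stop("condition(s) with fewer than ", min_replicates, " wells: ",
         paste(names(counts)[counts < min_replicates], collapse = ", "))
  irr <- unique(cells[cells$dose_Gy > 0,
                      c("experiment_id", "dose_Gy", "ps_present")])
  for (i in seq_len(nrow(irr))) {
    ok <- any(cells$experiment_id == irr$experiment_id[i] &
              cells$dose_Gy == 0 & cells$ps_present == irr$ps_present[i])
    if (!ok)
      stop(sprintf(
        "missing matched dose-0 control for experiment %s, dose %g Gy, PS %s",
        irr$experiment_id[i], irr$dose_Gy[i], irr$ps_present[i]))
  }
  structure(data, class = c("plate_readout", "data.frame"))
}

#' Compute viability fractions against matched controls
#'
#' Blank-corrects each well (per-experiment mean blank), averages wells per
#' condition, and divides by the matched unirradiated control of the same
#' photosensitiser status (irradiated no-PS cells vs media controls,
#' PS-incubated irradiated cells vs PS dark controls).  The SEM is propagated
#' by the delta method.  Viabilities above 1.2 are flagged as anomalous, not
#' clipped.
#'
#' @param readout A [plate_readout()].
#' @return Object of class `viability_result`: a data frame with one row per
#'   condition (`experiment_id`, `dose_Gy`, `ps_present`, `viability`, `sem`,
#'   `n_wells`, `flag_high`) plus a per-well table in attribute `"wells"`.
#' @export
compute_viability <- function(readout) {
  stopifnot(inherits(readout, "plate_readout"))
  df <- as.data.frame(readout)
  blanks <- tapply(df$absorbance[df$is_blank],
                   df$experiment_id[df$is_blank], mean)
  cells <- df[!df$is_blank, , drop = FALSE]
  cells$corrected <- cells$absorbance -
    as.numeric(blanks[as.character(cells$experiment_id)])
  if (any(cells$corrected < -0.05))
    warning("blank-corrected absorbance below -0.05 in ",
            sum(cells$corrected < -0.05), " well(s)")
  conds <- unique(cells[, c("experiment_id", "dose_Gy", "ps_present")])
  conds <- conds[order(conds$experiment_id, conds$dose_Gy,
                       conds$ps_present), , drop = FALSE]
  rownames(conds) <- NULL
  res <- conds
  res$viability <- NA_real_
  res$sem <- NA_real_
  res$n_wells <- NA_integer_
  wells_out <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- cells$experiment_id == conds$experiment_id[i] &
      cells$dose_Gy == conds$dose_Gy[i] &
      cells$ps_present == conds$ps_present[i]
    ctl <- cells$experiment_id == conds$experiment_id[i] &
      cells$dose_Gy == 0 & cells$ps_present == conds$ps_present[i]
    m <- mean(cells$corrected[sel])
    s <- stats::sd(cells$corrected[sel]) / sqrt(sum(sel))
    mc <- mean(cells$corrected[ctl])
    sc <- stats::sd(cells$corrected[ctl]) / sqrt(sum(ctl))
    if (mc <= 0) stop("non-positive control mean for experiment ",
                      conds$experiment_id[i])
    v <- m / mc
    res$viability[i] <- v
    # delta method for a ratio of independent means
    res$sem[i] <- abs(v) * sqrt((s / m)^2 + (sc / mc)^2)
    res$n_wells[i] <- sum(sel)
    wells_out[[i]] <- data.frame(
      experiment_id = conds$experiment_id[i], dose_Gy = conds$dose_Gy[i],
      ps_present = conds$ps_present[i],
      well_viability = cells$corrected[sel] / mc)
  }
  res$flag_high <- res$viability > 1.2
  structure(res, class = c("viability_result", "data.frame"),
            wells = do.call(rbind, wells_out))
}

#' Differential proton-dynamic gain
#'
#' Gain = viability(no PS) - viability(PS) at equal dose, in percentage
#' points: the extra cell kill attributable to the photosensitiser beyond
#' radiation alone.  Per (experiment, dose) pair a two-sided Welch test on
#' the per-well viabilities is reported (NA with a note when a dose was
#' tested once only, i.e. a side has a single well).  The aggregate pools
#' all (experiment, dose) gains.
#'
#' @param result A [compute_viability()] result.
#' @return List with `gains` (data frame: `experiment_id`, `dose_Gy`,
#'   `gain_points`, `p_value`), `mean_gain`, `median_gain`.
#' @export
differential_gain <- function(result) {
  stopifnot(inherits(result, "viability_result"))
  wells <- attr(result, "wells")
  df <- as.data.frame(result)
  irr <- df[df$dose_Gy > 0, , drop = FALSE]
  pairs <- unique(irr[, c("experiment_id", "dose_Gy")])
  if (!nrow(pairs)) stop("no irradiated conditions present")
  out <- pairs
  out$gain_points <- NA_real_
  out$p_value <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    sel <- irr$experiment_id == pairs$experiment_id[i] &
      irr$dose_Gy == pairs$dose_Gy[i]
    v_no <- irr$viability[sel & !irr$ps_present]
    v_ps <- irr$viability[sel & irr$ps_present]
    if (!length(v_no) || !length(v_ps))
      stop(sprintf("unpaired dose %g Gy in experiment %s",
                   pairs$dose_Gy[i], pairs$experiment_id[i]))
    out$gain_points[i] <- 100 * (v_no - v_ps)
    w_no <- wells$well_viability[wells$experiment_id == pairs$experiment_id[i] &
                                 wells$dose_Gy == pairs$dose_Gy[i] &
                                 !wells$ps_present]
    w_ps <- wells$well_viability[wells$experiment_id == pairs$experiment_id[i] &
                                 wells$dose_Gy == pairs$dose_Gy[i] &
                                 wells$ps_present]
    if (length(w_no) >= 2L && length(w_ps) >= 2L) {
      out$p_value[i] <- stats::t.test(w_no, w_ps)$p.value
    }  # else: tested once only - no statistical analysis possible
  }
  rownames(out) <- NULL
  list(gains = out, mean_gain = mean(out$gain_points),
       median_gain = stats::median(out$gain_points))
}

#' Linear-quadratic survival with an additive proton-dynamic term
#'
#' S(D) = exp(-alpha (RBE D) - beta (RBE D)^2) * exp(-pd_coefficient D c):
#' the standard LQ cell-survival model at the proton relative biological
#' effectiveness (1.1), multiplied by a proton-dynamic kill term proportional
#' to dose and photosensitiser concentration.  Reduces to pure LQ at c = 0.
#'
#' @param doses Doses in Gy.
#' @param lq_alpha LQ alpha, Gy^-1.
#' @param lq_beta LQ beta, Gy^-2.
#' @param pd_coefficient Proton-dynamic kill coefficient, Gy^-1 M^-1.
#' @param ps_conc Photosensitiser concentration, M.
#' @param rbe Relative biological effectiveness (default 1.1).
#' @return Expected surviving fractions.
#' @export
#' @examples
#' simulate_survival(c(2, 5, 10), 0.08, 0.006, 2e4, 6e-6)
simulate_survival <- function(doses, lq_alpha, lq_beta, pd_coefficient = 0,
                              ps_conc = 0, rbe = 1.1) {
  if (any(c(doses, lq_alpha, lq_beta, pd_coefficient, ps_conc, rbe) < 0))
    stop("all parameters must be >= 0")
  d_eff <- rbe * doses
  exp(-lq_alpha * d_eff - lq_beta * d_eff^2) *
    exp(-pd_coefficient * doses * ps_conc)
}
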