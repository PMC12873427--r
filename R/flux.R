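#' Construct a flux-assay trace
#'
#' Simultaneous extravesicular chloride (Ag/AgCl electrode, mM) and pH
#' (micro pH electrode) recordings from a proteoliposome flux assay.
#' Transport is electrically blocked until valinomycin dissipates the
#' membrane potential, so slopes are measured from
#' \code{valinomycin_time_s} onward.  Sign convention: Cl- release from
#' vesicles (extravesicular increase) positive, H+ uptake into vesicles
#' (extravesicular pH increase) positive.
#'
#' @param time_s strictly increasing time, s.
#' @param chloride_mM extravesicular chloride, mM.
#' @param pH extravesicular pH.
#' @param valinomycin_time_s time of valinomycin addition (inside record).
#' @return object of class \code{clc_flux_trace}.
#' @export
flux_trace <- function(time_s, chloride_mM, pH, valinomycin_time_s) {
  stopifnot(length(time_s) == length(chloride_mM),
            length(time_s) == length(pH), all(diff(time_s) > 0))
  if (valinomycin_time_s < min(time_s) || valinomycin_time_s > max(time_s))
    stop("valinomycin_time_s outside the recorded range")
  structure(list(time_s = time_s, chloride_mM = chloride_mM, pH = pH,
                 valinomycin_time_s = valinomycin_time_s),
            class = "clc_flux_trace")
}

#' Assay parameters for rate conversion
#'
#' @param n_transporters number of active transporters in the assay (> 0).
#'   The usual experimental alternative (protein:lipid ratio + molecular mass +
#'   orientation assumptions) can be folded in by the caller; no default is
#'   asserted here.
#' @param volume_L extravesicular volume, L.
#' @param buffering_capacity_M_per_pH buffering capacity converting a pH
#'   change into moles of H+ per litre (mol / pH unit / L); must be
#'   supplied for proton-channel analysis.
#' @return object of class \code{clc_assay_params}.
#' @export
assay_params <- function(n_transporters, volume_L = 6e-4,
                         buffering_capacity_M_per_pH = 0.01) {
  stopifnot(n_transporters > 0, volume_L > 0,
            buffering_capacity_M_per_pH > 0)
  structure(list(n_transporters = n_transporters, volume_L = volume_L,
                 buffering_capacity = buffering_capacity_M_per_pH),
            class = "clc_assay_params")
}

.avogadro <- 6.02214076e23

#' Initial post-valinomycin transport slope
#'
#' Least-squares (optionally Theil-Sen) slope of the selected channel over
#' a window starting at valinomycin addition, converted to mol/s via the
#' extravesicular volume (and the buffering capacity for the proton
#' channel).
#'
#' @param trace \code{clc_flux_trace}.
#' @param channel "chloride" or "proton".
#' @param params \code{clc_assay_params}.
#' @param window_s slope window length after valinomycin, s (default 10).
#' @param start_s window start; must be at or after valinomycin addition.
#' @param robust use a Theil-Sen median-of-slopes estimator.
#' @return slope in mol/s (positive = transport by the sign convention),
#'   with attribute \code{"n_points"}.
#' @export
initial_slope <- function(trace, channel = c("chloride", "proton"), params,
                          window_s = 10, start_s = trace$valinomycin_time_s,
                          robust = FALSE) {
  channel <- match.arg(channel)
  if (start_s < trace$valinomycin_time_s)
    stop("slope window precedes valinomycin addition: transport is ",
         "electrically blocked before it")
  sel <- trace$time_s >= start_s & trace$time_s <= start_s + window_s
  if (sum(sel) < 5)
    stop("fewer than 5 samples in the slope window")
  t <- trace$time_s[sel]
  y <- if (channel == "chloride") trace$chloride_mM[sel] else trace$pH[sel]
  if (robust) {
    cmb <- utils::combn(length(t), 2)
    sl <- (y[cmb[2, ]] - y[cmb[1, ]]) / (t[cmb[2, ]] - t[cmb[1, ]])
    slope <- stats::median(sl)
  } else {
    slope <- stats::cov(t, y) / stats::var(t)
  }
  # residual-based standard error of the slope: the detection floor that
  # separates real transport from electrode noise
  resid <- y - mean(y) - slope * (t - mean(t))
  se <- sqrt(sum(resid^2) / (length(t) - 2)) / sqrt(sum((t - mean(t))^2))
  conv <- if (channel == "chloride") {
    1e-3 * params$volume_L                  # mM/s -> mol/s
  } else {
    params$buffering_capacity * params$volume_L  # pH/s -> mol/s
  }
  structure(slope * conv, n_points = sum(sel), se = se * conv)
}

#' Per-transporter turnover rates
#'
#' @param cl_slope_mol_s,h_slope_mol_s slopes from [initial_slope()],
#'   mol/s.
#' @param params \code{clc_assay_params}.
#' @return list(cl_rate, h_rate) in ions per second per transporter; a
#'   negative proton slope (extravesicular acidification) indicates leak,
#'   is reported as \code{h_rate = 0} with attribute \code{"leak"}.
#' @export
turnover_rates <- function(cl_slope_mol_s, h_slope_mol_s, params) {
  if (params$n_transporters <= 0) stop("transporter count must be positive")
  to_rate <- function(x) as.numeric(x) * .avogadro / params$n_transporters
  cl <- to_rate(cl_slope_mol_s)
  h <- to_rate(h_slope_mol_s)
  leak <- FALSE
  if (h < 0) {
    # under the imposed twofold H+ gradient, inward H+ movement can only be
    # active transport; an outward (negative) slope is leak, not transport
    leak <- TRUE
    h <- 0
  } else if (!is.null(attr(h_slope_mol_s, "se")) &&
             as.numeric(h_slope_mol_s) < 2 * attr(h_slope_mol_s, "se")) {
    # below the electrode detection floor: no measurable H+ transport
    h <- 0
  }
  structure(list(cl_rate = max(cl, 0), h_rate = h), leak = leak)
}

#' Cl-/H+ transport stoichiometry
#'
#' Ratio of the chloride and proton turnover rates.  A zero proton rate
#' (uncoupled transporter, or leak-only proton signal) yields \code{NA}
#' with attribute \code{"uncoupled" = TRUE} rather than a number.
#'
#' @param rates list(cl_rate, h_rate) from [turnover_rates()].
#' @return stoichiometry, or NA flagged uncoupled.
#' @export
stoichiometry <- function(rates) {
  if (rates$h_rate <= 0)
    return(structure(NA_real_, uncoupled = TRUE))
  structure(rates$cl_rate / rates$h_rate, uncoupled = FALSE)
}

#' Aggregate replicate transport results
#'
#' Mean and standard error per quantity across biological replicates.
#' Stoichiometry is aggregated as the mean of per-replicate ratios, not the
#' ratio of mean rates (the two differ on heterogeneous replicates).
#'
#' @param results list of per-replicate lists with elements \code{cl_rate},
#'   \code{h_rate}, \code{stoichiometry} (NA allowed for uncoupled).
#' @return list(cl_rate, cl_sem, h_rate, h_sem, stoichiometry,
#'   stoichiometry_sem, n, uncoupled).
#' @export
aggregate_replicates <- function(results) {
  n <- length(results)
  if (n == 0) stop("no replicates")
  cl <- vapply(results, function(r) r$cl_rate, numeric(1))
  h <- vapply(results, function(r) r$h_rate, numeric(1))
  st <- vapply(results, function(r) as.numeric(r$stoichiometry), numeric(1))
  sem <- function(x) if (length(x) < 2) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  uncoupled <- all(is.na(st))
  out <- list(cl_rate = mean(cl), cl_sem = sem(cl),
              h_rate = mean(h), h_sem = sem(h),
              stoichiometry = if (uncoupled) NA_real_ else
                mean(st, na.rm = TRUE),
              stoichiometry_sem = if (uncoupled) NA_real_ else
                sem(st[!is.na(st)]),
              n = n, uncoupled = uncoupled)
  if (n < 2) attr(out, "single_replicate") <- TRUE
  out
}

#' Analyse one flux trace end to end
#'
#' Convenience wrapper: slopes for both channels, turnover rates and
#' stoichiometry.
#'
#' @param trace \code{clc_flux_trace}.
#' @param params \code{clc_assay_params}.
#' @param window_s slope window, s.
#' @param robust Theil-Sen slopes.
#' @return list(cl_rate, h_rate, stoichiometry, leak).
#' @export
analyze_flux_trace <- function(trace, params, window_s = 10,
                               robust = FALSE) {
  cl <- initial_slope(trace, "chloride", params, window_s, robust = robust)
  h <- initial_slope(trace, "proton", params, window_s, robust = robust)
  rates <- turnover_rates(cl, h, params)
  list(cl_rate = rates$cl_rate, h_rate = rates$h_rate,
       stoichiometry = stoichiometry(rates),
       leak = isTRUE(attr(rates, "leak")))
}
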