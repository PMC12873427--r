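#' Intrinsic amide-exchange rate model
#'
#' Three-term model of the chemical (unprotected) backbone-amide H/D
#' exchange rate: acid-catalysed, base-catalysed and water-catalysed
#' contributions,
#' \deqn{k_{int}(pH) = k_A 10^{-pH} + k_B 10^{pH - pK_w} + k_W.}
#' Defaults are sequence-averaged poly-DL-alanine reference constants
#' (experiment temperature ~21 C), expressed per second; only rate ratios
#' enter the pH-normalization, so the absolute scale is immaterial.  In the
#' base-dominated regime (pH >= ~4.5) the rate falls about tenfold per pH
#' unit; below pH ~3.5 the acid term bends the curve away from linearity
#' and correction factors are flagged approximate.
#'
#' @param log10_kA acid-catalysed constant, log10 of (per M per s).
#' @param log10_kB base-catalysed constant.
#' @param log10_kW water-catalysed constant, log10 of (per s).
#' @param pKw ionic-product exponent.
#' @return object of class \code{clc_intrinsic_model}.
#' @export
intrinsic_rate_model <- function(log10_kA = 1.62 - log10(60),
                                 log10_kB = 10.05 - log10(60),
                                 log10_kW = -1.5 - log10(60),
                                 pKw = 15.05) {
  structure(list(kA = 10^log10_kA, kB = 10^log10_kB, kW = 10^log10_kW,
                 pKw = pKw),
            class = "clc_intrinsic_model")
}

#' Intrinsic exchange rate at a pH
#' @param model \code{clc_intrinsic_model}.
#' @param pH value in (0, 14).
#' @return rate, 1/s (strictly positive).
#' @export
intrinsic_rate <- function(model, pH) {
  stopifnot(all(pH > 0), all(pH < 14))
  model$kA * 10^(-pH) + model$kB * 10^(pH - model$pKw) + model$kW
}

#' Cross-pH correction factor
#'
#' \code{k_int(pH_ref) / k_int(pH)}: multiplying an exposure time measured
#' at \code{pH} by this factor gives the chemically equivalent exposure at
#' \code{pH_ref}.  Factors involving pH below 3.5 carry an
#' \code{"approximate"} attribute, since the model deviates from the
#' log-linear regime there.
#'
#' @param model \code{clc_intrinsic_model}.
#' @param pH_ref,pH the two pH values.
#' @return positive factor with attribute \code{approximate}.
#' @export
correction_factor <- function(model, pH_ref, pH) {
  f <- intrinsic_rate(model, pH_ref) / intrinsic_rate(model, pH)
  attr(f, "approximate") <- (pH < 3.5) || (pH_ref < 3.5)
  f
}

#' Matched time point across pH
#'
#' The exposure time at \code{pH} giving the same intrinsic exposure
#' \code{k_int * t} as \code{t_ref} at \code{pH_ref} (e.g. 20 s at pH 6.5
#' maps to roughly 2000 s at pH 4.5 with default constants).
#'
#' @param model \code{clc_intrinsic_model}.
#' @param pH_ref,pH the two pH values.
#' @param t_ref reference exposure, s (> 0).
#' @return matched time, s.
#' @export
matched_timepoint <- function(model, pH_ref, t_ref, pH) {
  stopifnot(all(t_ref > 0))
  t_ref * as.numeric(correction_factor(model, pH_ref, pH))
}

#' Construct a deuterium-uptake curve
#'
#' @param peptide_id label.
#' @param pH labeling pH.
#' @param timepoints exposure times, s, strictly increasing.
#' @param deuteration deuterium uptake (Da), same length.
#' @param max_exchangeable number of exchangeable backbone amides.
#' @param residue_range optional c(start, end).
#' @param replicate_sd optional per-timepoint SD.
#' @return object of class \code{clc_uptake_curve}.
#' @export
uptake_curve <- function(peptide_id, pH, timepoints, deuteration,
                         max_exchangeable, residue_range = NULL,
                         replicate_sd = NULL) {
  stopifnot(length(timepoints) == length(deuteration),
            all(diff(timepoints) > 0), all(timepoints > 0),
            max_exchangeable >= 1)
  if (any(deuteration < 0) || any(deuteration > max_exchangeable + 1e-9))
    stop("deuteration outside [0, max_exchangeable]")
  structure(list(peptide_id = peptide_id, pH = pH, timepoints = timepoints,
                 deuteration = deuteration,
                 max_exchangeable = max_exchangeable,
                 residue_range = residue_range, replicate_sd = replicate_sd),
            class = "clc_uptake_curve")
}

#' Fully-deuterated control level
#' @param peptide_id label.
#' @param fd_level measured fully-deuterated deuteration, Da (> 0).
#' @return object of class \code{clc_fd_control}.
#' @export
fd_control <- function(peptide_id, fd_level) {
  if (fd_level <= 0) stop("fully deuterated control level must be positive")
  structure(list(peptide_id = peptide_id, fd_level = fd_level),
            class = "clc_fd_control")
}

#' Back-exchange correction against a fully deuterated control
#'
#' Scales measured deuteration by \code{max_exchangeable / fd_level},
#' recovering the deuterium lost during sample handling.  Corrected values
#' exceeding the theoretical maximum by more than 5 percent trigger a
#' warning and are clipped to the maximum.
#'
#' @param curve \code{clc_uptake_curve}.
#' @param fd \code{clc_fd_control} for the same peptide.
#' @return corrected \code{clc_uptake_curve}.
#' @export
back_exchange_correct <- function(curve, fd) {
  if (!identical(curve$peptide_id, fd$peptide_id))
    stop("peptide_id mismatch between curve and FD control")
  if (fd$fd_level < max(curve$deuteration))
    warning("FD control below an observed deuteration for peptide ",
            curve$peptide_id)
  scale <- curve$max_exchangeable / fd$fd_level
  d <- curve$deuteration * scale
  over <- d > curve$max_exchangeable * 1.05
  if (any(over)) {
    warning("corrected deuteration exceeds theoretical maximum by >5% for ",
            sum(over), " timepoint(s); clipping")
  }
  d <- pmin(d, curve$max_exchangeable)
  curve$deuteration <- d
  if (!is.null(curve$replicate_sd)) curve$replicate_sd <-
      curve$replicate_sd * scale
  curve
}

# matched-exposure deuteration of `curve` at target time t (s): nearest
# timepoint within a factor of `tol`, else log-time linear interpolation
.curve_at <- function(curve, t, tol = 1.5) {
  tp <- curve$timepoints
  ratio <- pmax(tp / t, t / tp)
  k <- which.min(ratio)
  if (ratio[k] <= tol) return(curve$deuteration[k])
  if (t < min(tp) || t > max(tp)) return(NA_real_)
  stats::approx(log(tp), curve$deuteration, xout = log(t))$y
}

#' Differential uptake between two pH conditions
#'
#' Compares two curves for the same peptide either at raw (identical) time
#' points or at pH-matched exposures: each timepoint of curve A is mapped
#' through [matched_timepoint()] onto curve B's time axis (nearest point
#' within a factor of 1.5, else log-time interpolation).  The difference is
#' B minus A at matched exposure, so with A at the higher (reference) pH a
#' positive value means faster-than-chemistry exchange at the lower pH --
#' the signature of a conformational change rather than chemistry.
#'
#' @param curve_a reference curve (e.g. pH 6.5).
#' @param curve_b comparison curve (e.g. pH 4.5).
#' @param model \code{clc_intrinsic_model} (needed for pH_matched mode).
#' @param mode "pH_matched" (default) or "raw".
#' @return data.frame(time_a_s, time_b_s, uptake_a, uptake_b, difference).
#' @export
differential_uptake <- function(curve_a, curve_b, model = NULL,
                                mode = c("pH_matched", "raw")) {
  mode <- match.arg(mode)
  if (!identical(curve_a$peptide_id, curve_b$peptide_id))
    stop("curves are for different peptides")
  if (mode == "raw") {
    common <- intersect(curve_a$timepoints, curve_b$timepoints)
    if (length(common) == 0) stop("no shared timepoints in raw mode")
    ia <- match(common, curve_a$timepoints)
    ib <- match(common, curve_b$timepoints)
    return(data.frame(time_a_s = common, time_b_s = common,
                      uptake_a = curve_a$deuteration[ia],
                      uptake_b = curve_b$deuteration[ib],
                      difference = curve_b$deuteration[ib] -
                        curve_a$deuteration[ia]))
  }
  if (is.null(model)) stop("pH_matched mode requires an intrinsic-rate model")
  tb <- matched_timepoint(model, curve_a$pH, curve_a$timepoints, curve_b$pH)
  ub <- vapply(tb, function(t) .curve_at(curve_b, t), numeric(1))
  ok <- !is.na(ub)
  if (!any(ok))
    stop("no alignable timepoints; curve B lacks coverage near matched ",
         "times ", paste(signif(tb, 3), collapse = ", "))
  data.frame(time_a_s = curve_a$timepoints[ok], time_b_s = tb[ok],
             uptake_a = curve_a$deuteration[ok], uptake_b = ub[ok],
             difference = ub[ok] - curve_a$deuteration[ok])
}

#' Fit a protection factor to an uptake curve
#'
#' Single-population model \eqn{D(t) = N f (1 - e^{-k_{int} t / P})} fitted
#' for log10 P by nonlinear least squares, where N is the number of
#' exchangeable amides and f the fully-deuterated efficiency.
#'
#' @param curve \code{clc_uptake_curve}.
#' @param model \code{clc_intrinsic_model}.
#' @param fd_efficiency plateau efficiency f in (0, 1]; default 1.
#' @return list(log10_P, P, fitted).
#' @export
fit_protection_factor <- function(curve, model, fd_efficiency = 1) {
  k <- intrinsic_rate(model, curve$pH)
  N <- curve$max_exchangeable
  t <- curve$timepoints
  d <- curve$deuteration
  obj <- function(lp) {
    pred <- N * fd_efficiency * (1 - exp(-k * t / 10^lp))
    sum((pred - d)^2)
  }
  # coarse grid then local refinement: robust across many decades of P
  grid <- seq(-1, 9, by = 0.25)
  lp0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
  opt <- stats::optimize(obj, interval = c(lp0 - 0.5, lp0 + 0.5))
  lp <- opt$minimum
  list(log10_P = lp, P = 10^lp,
       fitted = N * fd_efficiency * (1 - exp(-k * t / 10^lp)))
}

#' Read / write long-form HDX uptake tables
#'
#' Long-form TSV with columns peptide, start, end, pH, time_s, deuteration,
#' sd, max_exchangeable.
#'
#' @param path TSV file.
#' @return list of \code{clc_uptake_curve}, one per (peptide, pH).
#' @export
read_hdx_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("peptide", "pH", "time_s", "deuteration", "max_exchangeable")
  if (!all(req %in% names(df)))
    stop("HDX table lacks columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  out <- list()
  for (key in split(df, paste(df$peptide, df$pH))) {
    key <- key[order(key$time_s), ]
    out[[paste(key$peptide[1], key$pH[1])]] <-
      uptake_curve(key$peptide[1], key$pH[1], key$time_s, key$deuteration,
                   key$max_exchangeable[1],
                   residue_range = if (all(c("start", "end") %in% names(key)))
                     c(key$start[1], key$end[1]) else NULL,
                   replicate_sd = if ("sd" %in% names(key)) key$sd else NULL)
  }
  out
}

#' @rdname read_hdx_tsv
#' @param curves list of \code{clc_uptake_curve}
#' @return \code{path}, invisibly
#' @export
write_hdx_tsv <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(peptide = cv$peptide_id,
               start = if (is.null(cv$residue_range)) NA else
                 cv$residue_range[1],
               end = if (is.null(cv$residue_range)) NA else
                 cv$residue_range[2],
               pH = cv$pH, time_s = cv$timepoints,
               deuteration = cv$deuteration,
               sd = if (is.null(cv$replicate_sd)) NA else cv$replicate_sd,
               max_exchangeable = cv$max_exchangeable))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
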