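# Thermal-shift (differential scanning fluorimetry) analysis: smoothed
# negative-derivative series, trough detection with contaminant
# exclusion and parabolic sub-grid refinement, replicate summaries and
# paired delta-Tm statistics.

# validate a single melt curve and return (temp, fluor)
as_melt_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("temp_C", "fluorescence") %in% names(curve)))
  temp <- curve$temp_C
  if (is.unsorted(temp, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  step <- diff(temp)
  if (max(step) - min(step) > 1e-8)
    stop("temperature grid must have a uniform step")
  list(temp = temp, fluor = curve$fluorescence, step = step[1])
}

#' Smoothed negative derivative of a melt curve
#'
#' Savitzky-Golay polynomial smoothing differentiation of the
#' fluorescence series, negated (so an unfolding transition appears as a
#' trough), on the curve's own temperature grid.
#'
#' @param curve data.frame with `temp_C` and `fluorescence` columns on a
#'   strictly increasing uniform grid.
#' @param order derivative order, 1 or 2.
#' @param window odd smoothing window length in points, at least 5.
#' @param degree polynomial degree of the smoother.
#' @return a data.frame (`temp_C`, `deriv`) where `deriv` is the negated
#'   derivative of the requested order.
#' @export
smooth_and_differentiate <- function(curve, order = 1L, window = 7L,
                                     degree = 3L) {
  mc <- as_melt_curve(curve)
  stopifnot(order %in% c(1L, 2L),
            is_count(window, positive = TRUE), window %% 2 == 1,
            window >= 5)
  if (length(mc$fluor) < window)
    stop("curve shorter than the smoothing window")
  d <- signal::sgolayfilt(mc$fluor, p = degree, n = window, m = order,
                          ts = mc$step)
  data.frame(temp_C = mc$temp, deriv = -d)
}

# trough prominence: walk outward until a deeper point or the boundary,
# the barrier is the highest derivative value passed on each side
trough_prominence <- function(d, i) {
  n <- length(d)
  left <- i; bl <- d[i]
  while (left > 1 && d[left - 1] >= d[i]) {
    left <- left - 1; bl <- max(bl, d[left])
  }
  if (left == 1 && d[1] >= d[i]) bl <- max(bl, d[1])
  right <- i; br <- d[i]
  while (right < n && d[right + 1] >= d[i]) {
    right <- right + 1; br <- max(br, d[right])
  }
  min(bl, br) - d[i]
}

# local minima of a series (plateaus resolved to their first point)
local_minima <- function(d) {
  n <- length(d)
  if (n < 3) return(integer(0))
  which(vapply(2:(n - 1), function(i) {
    d[i] <= d[i - 1] && d[i] < d[i + 1]
  }, NA)) + 1L
}

# parabolic sub-grid refinement of a trough position
refine_trough <- function(temp, d, i) {
  if (i <= 1 || i >= length(d)) return(temp[i])
  y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom <= 0) return(temp[i])
  offset <- 0.5 * (y1 - y3) / denom
  temp[i] + offset * (temp[2] - temp[1])
}

#' Find melting temperatures in a derivative series
#'
#' Detects the most prominent troughs of a negative-derivative series,
#' optionally excluding a temperature window (e.g. 66-70 degrees Celsius
#' for a co-purified chaperone contaminant), refines each trough
#' position by parabolic interpolation of its neighbours, and returns up
#' to `max_peaks` melting temperatures sorted ascending (Tm1 below Tm2).
#'
#' @param deriv data.frame (`temp_C`, `deriv`) from
#'   [smooth_and_differentiate()].
#' @param max_peaks maximum number of troughs to report.
#' @param exclusion_window optional `c(low, high)` temperature window
#'   whose troughs are discarded.
#' @param min_prominence minimum trough prominence (derivative units);
#'   `NULL` uses 5 percent of the derivative range.
#' @param deriv_order derivative order recorded alongside each Tm.
#' @return a data.frame (`tm`, `prominence`, `deriv_order`), zero rows
#'   (with a warning) when no trough clears the prominence floor.
#' @export
find_tms <- function(deriv, max_peaks = 2L, exclusion_window = NULL,
                     min_prominence = NULL, deriv_order = 1L) {
  stopifnot(is.data.frame(deriv),
            all(c("temp_C", "deriv") %in% names(deriv)),
            is_count(max_peaks, positive = TRUE))
  d <- deriv$deriv; temp <- deriv$temp_C
  # absolute floor guards against numerical wiggle on flat curves
  eps <- sqrt(.Machine$double.eps) * max(1, max(abs(d)))
  if (is.null(min_prominence))
    min_prominence <- max(0.05 * diff(range(d)), eps)
  min_prominence <- max(min_prominence, eps)
  cand <- local_minima(d)
  if (!is.null(exclusion_window)) {
    stopifnot(length(exclusion_window) == 2)
    cand <- cand[temp[cand] < exclusion_window[1] |
                   temp[cand] > exclusion_window[2]]
  }
  prom <- vapply(cand, function(i) trough_prominence(d, i), 0)
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) {
    warning("no trough above the prominence floor")
    return(data.frame(tm = numeric(0), prominence = numeric(0),
                      deriv_order = integer(0)))
  }
  ord <- order(-prom)[seq_len(min(max_peaks, length(cand)))]
  cand <- cand[ord]; prom <- prom[ord]
  tm <- vapply(cand, function(i) refine_trough(temp, d, i), 0)
  o <- order(tm)
  data.frame(tm = tm[o], prominence = prom[o],
             deriv_order = rep(as.integer(deriv_order), length(tm)))
}

#' Extract melting temperatures from a melt curve
#'
#' High-level single-curve analysis: first-derivative troughs are
#' detected with [find_tms()]; when fewer than `max_peaks` transitions
#' clear the prominence floor there, the negative second derivative is
#' scanned for additional shoulder transitions (the derivative order
#' used is recorded per Tm).
#'
#' @param curve data.frame with `temp_C` and `fluorescence` columns.
#' @param max_peaks,exclusion_window,min_prominence see [find_tms()].
#' @param window,degree smoothing parameters, see
#'   [smooth_and_differentiate()].
#' @return a data.frame (`tm`, `prominence`, `deriv_order`) sorted by
#'   temperature.
#' @export
melt_tms <- function(curve, max_peaks = 2L, exclusion_window = NULL,
                     min_prominence = NULL, window = 7L, degree = 3L) {
  d1 <- smooth_and_differentiate(curve, order = 1L, window = window,
                                 degree = degree)
  res <- suppressWarnings(
    find_tms(d1, max_peaks, exclusion_window, min_prominence,
             deriv_order = 1L))
  if (nrow(res) < max_peaks) {
    d2 <- smooth_and_differentiate(curve, order = 2L, window = window,
                                   degree = degree)
    # shoulder transitions barely register next to the dominant one, so
    # the second-derivative pass uses a lower relative floor
    extra <- suppressWarnings(
      find_tms(d2, max_peaks, exclusion_window,
               min_prominence = 0.01 * diff(range(d2$deriv)),
               deriv_order = 2L))
    if (nrow(extra)) {
      # keep only shoulder transitions away from already-found troughs
      step <- curve$temp_C[2] - curve$temp_C[1]
      far <- vapply(extra$tm, function(t)
        all(abs(t - res$tm) > 4 * step), NA)
      extra <- extra[far, , drop = FALSE]
      need <- max_peaks - nrow(res)
      if (nrow(extra) > need)
        extra <- extra[order(-extra$prominence)[seq_len(need)], ,
                       drop = FALSE]
      res <- rbind(res, extra)
    }
  }
  if (nrow(res) == 0L) warning("no melting transition detected")
  res[order(res$tm), , drop = FALSE]
}

#' Analyze replicate melt curves
#'
#' Runs [melt_tms()] per replicate and summarizes Tm1 (and Tm2 when
#' biphasic) as mean and standard deviation across replicates.
#'
#' @param curves data.frame with `temp_C`, `fluorescence`, `replicate`
#'   and optionally `condition` columns.
#' @param ... passed to [melt_tms()].
#' @return an object of class `melt_result`: a list with
#'   `per_replicate` (data.frame `replicate`, `tm_index`, `tm`,
#'   `deriv_order`) and `summary` (data.frame `tm_index`, `mean`, `sd`,
#'   `n`).
#' @export
analyze_melt <- function(curves, ...) {
  stopifnot(is.data.frame(curves), "replicate" %in% names(curves))
  reps <- split(curves, curves$replicate)
  per <- do.call(rbind, lapply(names(reps), function(r) {
    tms <- melt_tms(reps[[r]], ...)
    if (nrow(tms) == 0L) return(NULL)
    data.frame(replicate = r, tm_index = seq_len(nrow(tms)),
               tm = tms$tm, deriv_order = tms$deriv_order,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    stop("no melting transition detected in any replicate")
  summ <- do.call(rbind, lapply(split(per, per$tm_index), function(d) {
    data.frame(tm_index = d$tm_index[1], mean = mean(d$tm),
               sd = stats::sd(d$tm) %||% NA_real_, n = nrow(d))
  }))
  summ$sd[is.na(summ$sd)] <- 0
  structure(list(per_replicate = per, summary = summ),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("Tm%d = %.1f +/- %.1f C (n = %d)\n",
                s$tm_index, s$mean, s$sd, s$n))
  }
  invisible(x)
}

#' Paired delta-Tm between conditions
#'
#' Computes `Tm_i(ligand) - Tm_i(apo)` per matched replicate pair and
#' reports the mean and standard deviation of the paired differences
#' per Tm index (not the difference of condition means with a pooled
#' sd). Replicates are matched by their `replicate` identifiers.
#'
#' @param apo,ligand `melt_result` objects from [analyze_melt()] for the
#'   apo and ligand-bound conditions.
#' @return a data.frame (`tm_index`, `mean_dtm`, `sd_dtm`, `n`).
#' @export
delta_tm <- function(apo, ligand) {
  stopifnot(inherits(apo, "melt_result"), inherits(ligand, "melt_result"))
  a <- apo$per_replicate; b <- ligand$per_replicate
  out <- do.call(rbind, lapply(sort(unique(a$tm_index)), function(k) {
    ak <- a[a$tm_index == k, ]; bk <- b[b$tm_index == k, ]
    if (!setequal(ak$replicate, bk$replicate) ||
          nrow(ak) != nrow(bk))
      stop("unpaired replicate(s) for Tm", k)
    dd <- bk$tm[match(ak$replicate, bk$replicate)] - ak$tm
    data.frame(tm_index = k, mean_dtm = mean(dd),
               sd_dtm = if (length(dd) > 1) stats::sd(dd) else 0,
               n = length(dd))
  }))
  out
}
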