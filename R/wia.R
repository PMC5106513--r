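# Coronary wave intensity analysis: smoothing/differentiation of (p, U)
# traces, net and separated wave intensity, six-wave segmentation and
# classification, cumulative percentage wave areas and grouped indices.
#
# Conventions: forward = proximal-to-distal travel; a pushing
# (compression) wave raises pressure as it passes, a suction (expansion)
# wave lowers it. Wave intensity dI = dp * dU is positive for forward and
# negative for backward travel; the water-hammer separation splits it
# exactly: dI = dI+ + dI-.

.WAVE_LABELS <- list(
  backward = c("early-BPW", "late-BPW", "BSW"),
  forward = c("DFPW", "FSW", "late-FPW"))
.WAVE_KINDS <- list(
  backward = c("pushing", "pushing", "suction"),
  forward = c("pushing", "suction", "pushing"))
# Canonical cycle ordering of the six waves (contraction -> relaxation):
.WAVE_ORDER <- c("early-BPW", "DFPW", "late-BPW", "FSW", "BSW", "late-FPW")

#' Pressure and velocity increments
#'
#' Per-sample increments of uniformly sampled traces, either by
#' Savitzky-Golay local-polynomial differentiation (default) or raw first
#' differences. Increments are returned per sample (slope times the
#' sampling interval).
#'
#' @param p,U Pressure (kPa) and velocity (mm/s) traces, uniform
#'   sampling.
#' @param window Odd Savitzky-Golay window length (samples).
#' @param order Polynomial order.
#' @param smoothing `"sg"` or `"raw"` (plain first differences).
#' @return List with `dp` and `dU` (same length as input).
#' @export
wia_increments <- function(p, U, window = 11, order = 2,
                           smoothing = c("sg", "raw")) {
  smoothing <- match.arg(smoothing)
  stopifnot(length(p) == length(U))
  if (smoothing == "raw") {
    dp <- c(p[2] - p[1], diff(p))
    dU <- c(U[2] - U[1], diff(U))
    return(list(dp = dp, dU = dU))
  }
  if (window %% 2 == 0 || window >= length(p))
    stop("smoothing window must be odd and shorter than the trace")
  list(dp = signal::sgolayfilt(p, p = order, n = window, m = 1, ts = 1),
       dU = signal::sgolayfilt(U, p = order, n = window, m = 1, ts = 1))
}

#' Net wave intensity
#'
#' @param dp,dU Increment vectors.
#' @return Elementwise product `dI = dp * dU`.
#' @export
wave_intensity <- function(dp, dU) {
  stopifnot(length(dp) == length(dU))
  dp * dU
}

#' Water-hammer separation of wave intensity
#'
#' `dp+- = (dp +- rho c dU) / 2` and `dI+- = +-(dp +- rho c dU)^2 /
#' (4 rho c)`, so that `dI+ + dI- = dp dU` exactly. A pure forward wave
#' (`dp = rho c dU`) has `dI- = 0` and vice versa.
#'
#' @param dp,dU Increment vectors.
#' @param rho Blood density (kg mm^-3).
#' @param c Wave speed (mm s^-1).
#' @return List with `dIp`, `dIm`, `dpp`, `dpm` (forward/backward
#'   intensities and pressure increments).
#' @export
wia_separate <- function(dp, dU, rho, c) {
  stopifnot(rho > 0, c > 0)
  zc <- rho * c
  dpp <- (dp + zc * dU) / 2
  dpm <- (dp - zc * dU) / 2
  list(dIp = dpp^2 / zc, dIm = -dpm^2 / zc, dpp = dpp, dpm = dpm)
}

#' PU-loop wave speed estimate
#'
#' Single-point estimate `c = (1/rho) sqrt(sum(dp^2) / sum(dU^2))` from
#' the increments of a full cycle (an alternative to the tube-law wave
#' speed for externally supplied traces).
#'
#' @param dp,dU Increment vectors.
#' @param rho Blood density.
#' @return Wave speed (mm s^-1).
#' @export
pu_wave_speed <- function(dp, dU, rho) {
  sqrt(sum(dp^2) / sum(dU^2)) / rho
}

# Find runs of TRUE in a mask; returns data.frame(start, end) of indices.
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Segment one separated channel into at most 3 labelled windows.
.segment_channel <- function(mag, dpc, t, thresh_frac, merge_gap_s, dt) {
  thr <- thresh_frac * max(mag)
  if (max(mag) <= 0) return(NULL)
  w <- .runs(mag > thr)
  if (!nrow(w)) return(NULL)
  # merge windows separated by short sub-threshold gaps
  merged <- w[1, , drop = FALSE]
  if (nrow(w) > 1) for (i in 2:nrow(w)) {
    if ((w$start[i] - merged$end[nrow(merged)]) * dt < merge_gap_s)
      merged$end[nrow(merged)] <- w$end[i]
    else merged <- rbind(merged, w[i, ])
  }
  # split windows at persistent sign changes of the separated pressure
  # increment (a pushing/suction boundary within one contiguous window,
  # e.g. the forward suction wave running into the valve-closure pushing
  # wave)
  split <- NULL
  for (i in seq_len(nrow(merged))) {
    idx <- merged$start[i]:merged$end[i]
    sgn <- rle(sign(dpc[idx]) >= 0)
    ends <- cumsum(sgn$lengths); starts <- ends - sgn$lengths + 1L
    sub <- data.frame(start = idx[starts], end = idx[ends])
    sub$area <- vapply(seq_len(nrow(sub)), function(j)
      sum(mag[sub$start[j]:sub$end[j]]), numeric(1))
    # absorb minor sign flickers into the dominant neighbours
    keep <- sub$area >= 0.1 * sum(sub$area)
    if (sum(keep) <= 1) { split <- rbind(split, merged[i, c("start", "end")])
    } else {
      sub <- sub[keep, ]
      sub$end[nrow(sub)] <- merged$end[i]
      sub$start[1] <- merged$start[i]
      if (nrow(sub) > 1) for (j in 2:nrow(sub))
        sub$start[j] <- sub$end[j - 1] + 1L
      split <- rbind(split, sub[, c("start", "end")])
    }
  }
  merged <- split
  merged$area <- vapply(seq_len(nrow(merged)), function(i)
    sum(mag[merged$start[i]:merged$end[i]]), numeric(1))
  merged$dpsum <- vapply(seq_len(nrow(merged)), function(i)
    sum(dpc[merged$start[i]:merged$end[i]]), numeric(1))
  merged[order(merged$start), ]
}

# Label the windows of a channel by anchoring on the dominant windows of
# each kind and folding leftover fragments into their nearest labelled
# neighbour. Backward channel: the largest suction window is the backward
# suction wave; the earliest pushing window before it is the early
# backward pushing wave and the largest remaining pushing window the late
# one. Forward channel: the largest pushing window is the dominant
# forward pushing wave, the largest suction window at or after it the
# forward suction wave, and the largest pushing window after that the
# late forward pushing wave. Returns the labelled windows (<= 3 rows).
.assign_labels <- function(win, channel) {
  win$kind <- ifelse(win$dpsum >= 0, "pushing", "suction")
  win$label <- NA_character_
  n <- nrow(win)
  if (channel == "backward") {
    suc <- which(win$kind == "suction")
    if (length(suc)) {
      bsw <- suc[which.max(win$area[suc])]
      win$label[bsw] <- "BSW"
      push_pre <- which(win$kind == "pushing" & win$start < win$start[bsw])
      if (length(push_pre)) {
        e <- push_pre[1]
        win$label[e] <- "early-BPW"
        rest <- setdiff(push_pre, e)
        if (length(rest)) win$label[rest[which.max(win$area[rest])]] <-
            "late-BPW"
      }
    } else {
      # no suction wave at all: pushing windows in time order
      win$label[seq_len(min(n, 2))] <- c("early-BPW", "late-BPW")[
        seq_len(min(n, 2))]
    }
  } else {
    push <- which(win$kind == "pushing")
    if (length(push)) {
      dfpw <- push[which.max(win$area[push])]
      win$label[dfpw] <- "DFPW"
      suc <- which(win$kind == "suction" & win$start >= win$start[dfpw])
      if (!length(suc)) suc <- which(win$kind == "suction")
      if (length(suc)) {
        fsw <- suc[which.max(win$area[suc])]
        win$label[fsw] <- "FSW"
        push_post <- which(win$kind == "pushing" &
                             win$start > win$start[fsw])
        if (length(push_post))
          win$label[push_post[which.max(win$area[push_post])]] <-
            "late-FPW"
      }
    } else if (n) {
      win$label[which.max(win$area)] <- "FSW"
    }
  }
  lab_idx <- which(!is.na(win$label))
  if (!length(lab_idx)) return(win[0, ])
  # fold unlabelled fragments into the nearest labelled window in time
  for (i in setdiff(seq_len(n), lab_idx)) {
    mid <- (win$start[i] + win$end[i]) / 2
    lmid <- (win$start[lab_idx] + win$end[lab_idx]) / 2
    j <- lab_idx[which.min(abs(lmid - mid))]
    win$area[j] <- win$area[j] + win$area[i]
    win$dpsum[j] <- win$dpsum[j] + win$dpsum[i]
  }
  win <- win[lab_idx, ]
  win[order(win$start), ]
}

#' Classify the six coronary waves
#'
#' Segments the forward and backward separated-intensity channels into
#' contiguous windows exceeding a fraction of the channel maximum, merges
#' windows separated by short gaps, folds minor fragments into their
#' nearest neighbour, and assigns the canonical six labels by timing
#' order within each channel (backward: early backward pushing, late
#' backward pushing, backward suction; forward: dominant forward pushing,
#' forward suction, late forward pushing). The pushing/suction kind is
#' read from the sign of the corresponding separated pressure increment.
#'
#' @param sep Separation list from [wia_separate()].
#' @param t Time vector (s), uniform.
#' @param thresh_frac Detection threshold as a fraction of each channel's
#'   maximum intensity magnitude.
#' @param merge_gap_s Windows of the same channel closer than this gap
#'   (s) are merged.
#' @return Data frame of wave records: label, direction, kind, t_start,
#'   t_end, cumulative intensity (signed integral of dI over the window,
#'   kPa mm s^-2 x s) and area magnitude. Warns when fewer than six waves
#'   are detectable.
#' @export
classify_waves <- function(sep, t, thresh_frac = 0.01, merge_gap_s = 0.005) {
  dt <- stats::median(diff(t))
  out <- NULL
  for (channel in c("backward", "forward")) {
    mag <- if (channel == "forward") sep$dIp else -sep$dIm
    dpc <- if (channel == "forward") sep$dpp else sep$dpm
    win <- .segment_channel(mag, dpc, t, thresh_frac, merge_gap_s, dt)
    if (is.null(win) || !nrow(win)) next
    win <- .assign_labels(win, channel)
    if (!nrow(win)) next
    rec <- data.frame(
      label = win$label, direction = channel,
      kind = ifelse(win$dpsum >= 0, "pushing", "suction"),
      t_start = t[win$start], t_end = t[win$end],
      cum_intensity = (if (channel == "forward") 1 else -1) * win$area * dt,
      area = win$area * dt)
    out <- rbind(out, rec)
  }
  if (is.null(out) || !nrow(out)) {
    warning("no waves detected")
    return(data.frame(label = character(), direction = character(),
                      kind = character(), t_start = numeric(),
                      t_end = numeric(), cum_intensity = numeric(),
                      area = numeric()))
  }
  if (nrow(out) < 6)
    warning(sprintf("only %d of 6 waves detectable", nrow(out)))
  out <- out[order(match(out$label, .WAVE_ORDER)), ]
  rownames(out) <- NULL
  out
}

#' Percentage wave areas and grouped indices
#'
#' Each wave's cumulative intensity magnitude as a percentage of the sum
#' over all detected waves, plus the three standard groupings:
#' contraction (early backward pushing, dominant forward pushing, late
#' backward pushing) vs relaxation; accelerating (dominant forward
#' pushing, backward suction, late forward pushing) vs decelerating;
#' forward vs backward.
#'
#' @param records Wave records from [classify_waves()].
#' @return List with `percent` (named per wave) and `groups` (named
#'   percentages).
#' @export
percent_areas <- function(records) {
  if (!nrow(records)) stop("no wave records")
  tot <- sum(abs(records$cum_intensity))
  pct <- 100 * abs(records$cum_intensity) / tot
  names(pct) <- records$label
  gp <- function(labels) sum(pct[names(pct) %in% labels])
  groups <- c(
    contraction = gp(c("early-BPW", "DFPW", "late-BPW")),
    relaxation = gp(c("FSW", "BSW", "late-FPW")),
    accelerating = gp(c("DFPW", "BSW", "late-FPW")),
    decelerating = gp(c("early-BPW", "late-BPW", "FSW")),
    forward = gp(c("DFPW", "FSW", "late-FPW")),
    backward = gp(c("early-BPW", "late-BPW", "BSW")))
  list(percent = pct, groups = groups)
}

#' Coronary wave intensity analysis of a (p, U) trace
#'
#' Full pipeline: resampling to a uniform analysis interval,
#' Savitzky-Golay differentiation, water-hammer separation, six-wave
#' classification and percentage areas.
#'
#' @param t Time (s).
#' @param p Pressure (kPa).
#' @param U Velocity (mm s^-1).
#' @param rho Blood density (kg mm^-3).
#' @param c Wave speed used for separation (mm s^-1); if `NULL`,
#'   estimated from the PU loop.
#' @param dt_resample Analysis sampling interval (s).
#' @param window,order,smoothing Differentiation settings, see
#'   [wia_increments()].
#' @param thresh_frac,merge_gap_s Classification settings, see
#'   [classify_waves()].
#' @return An object of class `cwia`: records, percentage areas, grouped
#'   indices, the resampled traces and the separated intensities.
#' @examples
#' t <- seq(0, 0.8, by = 1e-3)
#' p <- 10 + sin(2 * pi * t / 0.8)
#' U <- 100 * sin(2 * pi * t / 0.8)
#' w <- wia(t, p, U, c = 15000)
#' @export
wia <- function(t, p, U, rho = 1.05e-6, c = NULL, dt_resample = 1e-3,
                window = 11, order = 2, smoothing = "sg",
                thresh_frac = 0.01, merge_gap_s = 0.005) {
  stopifnot(length(t) == length(p), length(t) == length(U))
  tt <- seq(min(t), max(t), by = dt_resample)
  pr <- stats::approx(t, p, tt)$y
  Ur <- stats::approx(t, U, tt)$y
  inc <- wia_increments(pr, Ur, window = window, order = order,
                        smoothing = smoothing)
  if (is.null(c)) c <- pu_wave_speed(inc$dp, inc$dU, rho)
  sep <- wia_separate(inc$dp, inc$dU, rho, c)
  records <- classify_waves(sep, tt, thresh_frac, merge_gap_s)
  pa <- if (nrow(records)) percent_areas(records)
  else list(percent = numeric(), groups = numeric())
  structure(list(t = tt, p = pr, U = Ur, dp = inc$dp, dU = inc$dU,
                 dI = wave_intensity(inc$dp, inc$dU), sep = sep,
                 rho = rho, c = c, records = records,
                 percent = pa$percent, groups = pa$groups),
            class = "cwia")
}

#' @export
print.cwia <- function(x, ...) {
  cat("Coronary wave intensity analysis\n")
  cat(sprintf("  separation wave speed: %.0f mm/s; %d waves detected\n",
              x$c, nrow(x$records)))
  if (nrow(x$records)) {
    df <- x$records
    df$pct <- x$percent[df$label]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-9s %-8s %-7s  [%.3f, %.3f] s  %5.1f %%\n",
                  df$label[i], df$direction[i], df$kind[i],
                  df$t_start[i], df$t_end[i], df$pct[i]))
    cat(sprintf("  groups: forward %.1f%% backward %.1f%% | contraction %.1f%% relaxation %.1f%%\n",
                x$groups["forward"], x$groups["backward"],
                x$groups["contraction"], x$groups["relaxation"]))
  }
  invisible(x)
}

#' @export
summary.cwia <- function(object, ...) {
  list(percent = object$percent, groups = object$groups,
       n_waves = nrow(object$records), c = object$c)
}

#' @export
plot.cwia <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$p, type = "l", xlab = "t (s)", ylab = "p (kPa)",
                 ...)
  graphics::plot(x$t, x$sep$dIp, type = "l", col = "blue",
                 ylim = range(c(x$sep$dIp, x$sep$dIm)), xlab = "t (s)",
                 ylab = "dI+/- per sample")
  graphics::lines(x$t, x$sep$dIm, col = "red")
  if (nrow(x$records))
    graphics::abline(v = x$records$t_start, lty = 3, col = "grey")
  invisible(x)
}

#' Read a standalone (t, p, U) trace from CSV
#'
#' Expects columns `t`, `p`, `U` (s, kPa, mm/s).
#'
#' @param file CSV path.
#' @return Data frame with `t`, `p`, `U`.
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  stopifnot(all(c("t", "p", "U") %in% names(df)))
  df
}
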