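#' Construct a force-displacement curve
#'
#' The common currency of the mechanical test and the FE solve: ordered
#' displacement samples (mm, strictly increasing) with the corresponding
#' total force (N).
#'
#' @param displacement Numeric, strictly increasing (mm).
#' @param force Numeric, same length (N).
#' @param source `"mechanical"` or `"fea"`.
#' @return A tibble of class `fd_curve` with columns `displacement`,
#'   `force` and a `source` attribute.
#' @export
fd_curve <- function(displacement, force, source = c("mechanical", "fea")) {
  source <- match.arg(source)
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force) || length(force) < 3L) {
    stop("curve needs matching displacement/force of length >= 3",
         call. = FALSE)
  }
  if (any(diff(displacement) <= 0)) {
    stop("displacement must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(displacement = displacement, force = force)
  attr(out, "source") <- source
  class(out) <- c("fd_curve", class(out))
  out
}

curve_source <- function(curve) attr(curve, "source") %||% "mechanical"

#' Read / write force-displacement curves as CSV
#' @param path CSV with columns `displacement_mm`, `force_N`.
#' @param source Curve source tag for [fd_curve()].
#' @return An [fd_curve()] (read); `path` (write).
#' @export
read_curve_csv <- function(path, source = "mechanical") {
  df <- utils::read.csv(path)
  fd_curve(df$displacement_mm, df$force_N, source = source)
}

#' @rdname read_curve_csv
#' @param curve An [fd_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(displacement_mm = curve$displacement, force_N = curve$force),
    path, row.names = FALSE
  )
  invisible(path)
}

## ---- stiffness and fracture detection ------------------------------------

#' Structural stiffness from the 20-80% force window
#'
#' Least-squares slope of force against displacement over the samples whose
#' force lies between 20% and 80% of the fracture load — the window used to
#' report stiffness from quasi-static femur compression tests.
#'
#' @param curve An [fd_curve()].
#' @param fracture_load Maximum (fracture) load in N defining the window.
#' @return Stiffness in N/mm.
#' @export
stiffness_20_80 <- function(curve, fracture_load) {
  w <- which(curve$force >= 0.2 * fracture_load &
               curve$force <= 0.8 * fracture_load)
  if (length(w) < 2L) {
    stop("fewer than 2 samples between 20% and 80% of the fracture load; ",
         "record the curve with denser sampling", call. = FALSE)
  }
  x <- curve$displacement[w]
  y <- curve$force[w]
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# reference (initial linear segment) stiffness: grow the fit while each new
# forward tangent stays within 5% of the running fit; at least 3 samples
reference_stiffness <- function(d, f, min_pts = 3L) {
  n <- length(d)
  tangents <- diff(f) / diff(d)
  k <- min_pts
  while (k < n) {
    run <- stats::coef(stats::lm(f[1:k] ~ d[1:k]))[2]
    if (abs(tangents[k] - run) > 0.05 * abs(run)) break
    k <- k + 1L
  }
  list(
    slope = unname(stats::coef(stats::lm(f[1:k] ~ d[1:k]))[2]),
    n_used = k
  )
}

# shared detector core: first segment whose tangent falls below the
# threshold and stays below at the next segment too (or is the last
# segment) - the persistence guard keeps single-segment noise spikes from
# firing the detector. Fracture is reported at the segment's start sample.
detect_tangent_drop <- function(d, f, drop_fraction, reference,
                                min_index = 1L, max_index = Inf) {
  tangents <- diff(f) / diff(d)
  thr <- (1 - drop_fraction) * reference
  below <- tangents < thr
  n <- length(below)
  persistent <- below & (c(below[-1], TRUE))
  cand <- which(persistent)
  cand <- cand[cand >= min_index & cand <= max_index]
  if (length(cand) == 0L) {
    return(list(index = NA_integer_, reference = reference))
  }
  list(index = cand[1], reference = reference)
}

new_fracture_metrics <- function(fracture_load, stiffness, reference,
                                 index, method, curve) {
  structure(
    list(fracture_load = fracture_load, stiffness = stiffness,
         reference_stiffness = reference, detection_index = index,
         method = method, curve = curve),
    class = "fracture_metrics"
  )
}

#' @export
print.fracture_metrics <- function(x, ...) {
  cat(sprintf(
    "<fracture_metrics> %s: fracture load %.4g N at sample %d, stiffness %.4g N/mm\n",
    x$method, x$fracture_load, x$detection_index, x$stiffness
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fracture_metrics <- function(x, ...) {
  tibble::tibble(
    method = x$method, fracture_load = x$fracture_load,
    stiffness = x$stiffness, reference_stiffness = x$reference_stiffness,
    detection_index = x$detection_index
  )
}

#' Fracture load from an FE-predicted curve
#'
#' The predicted fracture load is the force at which the curve's tangent
#' stiffness has declined by more than `drop_fraction` (default 20%) of the
#' reference stiffness, where the reference is the least-squares slope of
#' the initial linear segment (samples kept while each forward tangent
#' stays within 5% of the running fit, minimum 3).
#'
#' @param curve An [fd_curve()].
#' @param drop_fraction Tangent-drop threshold (default 0.2).
#' @return A `fracture_metrics` object (fracture load, the 20-80% window
#'   stiffness, reference stiffness, detection index).
#' @export
fracture_load_fea <- function(curve, drop_fraction = 0.2) {
  if (nrow(curve) < 4L) stop("need at least 4 samples", call. = FALSE)
  ref <- reference_stiffness(curve$displacement, curve$force)
  det <- detect_tangent_drop(curve$displacement, curve$force, drop_fraction,
                             reference = ref$slope,
                             min_index = ref$n_used - 1L)
  if (is.na(det$index)) {
    cond <- structure(
      class = c("femstrength_no_fracture", "error", "condition"),
      list(message = "no fracture detected: tangent stiffness never dropped below threshold",
           call = sys.call(-1), curve = curve)
    )
    stop(cond)
  }
  fl <- curve$force[det$index]
  new_fracture_metrics(
    fracture_load = fl,
    stiffness = stiffness_20_80(curve, fl),
    reference = det$reference,
    index = det$index,
    method = "fea_20pct",
    curve = curve
  )
}

#' Fracture load from a mechanical test recording
#'
#' Identifies mechanical fracture where the curve slope rapidly decreases,
#' operationalised as the FE detector's >20% tangent-drop rule made robust
#' to load-cell noise: the force signal is moving-average smoothed, the
#' reference stiffness is the least-squares slope over the samples between
#' 20% and 80% of the provisional peak (pooling many samples instead of a
#' short initial segment), the drop must persist for two consecutive
#' segments, and the reported load is then refined as the intersection of
#' the pre-drop and post-drop least-squares lines - on a noise-free
#' bilinear recording this returns the knee load exactly, and under noise
#' it averages over many samples instead of quantising to one. Pick
#' `smooth_window` so it spans a few percent of the loading stroke when
#' the recording is densely sampled.
#'
#' @param curve An [fd_curve()].
#' @param drop_fraction Tangent-drop threshold (default 0.2).
#' @param smooth_window Moving-average window in samples (default 5).
#' @return A `fracture_metrics` object.
#' @export
fracture_load_mechanical <- function(curve, drop_fraction = 0.2,
                                     smooth_window = 5L) {
  if (nrow(curve) < 4L) stop("need at least 4 samples", call. = FALSE)
  n <- nrow(curve)
  d <- curve$displacement
  f <- curve$force
  hw <- 0L
  if (smooth_window > 1L && n > smooth_window) {
    sm <- stats::filter(f, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    f <- ifelse(is.na(sm), f, as.vector(sm))
    # the filter leaves the first/last half-window unsmoothed; their raw
    # tangents must not fire the detector
    hw <- smooth_window %/% 2L
  }
  peak <- max(f)
  w <- which(f >= 0.2 * peak & f <= 0.8 * peak)
  pre_fit <- if (length(w) >= 2L) {
    stats::coef(stats::lm(f[w] ~ d[w]))
  } else {
    c(0, reference_stiffness(d, f)$slope)
  }
  ref_slope <- unname(pre_fit[2])
  det <- detect_tangent_drop(d, f, drop_fraction, reference = ref_slope,
                             min_index = hw + 1L,
                             max_index = n - 1L - hw)
  if (is.na(det$index)) {
    cond <- structure(
      class = c("femstrength_no_fracture", "error", "condition"),
      list(message = "no fracture detected: tangent stiffness never dropped below threshold",
           call = sys.call(-1), curve = curve)
    )
    stop(cond)
  }
  # refine: intersect the pre-drop line with the post-drop line; the
  # pre-drop fit re-restricts the 20-80% window to samples before the
  # detected drop so post-knee samples cannot tilt it
  pre_idx <- w[w <= det$index - hw] # half-window clear of the knee blur
  if (length(pre_idx) >= 2L) {
    pre_fit <- stats::coef(stats::lm(f[pre_idx] ~ d[pre_idx]))
  }
  post_idx <- seq.int(min(det$index + hw + 1L, n), n)
  fl <- f[det$index]
  idx <- det$index
  if (length(post_idx) >= 3L) {
    post_fit <- stats::coef(stats::lm(f[post_idx] ~ d[post_idx]))
    if (is.finite(post_fit[2]) && abs(pre_fit[2] - post_fit[2]) > 1e-12) {
      d_star <- (post_fit[1] - pre_fit[1]) / (pre_fit[2] - post_fit[2])
      if (d_star >= d[1] && d_star <= d[n]) {
        fl <- unname(pre_fit[1] + pre_fit[2] * d_star)
        idx <- which.min(abs(d - d_star))
      }
    }
  }
  new_fracture_metrics(
    fracture_load = fl,
    stiffness = stiffness_20_80(curve, fl),
    reference = ref_slope,
    index = idx,
    method = "mech_rapid_drop",
    curve = curve
  )
}

#' Plot a force-displacement curve
#'
#' @param object An [fd_curve()].
#' @param metrics Optional `fracture_metrics` to annotate the detected
#'   fracture point.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_curve <- function(object, metrics = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$displacement, y = .data$force)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Displacement (mm)", y = "Force (N)",
                  title = sprintf("Force-displacement (%s)",
                                  curve_source(object)))
  if (!is.null(metrics)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$displacement[metrics$detection_index],
      linetype = "dashed", colour = "firebrick"
    ) +
      ggplot2::geom_hline(yintercept = metrics$fracture_load,
                          linetype = "dotted", colour = "firebrick")
  }
  p
}
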