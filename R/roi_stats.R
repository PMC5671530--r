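#' Collect principal stresses over an ROI
#'
#' One maximum and one minimum principal stress sample per ROI element
#' (element-count weighting; an area-weighted variant is available for
#' sensitivity checks via `weights`).
#'
#' @param stress ne x 4 element stress matrix, or a `macro_solution`.
#' @param roi integer vector of element indices.
#' @return list with numeric vectors `sigma_max` and `sigma_min` (MPa)
#'   and, as an attribute, the element indices used.
#' @export
collect_roi_stresses <- function(stress, roi) {
  if (inherits(stress, "macro_solution")) stress <- stress$stress
  roi <- as.integer(roi)
  if (length(roi) == 0) stop("empty ROI")
  if (any(roi < 1L) || any(roi > nrow(stress)))
    stop("ROI indices outside the stress field")
  pr <- principal_stresses(stress[roi, , drop = FALSE])
  structure(list(sigma_max = pr[, 1], sigma_min = pr[, 3]), roi = roi)
}

#' Histogram of a stress sample
#'
#' Frequency histogram used to extract the highest-probability (modal)
#' stress. The bin rule defaults to Freedman-Diaconis with a fallback to
#' 20 uniform bins when the IQR is degenerate or the sample tiny.
#'
#' @param samples numeric vector of stresses (MPa).
#' @param bin_rule `"fd"` (Freedman-Diaconis) or a positive integer bin
#'   count.
#' @return object of class `stress_histogram`: `bin_edges`, `counts`,
#'   `mode`, `n_samples`.
#' @export
stress_histogram <- function(samples, bin_rule = "fd") {
  n <- length(samples)
  if (n < 1) stop("need at least one sample")
  rng <- range(samples)
  if (diff(rng) == 0) {
    h <- structure(list(bin_edges = rng + c(-0.5, 0.5) * max(1e-12, abs(rng[1]) * 1e-6),
                        counts = n, mode = rng[1], n_samples = n),
                   class = "stress_histogram")
    return(h)
  }
  nb <- if (identical(bin_rule, "fd")) {
    bw <- 2 * stats::IQR(samples) / n^(1 / 3)
    if (bw <= 0) 20L else max(1L, min(200L, ceiling(diff(rng) / bw)))
  } else {
    stopifnot(is.numeric(bin_rule), bin_rule >= 1)
    as.integer(bin_rule)
  }
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  ix <- pmin(nb, pmax(1L, findInterval(samples, edges, rightmost.closed = TRUE)))
  counts <- tabulate(ix, nbins = nb)
  ctr <- (edges[-1] + edges[-(nb + 1L)]) / 2
  best <- which(counts == max(counts))
  mode <- ctr[best[which.min(abs(ctr[best]))]]  # ties -> smaller |stress|
  structure(list(bin_edges = edges, counts = counts, mode = mode,
                 n_samples = n),
            class = "stress_histogram")
}

#' @export
print.stress_histogram <- function(x, ...) {
  cat(sprintf(
    "<stress_histogram> n = %d, %d bins, mode = %.5g MPa\n",
    x$n_samples, length(x$counts), x$mode))
  invisible(x)
}

#' Modal (highest-probability) stress
#'
#' Centre of the highest-count histogram bin; ties are broken towards the
#' bin of smaller absolute stress. The modal maximum/minimum principal
#' stresses of an ROI become the far-field boundary conditions of the
#' capillary structural model.
#'
#' @inheritParams stress_histogram
#' @return stress (MPa).
#' @export
modal_stress <- function(samples, bin_rule = "fd") {
  stress_histogram(samples, bin_rule)$mode
}

#' Modal principal-stress pair for each ROI layer
#'
#' @param sol a `macro_solution` (or ne x 4 stress matrix).
#' @param rois named list of ROI element-index vectors from
#'   [define_roi_layers()].
#' @param bin_rule passed to [stress_histogram()].
#' @return named list; per ROI a list with `sigma_max`, `sigma_min`
#'   (modal values, MPa), the two `stress_histogram`s and the sample size.
#' @export
roi_modal_stresses <- function(sol, rois, bin_rule = "fd") {
  lapply(rois, function(roi) {
    s <- collect_roi_stresses(sol, roi)
    hmax <- stress_histogram(s$sigma_max, bin_rule)
    hmin <- stress_histogram(s$sigma_min, bin_rule)
    list(sigma_max = hmax$mode, sigma_min = hmin$mode,
         hist_max = hmax, hist_min = hmin, n = hmax$n_samples)
  })
}
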