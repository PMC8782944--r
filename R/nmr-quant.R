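#' Exponential apodization (line broadening)
#'
#' Multiplies point k by exp(-pi * lb_hz * t_k), adding `lb_hz` to every
#' Lorentzian linewidth. Default 0.3 Hz. Resolution enhancement (negative
#' lb) is out of scope.
#'
#' @param fid an [new_fid()] object.
#' @param lb_hz line-broadening factor in Hz, >= 0.
#' @return apodized fid, metadata unchanged.
#' @export
apodize <- function(fid, lb_hz = 0.3) {
  stopifnot(inherits(fid, "fid"))
  if (!is.numeric(lb_hz) || length(lb_hz) != 1L || lb_hz < 0)
    stop("lb_hz must be a single number >= 0")
  if (lb_hz == 0) return(fid)
  n <- length(fid$points)
  t <- (seq_len(n) - 1) * fid$aq_s / n
  fid$points <- fid$points * exp(-pi * lb_hz * t)
  fid
}

#' Fourier transform an FID into a spectrum
#'
#' Discrete Fourier transform with the frequency axis converted to a
#' monotone increasing ppm axis via the spectrometer frequency, centred on
#' the carrier. The first time-domain point is halved before the
#' transform -- the standard convention that removes the constant
#' vertical offset (sum of amplitudes / 2) a plain DFT of a causal decay
#' would add to every spectral point. The intensity is complex pending
#' phase correction.
#'
#' @param fid an fid object.
#' @param first_point_half logical; disable to obtain the raw DFT.
#' @return object of class "spectrum" with fields ppm, intensity
#'   (complex), referenced = FALSE.
#' @export
nmr_transform <- function(fid, first_point_half = TRUE) {
  stopifnot(inherits(fid, "fid"))
  n <- length(fid$points)
  pts <- fid$points
  if (first_point_half) pts[1] <- pts[1] / 2
  sp <- stats::fft(pts)
  ## fftshift: ascending frequency -sw/2 .. sw/2
  idx <- c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))
  sp <- sp[idx]
  dt <- fid$aq_s / n
  f <- (seq_len(n) - 1 - floor(n / 2)) / (n * dt)
  structure(list(ppm = fid$carrier_ppm + f / fid$sfrq_mhz,
                 intensity = sp,
                 referenced = FALSE,
                 sfrq_mhz = fid$sfrq_mhz),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points | %.3f .. %.3f ppm | %s\n",
              length(x$ppm), min(x$ppm), max(x$ppm),
              if (x$referenced) "referenced" else "unreferenced"))
  invisible(x)
}

## negative-intensity criterion used by automatic phasing
.phase_objective <- function(par, sp) {
  n <- length(sp)
  ph <- par[1] + par[2] * (seq_len(n) - 1) / n
  re <- Re(sp * exp(1i * ph))
  neg <- re[re < 0]
  sum(neg^2)
}

.apply_phase <- function(sp, par) {
  n <- length(sp)
  sp * exp(1i * (par[1] + par[2] * (seq_len(n) - 1) / n))
}

#' Phase, baseline-correct and reference a spectrum
#'
#' Zero- and first-order phase are chosen automatically by minimizing the
#' integrated squared negative intensity (coarse zero-order grid followed
#' by Nelder-Mead refinement; the identity is kept when it is already
#' optimal). The baseline is estimated by an iterative low-order
#' polynomial fit over putative signal-free points (those below a rolling
#' quantile) and subtracted. Finally the axis is shifted so the TSP apex
#' sits at 0 ppm and the referenced flag is set.
#'
#' @param spectrum unreferenced spectrum containing a TSP resonance.
#' @param baseline_degree polynomial degree (<= 3) for the baseline model.
#' @param baseline_min_frac negligibility gate: the fitted baseline is
#'   only subtracted when its largest excursion exceeds this fraction of
#'   the spectrum maximum (default 1e-3). Keeps the correction an exact
#'   identity on clean spectra, where the fit only chases Lorentzian
#'   tails.
#' @param tsp_search_ppm half-width of the window around the nominal TSP
#'   position searched for the apex.
#' @param phase logical; set FALSE to skip automatic phasing.
#' @param baseline logical; set FALSE to skip baseline subtraction.
#' @return referenced spectrum with real (absorption) intensity.
#' @export
correct_spectrum <- function(spectrum, baseline_degree = 3,
                             baseline_min_frac = 1e-3,
                             tsp_search_ppm = 0.3,
                             phase = TRUE, baseline = TRUE) {
  stopifnot(inherits(spectrum, "spectrum"))
  sp <- spectrum$intensity
  if (phase) {
    ## coarse grid on zero-order phase, then simplex refinement
    grid <- seq(-pi, pi, length.out = 37)
    obj0 <- vapply(grid, function(p) .phase_objective(c(p, 0), sp), 0)
    start <- c(grid[which.min(obj0)], 0)
    opt <- stats::optim(start, .phase_objective, sp = sp,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    scale <- sum(Mod(sp)^2)
    if (.phase_objective(c(0, 0), sp) <= opt$value + 1e-12 * scale) {
      par <- c(0, 0)                      # identity already optimal
    } else {
      par <- opt$par
    }
    sp <- .apply_phase(sp, par)
  }
  intensity <- Re(sp)
  if (baseline) {
    fit <- .estimate_baseline(intensity, baseline_degree)
    if (max(abs(fit)) > baseline_min_frac * max(abs(intensity)))
      intensity <- intensity - fit
  }
  ## reference: locate TSP apex near its nominal position
  out <- structure(list(ppm = spectrum$ppm, intensity = intensity,
                        referenced = FALSE, sfrq_mhz = spectrum$sfrq_mhz),
                   class = "spectrum")
  win <- which(abs(out$ppm) <= tsp_search_ppm)
  if (!length(win)) stop("referencing error: 0 ppm outside spectral window")
  apex <- win[which.max(out$intensity[win])]
  noise <- stats::mad(out$intensity) + 1e-300
  if (out$intensity[apex] < stats::median(out$intensity) + 5 * noise)
    stop("referencing error: no detectable TSP peak near 0 ppm")
  out$ppm <- out$ppm - out$ppm[apex]
  out$referenced <- TRUE
  out
}

## iterative polynomial baseline over points below a rolling quantile;
## selection uses relative thresholds only, so it is scale-invariant
.estimate_baseline <- function(y, degree = 3, n_windows = 64,
                               quantile = 0.3, n_iter = 3) {
  n <- length(y)
  degree <- min(degree, 3L)
  win <- cut(seq_len(n), breaks = n_windows, labels = FALSE)
  sel <- unlist(lapply(split(seq_len(n), win), function(ix) {
    thr <- stats::quantile(y[ix], quantile)
    ix[y[ix] <= thr]
  }), use.names = FALSE)
  x <- (seq_len(n) - n / 2) / n
  fit <- rep(0, n)
  X_full <- cbind(1, stats::poly(x, degree, raw = TRUE, simple = TRUE))
  for (it in seq_len(n_iter)) {
    co <- stats::lm.fit(X_full[sel, , drop = FALSE], y[sel])$coefficients
    fit <- drop(X_full %*% ifelse(is.na(co), 0, co))
    resid <- y - fit
    s <- stats::mad(resid[sel]) + 1e-300
    sel <- which(resid <= 2 * s)
    if (length(sel) < 4 * (degree + 1)) break
  }
  fit
}

#' Construct integration regions from a peak library
#'
#' @param library peak library data.frame.
#' @param halfwidth_ppm half-width of each region around the peak centre.
#' @return region data.frame: metabolite, ppm_low, ppm_high, protons,
#'   is_glycogen.
#' @export
regions_from_library <- function(library, halfwidth_ppm = 0.04) {
  validate_peak_library(library)
  reg <- data.frame(metabolite = library$metabolite,
                    ppm_low = library$center_ppm - halfwidth_ppm,
                    ppm_high = library$center_ppm + halfwidth_ppm,
                    protons = library$protons,
                    is_glycogen = library$metabolite == "glycogen")
  validate_regions(reg)
  reg
}

#' Validate an integration region set
#' @param regions region data.frame.
#' @param allow_overlap logical; overlapping regions are an error unless
#'   TRUE.
#' @return the regions, invisibly.
#' @export
validate_regions <- function(regions, allow_overlap = FALSE) {
  stopifnot(is.data.frame(regions),
            all(c("metabolite", "ppm_low", "ppm_high",
                  "protons") %in% names(regions)))
  if (is.null(regions$is_glycogen)) regions$is_glycogen <- FALSE
  if (any(regions$ppm_low >= regions$ppm_high))
    stop("each region must satisfy ppm_low < ppm_high")
  if (any(regions$protons < 1)) stop("protons must be >= 1")
  if (!allow_overlap && nrow(regions) > 1) {
    o <- order(regions$ppm_low)
    lo <- regions$ppm_low[o]; hi <- regions$ppm_high[o]
    if (any(lo[-1] < hi[-length(hi)]))
      stop("integration regions overlap; pass allow_overlap = TRUE ",
           "to permit this")
  }
  invisible(regions)
}

#' Read / write a region definition file
#'
#' Plain CSV `metabolite, ppm_low, ppm_high, protons, is_glycogen` --
#' the analogue of a pre-written integration region text file.
#' @param path file path.
#' @param regions region data.frame.
#' @export
read_regions <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_regions(reg)
  reg
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  utils::write.csv(regions, path, row.names = FALSE)
  invisible(path)
}

#' Integrate spectral regions
#'
#' Trapezoidal area of the (phased, referenced) intensity over each
#' region. Negative areas -- possible over pure-noise floors -- are
#' clipped at zero and the clipping is logged.
#'
#' @param spectrum referenced spectrum.
#' @param regions region data.frame.
#' @return named numeric vector of areas (one per metabolite).
#' @export
integrate_regions <- function(spectrum, regions) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (!spectrum$referenced)
    stop("spectrum must be referenced before integration")
  validate_regions(regions, allow_overlap = TRUE)
  ppm <- spectrum$ppm
  y <- Re(spectrum$intensity)
  out <- stats::setNames(numeric(nrow(regions)), regions$metabolite)
  for (i in seq_len(nrow(regions))) {
    lo <- regions$ppm_low[i]; hi <- regions$ppm_high[i]
    if (lo < min(ppm) || hi > max(ppm))
      stop(sprintf("region '%s' [%g, %g] outside spectral axis range",
                   regions$metabolite[i], lo, hi))
    ## interior grid points plus interpolated values at the exact
    ## bounds, so adjacent regions tile exactly (split additivity)
    ix <- which(ppm > lo & ppm < hi)
    ends <- stats::approx(ppm, y, xout = c(lo, hi))$y
    xs <- c(lo, ppm[ix], hi)
    ys <- c(ends[1], y[ix], ends[2])
    a <- sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
    if (a < 0) {
      cm_log("nmr_quant", "info",
             sprintf("negative area clipped to 0 for region '%s'",
                     regions$metabolite[i]), area = a)
      a <- 0
    }
    out[i] <- a
  }
  out
}

#' Quantify metabolite concentrations from region areas
#'
#' Areas are normalized to the TSP peak (9 equivalent protons) and scaled
#' by the known TSP amount and the tissue wet weight:
#' `conc_m = (area_m / area_TSP) * (9 / protons_m) * tsp_nmol / wet_weight_g`.
#' Glycogen regions skip the proton division and are reported as mobile-1H
#' glucosyl-equivalents normalized to TSP. TSP itself is excluded from the
#' output.
#'
#' @param areas named vector from [integrate_regions()], containing "TSP".
#' @param regions region data.frame (for proton counts and glycogen flag).
#' @param tsp_nmol amount of TSP reference in the sample.
#' @param wet_weight_g tissue wet weight in grams.
#' @param sample_id optional sample identifier carried into the result.
#' @return data.frame with one row per metabolite: sample_id, metabolite,
#'   concentration.
#' @export
quantify <- function(areas, regions, tsp_nmol, wet_weight_g,
                     sample_id = NA_character_) {
  validate_regions(regions, allow_overlap = TRUE)
  if (!"TSP" %in% names(areas)) stop("TSP area missing: reference lost")
  a_tsp <- areas[["TSP"]]
  if (!is.finite(a_tsp) || a_tsp <= 0)
    stop("TSP area must be > 0: reference lost")
  .check_scalar_num(tsp_nmol, "tsp_nmol", 0, strict_lower = TRUE)
  .check_scalar_num(wet_weight_g, "wet_weight_g", 0, strict_lower = TRUE)
  keep <- setdiff(names(areas), "TSP")
  reg <- regions[match(keep, regions$metabolite), , drop = FALSE]
  protons <- ifelse(reg$is_glycogen, 1, reg$protons)
  conc <- (areas[keep] / a_tsp) * (9 / protons) * tsp_nmol / wet_weight_g
  data.frame(sample_id = sample_id, metabolite = keep,
             concentration = unname(conc), row.names = NULL)
}

#' Full quantification chain for one FID
#'
#' apodize -> Fourier transform -> phase/baseline/reference -> integrate
#' -> quantify, with the processing defaults of the pipeline (0.3 Hz
#' exponential line broadening, automatic phase and baseline correction,
#' TSP referencing).
#'
#' @inheritParams apodize
#' @inheritParams quantify
#' @param regions region data.frame including a TSP region.
#' @param lb_hz exponential line broadening (Hz).
#' @param ... passed to [correct_spectrum()].
#' @return data.frame as from [quantify()].
#' @export
nmr_quantify <- function(fid, regions, tsp_nmol, wet_weight_g,
                         lb_hz = 0.3, sample_id = NA_character_, ...) {
  sp <- correct_spectrum(nmr_transform(apodize(fid, lb_hz)), ...)
  areas <- integrate_regions(sp, regions)
  quantify(areas, regions, tsp_nmol, wet_weight_g, sample_id)
}
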