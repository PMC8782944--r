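#' Default 1H peak library
#'
#' One singlet per metabolite at its canonical chemical shift, chosen to
#' be non-overlapping at 600 MHz with 1 Hz natural linewidths. TSP sits at
#' 0 ppm with 9 equivalent protons and anchors both referencing and
#' quantification. Equal linewidths mean the finite-region truncation of
#' the Lorentzian tails cancels exactly in the area ratio to TSP.
#'
#' @return data.frame with columns metabolite, center_ppm, protons,
#'   linewidth_hz.
#' @export
default_peak_library <- function() {
  lib <- data.frame(
    metabolite = c("TSP", "lactate", "alanine", "acetate", "glutamate",
                   "succinate", "citrate", "aspartate", "creatine",
                   "choline", "glycine", "glucose", "fumarate"),
    center_ppm = c(0.00, 1.33, 1.48, 1.92, 2.08,
                   2.41, 2.54, 2.68, 3.03,
                   3.20, 3.56, 5.23, 6.52),
    protons = c(9, 3, 3, 3, 2, 4, 2, 1, 3, 9, 2, 1, 2),
    linewidth_hz = 1.0)
  validate_peak_library(lib)
  lib
}

#' Validate a peak library
#' @param lib data.frame with metabolite, center_ppm, protons, linewidth_hz.
#' @return the library, invisibly, or an error.
#' @export
validate_peak_library <- function(lib) {
  stopifnot(is.data.frame(lib),
            all(c("metabolite", "center_ppm", "protons",
                  "linewidth_hz") %in% names(lib)))
  if (any(lib$protons < 1)) stop("protons must be >= 1")
  if (any(lib$linewidth_hz <= 0)) stop("linewidth_hz must be > 0")
  if ("TSP" %in% lib$metabolite &&
      abs(lib$center_ppm[lib$metabolite == "TSP"]) > 1e-12)
    stop("TSP entry must sit at 0 ppm")
  invisible(lib)
}

#' Construct a free induction decay object
#'
#' @param points complex vector of time-domain points.
#' @param sfrq_mhz spectrometer 1H frequency (MHz).
#' @param sweep_ppm spectral width (ppm).
#' @param aq_s acquisition time (s); must satisfy
#'   `aq_s = npoints / (sweep_ppm * sfrq_mhz)` (dwell-time consistency).
#' @param carrier_ppm transmitter offset on the ppm axis (default 4.7,
#'   the water resonance).
#' @return object of class "fid".
#' @export
new_fid <- function(points, sfrq_mhz, sweep_ppm, aq_s, carrier_ppm = 4.7) {
  if (length(points) < 2L) stop("FID needs at least 2 points")
  .check_scalar_num(sfrq_mhz, "sfrq_mhz", 0, strict_lower = TRUE)
  .check_scalar_num(sweep_ppm, "sweep_ppm", 0, strict_lower = TRUE)
  sw_hz <- sweep_ppm * sfrq_mhz
  dwell <- aq_s / length(points)
  if (abs(dwell * sw_hz - 1) > 1e-6)
    stop("inconsistent FID: dwell time aq_s/npoints must equal 1/sweep_hz")
  structure(list(points = as.complex(points), sfrq_mhz = sfrq_mhz,
                 sweep_ppm = sweep_ppm, aq_s = aq_s,
                 carrier_ppm = carrier_ppm),
            class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid> %d points | %.1f MHz | %.1f ppm sweep | aq %.3g s\n",
              length(x$points), x$sfrq_mhz, x$sweep_ppm, x$aq_s))
  invisible(x)
}

#' Default acquisition settings
#'
#' 600 MHz spectrometer, 20 ppm sweep width, 2.6 s acquisition time; the
#' number of points follows from the dwell time.
#' @return list(sfrq_mhz, sweep_ppm, aq_s, carrier_ppm, npoints)
#' @export
default_acquisition <- function() {
  sfrq <- 600; sweep <- 20; aq <- 2.6
  list(sfrq_mhz = sfrq, sweep_ppm = sweep, aq_s = aq, carrier_ppm = 4.7,
       npoints = as.integer(round(aq * sweep * sfrq)))
}

#' Simulate a raw FID from known metabolite content
#'
#' Each library peak contributes a complex exponential with amplitude
#' proportional to concentration x protons, frequency set by its chemical
#' shift relative to the carrier, and exponential decay from its natural
#' linewidth; optional white complex noise is added on top. Zero phase by
#' construction.
#'
#' @param concentrations named vector, umol/g (must include "TSP", the
#'   quantification reference, in the same amount units).
#' @param library peak library (see [default_peak_library()]).
#' @param acquisition list as from [default_acquisition()].
#' @param noise_sd standard deviation of the complex white noise per
#'   quadrature channel (0 = noiseless).
#' @param seed integer seed for the noise.
#' @return an [new_fid()] object.
#' @export
generate_fid <- function(concentrations, library = default_peak_library(),
                         acquisition = default_acquisition(),
                         noise_sd = 0, seed = 1L) {
  validate_peak_library(library)
  if (!"TSP" %in% names(concentrations) || !"TSP" %in% library$metabolite)
    stop("TSP must be present in both concentrations and library: ",
         "quantification reference absent")
  .check_scalar_num(noise_sd, "noise_sd", 0)
  n <- acquisition$npoints
  t <- (seq_len(n) - 1) / (acquisition$sweep_ppm * acquisition$sfrq_mhz)
  sig <- complex(real = numeric(n), imaginary = numeric(n))
  lib <- library[library$metabolite %in% names(concentrations), , drop = FALSE]
  for (i in seq_len(nrow(lib))) {
    conc <- concentrations[[lib$metabolite[i]]]
    if (conc == 0) next
    amp <- conc * lib$protons[i]
    f_hz <- (lib$center_ppm[i] - acquisition$carrier_ppm) * acquisition$sfrq_mhz
    sig <- sig + amp * exp((2i * pi * f_hz - pi * lib$linewidth_hz[i]) * t)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + complex(real = stats::rnorm(n, 0, noise_sd),
                         imaginary = stats::rnorm(n, 0, noise_sd))
  }
  new_fid(sig, acquisition$sfrq_mhz, acquisition$sweep_ppm,
          n / (acquisition$sweep_ppm * acquisition$sfrq_mhz),
          acquisition$carrier_ppm)
}

#' Write / read an FID as plain text
#'
#' Header lines `# key value` carry the acquisition metadata, followed by
#' CSV rows `index,real,imag`.
#'
#' @param fid an fid object.
#' @param path file path.
#' @return `read_fid` returns an fid object; `write_fid` the path,
#'   invisibly.
#' @export
write_fid <- function(fid, path) {
  stopifnot(inherits(fid, "fid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sfrq_mhz %.10g", fid$sfrq_mhz),
               sprintf("# sweep_ppm %.10g", fid$sweep_ppm),
               sprintf("# npoints %d", length(fid$points)),
               sprintf("# aq_s %.10g", fid$aq_s),
               sprintf("# carrier_ppm %.10g", fid$carrier_ppm)), con)
  utils::write.table(data.frame(index = seq_along(fid$points) - 1L,
                                real = Re(fid$points),
                                imag = Im(fid$points)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    meta[[parts[1]]] <- as.numeric(parts[2])
  }
  dat <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                             invert = TRUE)),
                         header = FALSE,
                         col.names = c("index", "real", "imag"))
  new_fid(complex(real = dat$real, imaginary = dat$imag),
          meta$sfrq_mhz, meta$sweep_ppm, meta$aq_s,
          if (!is.null(meta$carrier_ppm)) meta$carrier_ppm else 4.7)
}
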