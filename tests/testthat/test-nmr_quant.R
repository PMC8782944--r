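make_fid <- function(conc = c(TSP = 5, lactate = 2, glucose = 4),
                     noise_sd = 0, aq_s = 0.65) {
  acq <- list(sfrq_mhz = 600, sweep_ppm = 20, aq_s = aq_s,
              carrier_ppm = 4.7,
              npoints = as.integer(round(aq_s * 20 * 600)))
  generate_fid(conc, tiny_library(), acq, noise_sd = noise_sd, seed = 4)
}

test_that("apodization has its closed form and rejects negative lb", {
  fid <- make_fid()
  expect_identical(apodize(fid, 0), fid)
  ## constant unit signal: last point scaled by exp(-pi*lb*t_last)
  const <- new_fid(rep(1 + 0i, 1000), 600, 20, 1000 / 12000)
  ap <- apodize(const, 0.3)
  t_last <- 999 * const$aq_s / 1000
  expect_equal(Re(ap$points[1000]), exp(-pi * 0.3 * t_last),
               tolerance = 1e-12)
  expect_equal(Re(ap$points[1]), 1)
  expect_error(apodize(fid, -0.1), ">= 0")
})

test_that("apodization broadens a Lorentzian by the lb factor", {
  ## half-width at half maximum of an absorption Lorentzian is lw/2;
  ## fit the spectral FWHM before and after 2 Hz broadening
  fwhm_of <- function(lb) {
    sp <- nmr_transform(apodize(make_fid(c(TSP = 0, lactate = 1), aq_s = 2.6), lb))
    y <- Re(sp$intensity)
    hz <- (sp$ppm - 4.7) * 600   # frequency axis
    half <- max(y) / 2
    above <- range(which(y >= half))
    lo <- stats::approx(y[c(above[1] - 1, above[1])],
                        hz[c(above[1] - 1, above[1])], xout = half)$y
    hi <- stats::approx(y[c(above[2] + 1, above[2])],
                        hz[c(above[2] + 1, above[2])], xout = half)$y
    hi - lo
  }
  expect_equal(fwhm_of(2) - fwhm_of(0), 2, tolerance = 0.1)
})

test_that("transform places peaks correctly and preserves energy", {
  fid <- make_fid(c(TSP = 0, glucose = 1))
  sp <- nmr_transform(fid)
  expect_equal(sp$ppm[which.max(Mod(sp$intensity))], 5.23,
               tolerance = 0.01)
  ## Parseval on the raw DFT: FID energy equals spectrum energy / n
  raw <- nmr_transform(fid, first_point_half = FALSE)
  expect_equal(sum(Mod(fid$points)^2),
               sum(Mod(raw$intensity)^2) / length(fid$points),
               tolerance = 1e-9)
  z <- nmr_transform(new_fid(rep(0 + 0i, 64), 600, 20, 64 / 12000))
  expect_true(all(Mod(z$intensity) == 0))
})

test_that("correction is a fixed point on clean spectra and removes baselines", {
  sp <- nmr_transform(apodize(make_fid(aq_s = 2.6), 0.3))
  cor1 <- correct_spectrum(sp)
  expect_true(cor1$referenced)
  ## idempotent up to tolerance: feed the corrected absorption back in
  sp2 <- cor1
  sp2$referenced <- FALSE
  cor2 <- correct_spectrum(sp2)
  expect_equal(cor2$intensity, cor1$intensity,
               tolerance = 1e-6 * max(abs(cor1$intensity)))
  ## known linear baseline is removed: region integrals within 1%
  reg <- regions_from_library(tiny_library(), halfwidth_ppm = 0.04)
  a_clean <- integrate_regions(cor1, reg)
  spb <- sp
  spb$intensity <- spb$intensity +
    seq(0, 1, length.out = length(spb$ppm)) * max(Mod(sp$intensity)) * 0.02
  corb <- correct_spectrum(spb)
  a_base <- integrate_regions(corb, reg)
  expect_equal(unname(a_base / a_clean), rep(1, length(a_clean)),
               tolerance = 0.01)
})

test_that("TSP referencing recentres a shifted spectrum", {
  ## deliberately shift the carrier so TSP lands at +0.12 ppm
  fid <- make_fid()
  fid$carrier_ppm <- fid$carrier_ppm + 0.12
  sp <- correct_spectrum(nmr_transform(fid))
  tsp_apex <- sp$ppm[which.max(sp$intensity * (abs(sp$ppm) < 0.3))]
  expect_lt(abs(tsp_apex), 0.005)
  ## no TSP at all -> referencing error
  fid0 <- make_fid(c(TSP = 0, lactate = 2))
  expect_error(correct_spectrum(nmr_transform(fid0)), "TSP")
})

test_that("region integration is additive and matches the Lorentzian integral", {
  sp <- correct_spectrum(nmr_transform(make_fid(c(TSP = 3, lactate = 1), aq_s = 2.6)))
  ## zero-intensity span
  empty <- data.frame(metabolite = "nothing", ppm_low = 8, ppm_high = 8.5,
                      protons = 1, is_glycogen = FALSE)
  expect_equal(unname(integrate_regions(sp, empty)), 0, tolerance = 1e-6)
  ## split additivity
  whole <- data.frame(metabolite = "lac", ppm_low = 1.25, ppm_high = 1.41,
                      protons = 3, is_glycogen = FALSE)
  halves <- data.frame(metabolite = c("l1", "l2"),
                       ppm_low = c(1.25, 1.33), ppm_high = c(1.33, 1.41),
                       protons = 3, is_glycogen = FALSE)
  aw <- integrate_regions(sp, whole)
  ah <- integrate_regions(sp, halves)
  expect_equal(unname(sum(ah)), unname(aw), tolerance = 1e-9)
  ## wide region around an isolated noiseless Lorentzian captures the
  ## analytic integral: area(TSP)/area(lactate) = (3*9)/(1*3)
  wide <- data.frame(metabolite = c("TSP", "lactate"),
                     ppm_low = c(-0.04, 1.29), ppm_high = c(0.04, 1.37),
                     protons = c(9, 3), is_glycogen = FALSE)
  a <- integrate_regions(sp, wide)
  expect_equal(unname(a[["TSP"]] / a[["lactate"]]), 9, tolerance = 0.02)
  expect_error(integrate_regions(sp, data.frame(
    metabolite = "off", ppm_low = 30, ppm_high = 31, protons = 1,
    is_glycogen = FALSE)), "off")
})

test_that("quantification formula, glycogen convention and errors", {
  reg <- data.frame(metabolite = c("TSP", "met9", "glycogen"),
                    ppm_low = c(-0.1, 1, 5.3), ppm_high = c(0.1, 1.2, 5.5),
                    protons = c(9, 9, 1), is_glycogen = c(FALSE, FALSE, TRUE))
  ## area_m = area_TSP with 9 protons -> conc = tsp_nmol / weight
  res <- quantify(c(TSP = 2, met9 = 2, glycogen = 1), reg,
                  tsp_nmol = 40, wet_weight_g = 0.1)
  expect_equal(res$concentration[res$metabolite == "met9"], 400)
  ## glycogen skips the proton division: (1/2) * 9 * 40 / 0.1
  expect_equal(res$concentration[res$metabolite == "glycogen"],
               0.5 * 9 * 40 / 0.1)
  expect_false("TSP" %in% res$metabolite)
  res0 <- quantify(c(TSP = 2, met9 = 0, glycogen = 0), reg, 40, 0.1)
  expect_true(all(res0$concentration == 0))
  expect_error(quantify(c(TSP = 0, met9 = 1), reg, 40, 0.1), "reference")
  expect_error(quantify(c(met9 = 1), reg, 40, 0.1), "reference")
  expect_error(quantify(c(TSP = 2, met9 = 1), reg, 40, 0), "wet_weight")
})

test_that("full chain is linear and carrier-invariant", {
  lib <- tiny_library()
  reg <- regions_from_library(lib)
  run <- function(scale = 1, carrier = 4.7) {
    acq <- list(sfrq_mhz = 600, sweep_ppm = 20, aq_s = 0.65,
                carrier_ppm = carrier, npoints = 7800L)
    conc <- c(TSP = 5, lactate = 2 * scale, glucose = 4 * scale)
    fid <- generate_fid(conc, lib, acq, noise_sd = 0)
    r <- nmr_quantify(fid, reg, tsp_nmol = 0.5, wet_weight_g = 0.1)
    setNames(r$concentration, r$metabolite)
  }
  base <- run()
  expect_equal(unname(run(2) / base), c(2, 2), tolerance = 0.01)
  ## shifting the carrier must not change quantified values (referencing)
  expect_equal(run(carrier = 4.9), base, tolerance = 0.01)
  ## determinism
  expect_identical(run(), base)
})
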