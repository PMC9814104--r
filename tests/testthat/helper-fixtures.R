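# Shared fixture shorthands for the test suite.

noiseless_fixture <- function(isomer = "E") {
  default_fixture(isomer, noise_sd = 0)
}

short_series_times <- function() seq(30, 600, length.out = 20)

# single-Gaussian spectrum on a fine grid
gauss_spectrum <- function(center, fwhm = 10, grid = seq(1620, 1780, 0.5),
                           amp = 1, unit = "OD") {
  spectrum_1d(grid, amp * exp(-4 * log(2) * ((grid - center) / fwhm)^2),
              unit = unit)
}
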