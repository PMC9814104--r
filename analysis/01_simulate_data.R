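#!/usr/bin/env Rscript
# Generate the synthetic datasets every later stage consumes: one transient
# vibrational absorption map per starting isomer (seeded noise), a UV-Vis
# irradiation series per isomer, and pre/post-irradiation FTIR spectra built
# from synthetic harmonic line lists.

library(tvakit)

dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)

for (iso in c("E", "Z")) {
  fx <- default_fixture(iso)
  m <- generate_tva_map(fx, seed = 1)
  write_tva(m, sprintf("scratch/data/tva_map_%s.csv", iso))
  cat(sprintf("TVA map (%s): %d delays x %d wavenumbers, bleach peak %.2f mOD\n",
              iso, length(m$t), length(m$nu), min(m$dA)))
}

times <- seq(30, 600, length.out = 20)
for (iso in c("E", "Z")) {
  sys <- default_photosystem(iso)
  ser <- generate_irradiation_series(sys, times, seed = 7)
  out <- data.frame(time_s = ser$times,
                    E = ser$conc[, "E"], Z = ser$conc[, "Z"])
  write.csv(out, sprintf("scratch/data/irradiation_conc_%s.csv", iso),
            row.names = FALSE)
  for (i in c(1, length(times))) {
    write_xy(ser$spectra[[i]],
             sprintf("scratch/data/irradiation_%s_t%04.0fs.csv", iso,
                     ser$times[i]))
  }
  cat(sprintf("Irradiation series (%s start): %d spectra, final Z fraction %.3f\n",
              iso, length(times),
              ser$conc[nrow(ser$conc), "Z"] / sum(ser$conc[nrow(ser$conc), ])))
}

# synthetic line lists anchored to the three assigned mid-IR modes
lines_E <- line_list(c(1625, 1655, 1729), c(120, 250, 400),
                     c("aromatic C-H bend + C=C stretch",
                       "allylic C=C stretch", "C=O stretch"))
lines_Z <- line_list(c(1622, 1651, 1729), c(100, 200, 330),
                     c("aromatic C-H bend + C=C stretch",
                       "allylic C=C stretch", "C=O stretch"))
grid <- wavenumber_axis(seq(1550, 1800, 0.5))
ftir_E <- generate_ftir(lines_E, scale = 0.9879, fwhm = 8, grid = grid,
                        noise_sd = 0.02, seed = 3)
ftir_Z <- generate_ftir(lines_Z, scale = 0.9908, fwhm = 8, grid = grid,
                        noise_sd = 0.02, seed = 4)
write_xy(ftir_E, "scratch/data/ftir_E.csv")
write_xy(ftir_Z, "scratch/data/ftir_Z.csv")
write.csv(as.data.frame(lines_E), "scratch/data/lines_E.csv", row.names = FALSE)
write.csv(as.data.frame(lines_Z), "scratch/data/lines_Z.csv", row.names = FALSE)
cat("FTIR spectra synthesized from scaled line lists (0.9879 E / 0.9908 Z)\n")
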