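#!/usr/bin/env Rscript
# Classify illustrative first-order conical-intersection models. The actual
# g/h/s vectors of the molecule are not packaged, so these are synthetic
# models spanning the qualitative classes; the strongly tilted ones
# reproduce the sloped / single-pathed character reported for the low-lying
# intersections of this chromophore.

library(tvakit)

dir.create("results", showWarnings = FALSE)

models <- list(
  # tilt dominating the cone: sloped, single exit valley
  CI_Z_like   = ci_model(g = c(1.0, 0, 0), h = c(0, 0.35, 0),
                         s = c(1.6, 0, 0), label = "CI_Z_like"),
  CI_E_like   = ci_model(g = c(0.8, 0.1, 0), h = c(0, 0.3, 0.05),
                         s = c(1.1, 0.1, 0), label = "CI_E_like"),
  # untilted asymmetric cone: peaked, two valleys (textbook contrast case)
  peaked_ref  = ci_model(g = c(1, 0, 0), h = c(0, 0.5, 0),
                         s = c(0, 0, 0), label = "peaked_ref")
)

rows <- lapply(models, function(m) {
  cl <- classify_ci(m)
  cat(sprintf("%-11s -> %s, %s (%d valley%s)\n", m$label, cl$peaking,
              cl$pathing, length(cl$theta_minima),
              if (length(cl$theta_minima) == 1) "" else "s"))
  data.frame(label = m$label, peaking = cl$peaking, pathing = cl$pathing,
             n_valleys = length(cl$theta_minima),
             theta_min_deg = paste(round(cl$theta_minima * 180 / pi),
                                   collapse = ";"))
})
write.csv(do.call(rbind, rows), "results/ci_classes.csv", row.names = FALSE)
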