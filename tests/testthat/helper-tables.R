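# Published prediction tables, used as input fixtures for oracle checks.
# Percent cells are mean LDL-C % change from (pre-statin) baseline at week
# 12; the bempedoic-acid-alone row is the dose-0 row of every column.

printed_table3 <- function() {
  rbind(
    data.frame(statin = "atorvastatin", dose = c(10, 20, 40, 80),
               alone = c(-37, -43, -49, -54), combo = c(-51, -54, -58, -62),
               delta = c(-22, -19, -18, -17)),
    data.frame(statin = "simvastatin", dose = c(10, 20, 40),
               alone = c(-30, -36, -42), combo = c(-46, -50, -54),
               delta = c(-23, -22, -21)),
    data.frame(statin = "rosuvastatin", dose = c(10, 20, 40),
               alone = c(-46, -52, -57), combo = c(-57, -60, -63),
               delta = c(-20, -17, -14)),
    data.frame(statin = "pravastatin", dose = c(10, 20, 40, 80),
               alone = c(-21, -26, -32, -38), combo = c(-41, -44, -47, -51),
               delta = c(-25, -24, -22, -21))
  )
}

printed_ba_mono_pct <- -27

# Mean absolute LDL-C (mg/dL) on the common simulated baseline.
printed_table4 <- function() {
  rbind(
    data.frame(statin = "atorvastatin", dose = c(0, 10, 20, 40, 80),
               alone = c(183.1, 116.2, 104.0, 94.2, 84.2),
               combo = c(132.7, 89.6, 84.0, 77.5, 70.6)),
    data.frame(statin = "simvastatin", dose = c(0, 10, 20, 40),
               alone = c(183.1, 129.0, 117.7, 106.3),
               combo = c(132.7, 99.6, 92.5, 86.0)),
    data.frame(statin = "rosuvastatin", dose = c(0, 10, 20, 40),
               alone = c(183.1, 98.2, 87.8, 79.0),
               combo = c(132.7, 79.5, 72.6, 67.6)),
    data.frame(statin = "pravastatin", dose = c(0, 10, 20, 40, 80),
               alone = c(183.1, 143.4, 136.2, 124.6, 115.9),
               combo = c(132.7, 108.6, 104.3, 96.9, 90.3))
  )
}
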