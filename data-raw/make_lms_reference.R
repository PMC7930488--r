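# Builds inst/extdata/synthetic_lms_reference.csv: a SYNTHETIC growth
# reference in the CDC LMS file dialect (sex, agemos, L, M, S), covering
# 102-138 months in half-month steps. Values are smooth curves with
# magnitudes typical of BMI-for-age references at these ages; they are NOT
# the CDC 2000 tables. Regenerate with: Rscript data-raw/make_lms_reference.R
age <- seq(102, 138, by = 0.5)
mk <- function(sex, l0, l1, m0, m1, m2, s0, s1) {
  a <- age - 102
  data.frame(sex = sex, agemos = age,
             L = round(l0 + l1 * a, 5),
             M = round(m0 + m1 * a + m2 * a^2, 5),
             S = round(s0 + s1 * a, 6))
}
ref <- rbind(
  mk("M", -2.45, 0.0045, 16.40, 0.028, 0.00040, 0.135, 0.00060),
  mk("F", -2.20, 0.0040, 16.20, 0.030, 0.00050, 0.140, 0.00055)
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(ref, "inst/extdata/synthetic_lms_reference.csv", row.names = FALSE)
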