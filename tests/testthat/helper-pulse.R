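# Per-patient contribution column of the bundled pulse-count table as
# published (2 dp), used to check chi2_terms row by row.
pulse_printed_terms <- function() {
  data.frame(
    lower = c(11.87, 1.81, 4.18, 0.17, 5.19, 0.17, 1.51, 0.03, 0.08, 2.11,
              2.11, 0.58, 3.25, 4.18, 2.46, 12.68, 2.11, 0.99, 3.25, 3.68,
              0.16, 8.14, 5.19, 0.03, 1.79, 0.58, 0.08, 6.26, 2.11, 0.77,
              0.16, 2.84, 1.22, 4.18, 11.08, 2.46, 0.58, 1.49, 3.68, 4.15,
              4.18, 0.16, 0.00, 3.25, 1.24, 4.18, 4.15, 0.58, 5.19, 4.63),
    upper = c(6.17, 4.27, 0.04, 4.44, 4.27, 0.73, 3.07, 0.73, 0.42, 0.19,
              0.73, 0.16, 0.73, 7.82, 0.02, 5.18, 4.44, 2.39, 0.56, 0.92,
              0.09, 5.86, 7.25, 0.09, 0.73, 2.07, 0.29, 6.92, 0.56, 0.73,
              0.16, 0.56, 4.44, 7.82, 2.07, 0.29, 0.09, 1.13, 3.22, 2.86,
              2.39, 0.56, 0.09, 5.37, 5.18, 3.45, 6.92, 0.16, 2.39, 0.73))
}

# A 50-count dataset whose lower-data statistic component is far outside
# the alpha = 0.05 critical region while the upper-data component lies
# inside it: 25 records [40, 90] and 25 records [100, 110].
straddling_data <- function() {
  interval_counts(rep(c(40, 100), each = 25), rep(c(90, 110), each = 25))
}
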