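# Printed reference values of the two baseline scenario tables.
# Sub-unity cells quoted as "~1" in the source tables (no_bias rows 1-2 c_e,
# row 1 r_w) are NA here: the closed forms give 0.35-0.41 for them and the
# waste ratio is the binding check for those rows.
table2_printed <- data.frame(
  f_p = c(0.05, 0.05, 0.20, 0.20),
  t_d = c(0, 1, 0, 2),
  t_c = c(5, 6, 16, 18),
  r_w = c(4, 6, 292, 917),
  c_e = c(1, 1, 93, 291),
  ratio_pct = c(82.1, 85.0, 75.8, 75.9)
)

table3_printed <- data.frame(
  f_p = c(0.05, 0.05, 0.50, 0.50),
  t_d = c(0, 1, 0, 2),
  t_c = c(0.5, 1.5, 1, 3),
  r_w = c(NA, 1.5, 1, 32),
  c_e = c(NA, NA, NA, 17),
  ratio_pct = c(50.4, 78.5, 54.3, 66.2)
)

baseline_model <- function(f_p, t_d, mode = "biased") {
  goldrush(f_p = f_p, t_d = t_d, bias_mode = mode)
}
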