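# Packaged design tables used across test files.
pb_fixture <- function() {
  read_design_csv(fermkin_example("pb_table2.csv"),
                  fermkin_example("pb_table2.yaml"))
}

bbd_fixture <- function() {
  read_design_csv(fermkin_example("bbd_table4.csv"),
                  fermkin_example("bbd_table4.yaml"))
}

table6_fixture <- function() {
  utils::read.csv(fermkin_example("table6_params.csv"))
}

# Standard four-factor coded quadratic truth used by generator tests:
# the fitted enzyme-activity surface of the packaged Box-Behnken table.
ea_surface_truth <- function() {
  c("(Intercept)" = 266.19,
    X1 = -11.23, X2 = 7.06, X3 = -11.57, X4 = -9.06,
    "X1:X2" = 22.73, "X1:X3" = -27.38, "X1:X4" = -41.04,
    "X2:X3" = 14.87, "X2:X4" = 1.91, "X3:X4" = -44.73,
    "X1^2" = -22.03, "X2^2" = -23.43, "X3^2" = -41.11, "X4^2" = -49.78)
}
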