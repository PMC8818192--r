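# Shared fixtures, built once per test run.

fx_arterial <- arterial_input()
fx_portal <- portal_from_arterial(fx_arterial)
fx_schedule <- frame_schedule()
fx_truth <- kinetic_params(0.65, 0.59, 0.14, 0.064, 0.67)
fx_tissue <- tissue_curve(model_frames(fx_truth, fx_arterial, fx_portal),
                          fx_schedule, label = "HCC")

# Brute-force oracle: integrate the two-tissue ODE system
#   dCf/dt = k1 Cb - (k2+k3) Cf + k4 Cp
#   dCp/dt = k3 Cf - k4 Cp,  Ct = Cf + Cp
# with deSolve, independent of the analytic-convolution implementation.
ode_tissue_curve <- function(params, arterial, portal, t_out_s) {
  p <- unclass(dipetkin:::as_kinetic_params(params))
  cb <- blood_input(arterial, portal, p[["hpi"]])
  rhs <- function(t_min, y, parms) {
    cbv <- eval_input(cb, min(t_min * 60, max(cb$time_s)))
    list(c(parms[["k1"]] * cbv - (parms[["k2"]] + parms[["k3"]]) * y[1] +
             parms[["k4"]] * y[2],
           parms[["k3"]] * y[1] - parms[["k4"]] * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), t_out_s / 60, rhs, p[1:4],
                        rtol = 1e-8, atol = 1e-10)
  sol[, 2] + sol[, 3]
}
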