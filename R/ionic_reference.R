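#' Reference derivatives of the myocyte model (pure R)
#'
#' A direct R transcription of the published model equations (epicardial
#' parameter set), returning the full state derivative including the
#' membrane voltage. Intended as an independent reference for integrating
#' the single-cell model with a general-purpose adaptive ODE solver and for
#' validating the compiled implementation; it is far too slow for tissue
#' simulation.
#'
#' @param t time (ms); unused except for the deSolve calling convention.
#' @param state named state vector as from [initial_state()].
#' @param parms list with optional `stim_fun(t)` returning the stimulus
#'   current (pA/pF, negative depolarizes) at time `t`.
#' @return List (deSolve convention) with the derivative vector.
#' @export
tt06_derivatives <- function(t, state, parms = list()) {
  R <- 8314.472; Temp <- 310; F <- 96485.3415
  rtonf <- R * Temp / F
  Ko <- 5.4; Nao <- 140; Cao <- 2
  Cm <- 0.185; Vc <- 0.016404; Vsr <- 0.001094; Vss <- 0.00005468

  V <- state[["Vm"]]
  m <- state[["m"]]; h <- state[["h"]]; j <- state[["j"]]
  d <- state[["d"]]; f <- state[["f"]]; f2 <- state[["f2"]]
  fCass <- state[["fCass"]]; r <- state[["r"]]; s <- state[["s"]]
  xr1 <- state[["xr1"]]; xr2 <- state[["xr2"]]; xs <- state[["xs"]]
  Rbar <- state[["Rbar"]]
  Cai <- state[["Cai"]]; CaSS <- state[["CaSS"]]; CaSR <- state[["CaSR"]]
  Nai <- state[["Nai"]]; Ki <- state[["Ki"]]

  ENa <- rtonf * log(Nao / Nai)
  EK <- rtonf * log(Ko / Ki)
  EKs <- rtonf * log((Ko + 0.03 * Nao) / (Ki + 0.03 * Nai))
  ECa <- 0.5 * rtonf * log(Cao / Cai)

  INa <- 14.838 * m^3 * h * j * (V - ENa)
  vs <- V - 15
  e2 <- exp(2 * vs / rtonf)
  ICaL <- if (abs(vs) < 1e-6) {
    0.0000398 * d * f * f2 * fCass * 2 * F * (0.25 * CaSS - Cao)
  } else {
    0.0000398 * d * f * f2 * fCass * 4 * vs * (F / rtonf) *
      (0.25 * CaSS * e2 - Cao) / (e2 - 1)
  }
  Ito <- 0.294 * r * s * (V - EK)
  IKr <- 0.153 * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK)
  IKs <- 0.392 * xs^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- 5.405 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)
  INaCa <- 1000 *
    (exp(0.35 * V / rtonf) * Nai^3 * Cao -
       exp(-0.65 * V / rtonf) * Nao^3 * Cai * 2.5) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * V / rtonf)))
  INaK <- 2.724 * Ko / (Ko + 1) * Nai / (Nai + 40) /
    (1 + 0.1245 * exp(-0.1 * V / rtonf) + 0.0353 * exp(-V / rtonf))
  IpCa <- 0.1238 * Cai / (Cai + 0.0005)
  IpK <- 0.0146 * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbCa <- 0.000592 * (V - ECa)
  IbNa <- 0.00029 * (V - ENa)

  Istim <- if (is.function(parms$stim_fun)) parms$stim_fun(t) else 0
  Iion <- INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa + IpK +
    IbCa + IbNa

  gate <- function(inf, tau, g) (inf - g) / tau
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
  }
  tau_h <- 1 / (ah + bh)
  j_inf <- h_inf
  if (V >= -40) {
    aj <- 0
    bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  tau_j <- 1 / (aj + bj)
  d_inf <- 1 / (1 + exp((-8 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2_inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tau_f2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fCass_inf <- 0.6 / (1 + (CaSS / 0.05)^2) + 0.4
  tau_fCass <- 80 / (1 + (CaSS / 0.05)^2) + 2
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  s_inf <- 1 / (1 + exp((V + 20) / 5))
  tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- (450 / (1 + exp((-45 - V) / 10))) * (6 / (1 + exp((V + 30) / 11.5)))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- (3 / (1 + exp((-60 - V) / 20))) * (1.12 / (1 + exp((V - 60) / 20)))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- (1400 / sqrt(1 + exp((5 - V) / 6))) * (1 / (1 + exp((V - 35) / 15))) + 80

  kcasr <- 2.5 - 1.5 / (1 + (1.5 / CaSR)^2)
  k1 <- 0.15 / kcasr
  k2 <- 0.045 * kcasr
  O <- k1 * CaSS^2 * Rbar / (0.06 + k1 * CaSS^2)
  Irel <- 0.102 * O * (CaSR - CaSS)
  Ileak <- 0.00036 * (CaSR - Cai)
  Iup <- 0.006375 / (1 + 0.00025^2 / Cai^2)
  Ixfer <- 0.0038 * (CaSS - Cai)
  bufc <- 1 / (1 + 0.2 * 0.001 / (Cai + 0.001)^2)
  bufsr <- 1 / (1 + 10 * 0.3 / (CaSR + 0.3)^2)
  bufss <- 1 / (1 + 0.4 * 0.00025 / (CaSS + 0.00025)^2)

  deriv <- c(
    Vm = -(Iion + Istim),
    m = gate(m_inf, tau_m, m),
    h = gate(h_inf, tau_h, h),
    j = gate(j_inf, tau_j, j),
    d = gate(d_inf, tau_d, d),
    f = gate(f_inf, tau_f, f),
    f2 = gate(f2_inf, tau_f2, f2),
    fCass = gate(fCass_inf, tau_fCass, fCass),
    r = gate(r_inf, tau_r, r),
    s = gate(s_inf, tau_s, s),
    xr1 = gate(xr1_inf, tau_xr1, xr1),
    xr2 = gate(xr2_inf, tau_xr2, xr2),
    xs = gate(xs_inf, tau_xs, xs),
    Rbar = -k2 * CaSS * Rbar + 0.005 * (1 - Rbar),
    Cai = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                    (IbCa + IpCa - 2 * INaCa) * Cm / (2 * Vc * F)),
    CaSS = bufss * (-ICaL * Cm / (2 * Vss * F) + Irel * Vsr / Vss -
                      Ixfer * Vc / Vss),
    CaSR = bufsr * (Iup - Irel - Ileak),
    Nai = -(INa + IbNa + 3 * INaK + 3 * INaCa) * Cm / (Vc * F),
    Ki = -(Istim + IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * Cm / (Vc * F)
  )
  list(deriv)
}
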