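# Independent reference for the Courtemanche model: a direct plain-R
# transcription of the published 1998 equations, integrated by a generic
# stiff ODE solver (deSolve::lsoda). Used only as a test oracle; shares no
# code with the package's compiled integrator.

ref_initial_state <- function() {
  c(V = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
    oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
    xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
    fca = 7.755e-1, u = 0.0, v = 1.0, w = 9.992e-1,
    nai = 1.117e1, ki = 1.39e2, cai = 1.013e-4,
    caup = 1.488, carel = 1.488)
}

ref_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    R <- 8.3143; Temp <- 310.0; Fd <- 96.4867
    Cm <- 100.0
    Vi <- 13668.0; Vup <- 1109.52; Vrel <- 96.48
    Ko <- 5.4; Nao <- 140.0; Cao <- 1.8
    FRT <- Fd / (R * Temp)
    ena <- log(Nao / nai) / FRT
    ek  <- log(Ko / ki) / FRT
    eca <- log(Cao / cai) / (2 * FRT)
    ina <- Cm * 7.8 * m^3 * h * j * (V - ena)
    ik1 <- s_k1 * Cm * 0.09 * (V - ek) / (1 + exp(0.07 * (V + 80)))
    ito <- s_to * Cm * 0.1652 * oa^3 * oi * (V - ek)
    gkur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
    ikur <- s_kur * Cm * gkur * ua^3 * ui * (V - ek)
    ikr <- Cm * 0.029411765 * xr * (V - ek) / (1 + exp((V + 15) / 22.4))
    iks <- Cm * 0.12941176 * xs^2 * (V - ek)
    ical <- s_cal * Cm * 0.12375 * d * f * fca * (V - 65)
    sig <- (exp(Nao / 67.3) - 1) / 7
    fnak <- 1 / (1 + 0.1245 * exp(-0.1 * FRT * V) + 0.0365 * sig * exp(-FRT * V))
    inak <- Cm * 0.59933874 * fnak * (1 / (1 + (10 / nai)^1.5)) * (Ko / (Ko + 1.5))
    inaca <- Cm * 1600 *
      (exp(0.35 * FRT * V) * nai^3 * Cao -
         exp(-0.65 * FRT * V) * Nao^3 * cai) /
      ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * FRT * V)))
    ibna <- Cm * 0.0006744375 * (V - ena)
    ibca <- Cm * 0.001131 * (V - eca)
    ipca <- Cm * 0.275 * cai / (0.0005 + cai)
    irel <- 30 * u^2 * v * w * (carel - cai)
    itr <- (caup - carel) / 180
    iup <- 0.005 / (1 + 0.00092 / cai)
    iupleak <- 0.005 * caup / 15
    istim <- if (!is.null(parms$stim_fun)) parms$stim_fun(t) else 0

    am <- if (abs(V + 47.13) < 1e-10) 3.2 else
      0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
    bm <- 0.08 * exp(-V / 11)
    if (V >= -40) {
      ah <- 0; bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
      aj <- 0
      bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
    } else {
      ah <- 0.135 * exp(-(V + 80) / 6.8)
      bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
      aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    }
    KQ10 <- 3
    aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
    boa <- 0.65 / (2.5 + exp((V + 82) / 17))
    tauoa <- 1 / ((aoa + boa) * KQ10)
    oainf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
    aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
    boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
    tauoi <- 1 / ((aoi + boi) * KQ10)
    oiinf <- 1 / (1 + exp((V + 43.1) / 5.3))
    tauua <- tauoa
    uainf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
    aui <- 1 / (21 + exp(-(V - 185) / 28))
    bui <- exp((V - 158) / 16)
    tauui <- 1 / ((aui + bui) * KQ10)
    uiinf <- 1 / (1 + exp((V - 99.45) / 27.48))
    axr <- if (abs(V + 14.1) < 1e-10) 0.0015 else
      0.0003 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5))
    bxr <- if (abs(V - 3.3328) < 1e-10) 3.7836118e-4 else
      7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
    tauxr <- 1 / (axr + bxr)
    xrinf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
    axs <- if (abs(V - 19.9) < 1e-10) 0.00068 else
      4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17))
    bxs <- if (abs(V - 19.9) < 1e-10) 0.000315 else
      3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
    tauxs <- 0.5 / (axs + bxs)
    xsinf <- 1 / sqrt(1 + exp(-(V - 19.9) / 12.7))
    e10 <- exp(-(V + 10) / 6.24)
    taud <- if (abs(V + 10) < 1e-10) 4.579 / (1 + e10) else
      (1 - e10) / (0.035 * (V + 10) * (1 + e10))
    dinf <- 1 / (1 + exp(-(V + 10) / 8))
    tauf <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
    finf <- 1 / (1 + exp((V + 28) / 6.9))
    fcainf <- 1 / (1 + cai / 0.00035)
    fn <- 1e-12 * Vrel * irel - (5e-13 / Fd) * (0.5 * ical - 0.2 * inaca)
    uinf <- 1 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))
    tauv <- 1.91 + 2.09 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))
    vinf <- 1 - 1 / (1 + exp(-(fn - 6.835e-14) / 13.67e-16))
    e79 <- exp(-(V - 7.9) / 5)
    tauw <- if (abs(V - 7.9) < 1e-10) 6 * 0.2 / 1.3 else
      6 * (1 - e79) / ((1 + 0.3 * e79) * (V - 7.9))
    winf <- 1 - 1 / (1 + exp(-(V - 40) / 17))

    dV <- -(ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak + inaca +
              ibna + ibca) / Cm + istim
    b1 <- (2 * inaca - ipca - ical - ibca) / (2 * Fd * Vi) +
      (Vup * (iupleak - iup) + irel * Vrel) / Vi
    b2 <- 1 + 0.07 * 0.0005 / (cai + 0.0005)^2 + 0.05 * 0.00238 / (cai + 0.00238)^2
    list(c(dV,
           am * (1 - m) - bm * m,
           ah * (1 - h) - bh * h,
           aj * (1 - j) - bj * j,
           (oainf - oa) / tauoa, (oiinf - oi) / tauoi,
           (uainf - ua) / tauua, (uiinf - ui) / tauui,
           (xrinf - xr) / tauxr, (xsinf - xs) / tauxs,
           (dinf - d) / taud, (finf - f) / tauf,
           (fcainf - fca) / 2, (uinf - u) / 8, (vinf - v) / tauv,
           (winf - w) / tauw,
           (-3 * inak - 3 * inaca - ibna - ina) / (Fd * Vi),
           (2 * inak - ik1 - ito - ikur - ikr - iks) / (Fd * Vi),
           b1 / b2,
           iup - iupleak - itr * Vrel / Vup,
           (itr - irel) / (1 + 10 * 0.8 / (carel + 0.8)^2)))
  })
}

# pace the reference model; istim > 0 depolarizes (matches the package)
ref_pace <- function(scales = c(1, 1, 1, 1), cl = 1000, n_beats = 1,
                     amp = 25, dur = 2, y0 = ref_initial_state(),
                     sample_dt = 1) {
  parms <- list(s_to = scales[1], s_kur = scales[2], s_cal = scales[3],
                s_k1 = scales[4],
                stim_fun = function(t)
                  if (t < n_beats * cl && (t %% cl) < dur) amp else 0)
  times <- seq(0, n_beats * cl, by = sample_dt)
  out <- deSolve::lsoda(y0, times, ref_rhs, parms, rtol = 1e-8, atol = 1e-8,
                        maxsteps = 50000)
  list(t = out[, "time"], V = out[, "V"],
       state = out[nrow(out), 1 + seq_len(21)])
}
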