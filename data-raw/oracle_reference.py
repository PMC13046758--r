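"""Reference implementations of the published heat-stress algorithms.

These are direct, scalar/loop-style NumPy transcriptions of:

  * the U.S. National Weather Service heat-index procedure (Rothfusz
    regression with the low/high-humidity adjustments and the simple
    Steadman-average formula below the 80 F threshold);
  * the Liljegren et al. (2008) natural wet-bulb / black-globe energy
    balance (constants and iteration scheme of the published C code,
    including the stability-class 10 m -> 2 m wind profile);
  * the Brode et al. (2012) UTCI sixth-order polynomial approximation
    (the full 210-term coefficient table of UTCI_approx);
  * the operational mean-radiant-temperature flux balance used by the
    ECMWF thermal-indices software (half-sky/half-ground view factors,
    shortwave absorptivity 0.7, emissivity 0.97, Fanger projected-area
    factor).

They serve as the independent oracle for the R package: this script
freezes oracle outputs on a Latin-hypercube of valid inputs into
inst/extdata/oracle/*.csv and emits the shared UTCI coefficient table
into R/utci_coefficients.R.

Run from the repository root:  python data-raw/oracle_reference.py
"""

import math
import os

import numpy as np
from scipy.stats import qmc

# ---------------------------------------------------------------------------
# Saturation vapor pressure, Buck (1996) over-water form (pipeline convention)
# ---------------------------------------------------------------------------


def svp_buck(t_c):
    """hPa from deg C."""
    return 6.1121 * math.exp((18.678 - t_c / 234.5) * t_c / (257.14 + t_c))


# ---------------------------------------------------------------------------
# NWS heat index
# ---------------------------------------------------------------------------


def heat_index_c(ta_c, rh):
    """NWS heat-index algorithm; input deg C / %, output deg C."""
    t = ta_c * 9.0 / 5.0 + 32.0
    hi = 0.5 * (t + 61.0 + (t - 68.0) * 1.2 + rh * 0.094)
    if hi >= 80.0:
        hi = (
            -42.379
            + 2.04901523 * t
            + 10.14333127 * rh
            - 0.22475541 * t * rh
            - 6.83783e-3 * t * t
            - 5.481717e-2 * rh * rh
            + 1.22874e-3 * t * t * rh
            + 8.5282e-4 * t * rh * rh
            - 1.99e-6 * t * t * rh * rh
        )
        if rh < 13.0 and 80.0 <= t <= 112.0:
            hi -= ((13.0 - rh) / 4.0) * math.sqrt((17.0 - abs(t - 95.0)) / 17.0)
        elif rh > 85.0 and 80.0 <= t <= 87.0:
            hi += ((rh - 85.0) / 10.0) * ((87.0 - t) / 5.0)
    return (hi - 32.0) * 5.0 / 9.0


# ---------------------------------------------------------------------------
# Liljegren et al. (2008) WBGT: constants and helper functions as in the
# published C code (wbgt.c). Temperatures in K, pressure in hPa, rh 0-1.
# ---------------------------------------------------------------------------

STEFANB = 5.6696e-8
CP = 1003.5
M_AIR = 28.97
M_H2O = 18.015
R_GAS = 8314.34
R_AIR = R_GAS / M_AIR
PR = CP / (CP + 1.25 * R_AIR)
RATIO = CP * M_AIR / M_H2O

EMIS_GLOBE = 0.95
ALB_GLOBE = 0.05
DIAM_GLOBE = 0.0508
EMIS_WICK = 0.95
ALB_WICK = 0.4
DIAM_WICK = 0.007
LEN_WICK = 0.0254
EMIS_SFC = 0.999
ALB_SFC = 0.45

CONVERGENCE = 0.02
MAX_ITER = 50
MIN_SPEED = 0.13
REF_HEIGHT = 2.0


def esat_lil(tk):
    """Liljegren's saturation vapor pressure over water, hPa (Buck 1981
    with the 1.004 enhancement factor)."""
    return 1.004 * 6.1121 * math.exp(17.502 * (tk - 273.15) / (tk - 32.18))


def dew_point_lil(e_hpa):
    """Inverse of esat_lil, K."""
    z = math.log(e_hpa / (6.1121 * 1.004))
    return 273.15 + 240.97 * z / (17.502 - z)


def viscosity(tair_k):
    """Dynamic viscosity of air, kg/(m s)."""
    sigma = 3.617
    eps_kappa = 97.0
    tr = tair_k / eps_kappa
    omega = (tr - 2.9) / 0.4 * (-0.034) + 1.048
    return 2.6693e-6 * math.sqrt(M_AIR * tair_k) / (sigma * sigma * omega)


def thermal_cond(tair_k):
    return (CP + 1.25 * R_AIR) * viscosity(tair_k)


def diffusivity(tref_k, pair_hpa):
    """Diffusivity of water vapor in air, m2/s."""
    pcrit13 = (36.4 * 218.0) ** (1.0 / 3.0)
    tcrit512 = (132.0 * 647.3) ** (5.0 / 12.0)
    tcrit12 = math.sqrt(132.0 * 647.3)
    mmix = math.sqrt(1.0 / M_AIR + 1.0 / M_H2O)
    patm = pair_hpa / 1013.25
    return 3.64e-4 * (tref_k / tcrit12) ** 2.334 * pcrit13 * tcrit512 * mmix / patm * 1e-4


def evap(tair_k):
    """Latent heat of vaporization, J/kg."""
    return (313.15 - tair_k) / 30.0 * (-71100.0) + 2.4073e6


def emis_atm(tair_k, rh_frac):
    e = rh_frac * esat_lil(tair_k)
    return 0.575 * e ** 0.143


def h_sphere(tair_k, pair_hpa, speed):
    density = pair_hpa * 100.0 / (R_AIR * tair_k)
    sp = max(speed, MIN_SPEED)
    re = sp * density * DIAM_GLOBE / viscosity(tair_k)
    nu = 2.0 + 0.6 * math.sqrt(re) * PR ** 0.3333
    return nu * thermal_cond(tair_k) / DIAM_GLOBE


def h_cylinder(tair_k, pair_hpa, speed):
    b, c = 0.281, 0.4
    density = pair_hpa * 100.0 / (R_AIR * tair_k)
    sp = max(speed, MIN_SPEED)
    re = sp * density * DIAM_WICK / viscosity(tair_k)
    nu = b * re ** (1.0 - c) * PR ** 0.3333
    return nu * thermal_cond(tair_k) / DIAM_WICK


def tglobe(tair_k, rh_frac, pair_hpa, speed2m, solar, fdir, cza):
    tsfc = tair_k
    tg_prev = tair_k
    for _ in range(MAX_ITER):
        tref = 0.5 * (tg_prev + tair_k)
        h = h_sphere(tref, pair_hpa, speed2m)
        term = (
            0.5 * (emis_atm(tair_k, rh_frac) * tair_k ** 4 + EMIS_SFC * tsfc ** 4)
            - h / (STEFANB * EMIS_GLOBE) * (tg_prev - tair_k)
            + solar
            / (2.0 * STEFANB * EMIS_GLOBE)
            * (1.0 - ALB_GLOBE)
            * (fdir * (1.0 / (2.0 * cza) - 1.0) + 1.0 + ALB_SFC)
        )
        tg_new = term ** 0.25
        if abs(tg_new - tg_prev) < CONVERGENCE:
            return tg_new
        tg_prev = 0.9 * tg_prev + 0.1 * tg_new
    return float("nan")


def twb(tair_k, rh_frac, pair_hpa, speed2m, solar, fdir, cza):
    a = 0.56  # Bedingfield & Drew exponent
    tsfc = tair_k
    sza = math.acos(min(max(cza, -1.0), 1.0))
    eair = rh_frac * esat_lil(tair_k)
    tw_prev = dew_point_lil(eair)
    for _ in range(MAX_ITER):
        tref = 0.5 * (tw_prev + tair_k)
        h = h_cylinder(tref, pair_hpa, speed2m)
        fatm = STEFANB * EMIS_WICK * (
            0.5 * (emis_atm(tair_k, rh_frac) * tair_k ** 4 + EMIS_SFC * tsfc ** 4)
            - tw_prev ** 4
        ) + (1.0 - ALB_WICK) * solar * (
            (1.0 - fdir) * (1.0 + 0.25 * DIAM_WICK / LEN_WICK)
            + fdir * (math.tan(sza) / math.pi + 0.25 * DIAM_WICK / LEN_WICK)
            + ALB_SFC
        )
        ewick = esat_lil(tw_prev)
        density = pair_hpa * 100.0 / (R_AIR * tref)
        sc = viscosity(tref) / (density * diffusivity(tref, pair_hpa))
        tw_new = (
            tair_k
            - evap(tref) / RATIO * (ewick - eair) / (pair_hpa - ewick) * (PR / sc) ** a
            + fatm / h
        )
        if abs(tw_new - tw_prev) < CONVERGENCE:
            return tw_new
        tw_prev = 0.9 * tw_prev + 0.1 * tw_new
    return float("nan")


# stability-class wind profile (Liljegren's srdt scheme, rural exponents)
RURAL_EXP = [0.07, 0.07, 0.10, 0.15, 0.35, 0.55]


def stability_class(daytime, speed10, solar):
    if daytime:
        if solar >= 925.0:
            j = 0
        elif solar >= 675.0:
            j = 1
        elif solar >= 175.0:
            j = 2
        else:
            j = 3
        if speed10 >= 6.0:
            i = 4
        elif speed10 >= 5.0:
            i = 3
        elif speed10 >= 3.0:
            i = 2
        elif speed10 >= 2.0:
            i = 1
        else:
            i = 0
        table = [
            [1, 1, 2, 4],
            [1, 2, 3, 4],
            [2, 2, 3, 4],
            [3, 3, 4, 4],
            [3, 4, 4, 4],
        ]
        return table[i][j]
    # night, no vertical temperature gradient available: stable side
    return 4 if speed10 >= 2.5 else 6


def wind_2m(speed10, solar, cza):
    daytime = solar > 0.0 and cza > 0.0
    sc = stability_class(daytime, speed10, solar)
    est = speed10 * (REF_HEIGHT / 10.0) ** RURAL_EXP[sc - 1]
    return max(est, MIN_SPEED)


def wbgt_liljegren(ta_c, rh_pct, ps_pa, u10, ghi, fdir, cza):
    """Returns (Tw, Tg, WBGT) in deg C."""
    tk = ta_c + 273.15
    rh = min(max(rh_pct, 0.0), 100.0) / 100.0
    pair = ps_pa / 100.0
    u2 = wind_2m(u10, ghi, cza)
    cza_eff = cza
    fdir_eff = fdir
    if ghi <= 1.0 or cza_eff <= 0.00873:
        fdir_eff = 0.0
    tg_k = tglobe(tk, rh, pair, u2, ghi, fdir_eff, max(cza_eff, 0.00873))
    tw_k = twb(tk, rh, pair, u2, ghi, fdir_eff, max(cza_eff, 0.00873))
    tw = tw_k - 273.15
    tg = tg_k - 273.15
    return tw, tg, 0.7 * tw + 0.2 * tg + 0.1 * ta_c


# ---------------------------------------------------------------------------
# Mean radiant temperature (operational flux balance)
# ---------------------------------------------------------------------------

SIGMA_MRT = 5.67e-8


def mean_radiant_temperature_c(ssrd, ssr, dsrp, strd, fdir_h, strr, cossza):
    """deg C from W/m2 fluxes.

    ssrd: downwelling shortwave (GHI); ssr: net shortwave (1-albedo)*GHI;
    dsrp: direct normal irradiance; fdir_h: its horizontal component
    DNI*cos(theta_z); strd: downwelling longwave; strr: net longwave
    (down - up); cossza: cosine solar zenith truncated at zero.
    """
    cz = max(cossza, 0.0)
    ssrd = max(ssrd, 0.0)
    ssr = max(ssr, 0.0)
    dsrp = max(dsrp, 0.0)
    fdir_h = max(fdir_h, 0.0)
    dsw = max(ssrd - fdir_h, 0.0)  # diffuse shortwave
    rsw = max(ssrd - ssr, 0.0)  # reflected (upwelling) shortwave
    lur = strd - strr  # upwelling longwave
    gamma = math.degrees(math.asin(min(max(cz, 0.0), 1.0)))  # solar elevation
    fp = 0.308 * math.cos(math.radians(gamma * 0.998 - gamma * gamma / 50000.0))
    mrt4 = (1.0 / SIGMA_MRT) * (
        0.5 * strd + 0.5 * lur + (0.7 / 0.97) * (0.5 * dsw + 0.5 * rsw + fp * dsrp)
    )
    return max(mrt4, 0.0) ** 0.25 - 273.15


# ---------------------------------------------------------------------------
# UTCI sixth-order polynomial (Brode et al. 2012 UTCI_approx), 210 terms.
# Term order: for pa^p (p=0..6), d_tmrt^d (d=0..6-p), va^j (j=0..6-p-d),
# ta^i (i=0..6-p-d-j).
# ---------------------------------------------------------------------------

UTCI_COEFS = [
    # pa^0, dT^0
    6.07562052e-01, -2.27712343e-02, 8.06470249e-04, -1.54271372e-04,
    -3.24651735e-06, 7.32602852e-08, 1.35959073e-09,
    -2.25836520e+00, 8.80326035e-02, 2.16844454e-03, -1.53347087e-05,
    -5.72983704e-07, -2.55090145e-09,
    -7.51269505e-01, -4.08350271e-03, -5.21670675e-05, 1.94544667e-06,
    1.14099531e-08,
    1.58137256e-01, -6.57263143e-05, 2.22697524e-07, -4.16117031e-08,
    -1.27762753e-02, 9.66891875e-06, 2.52785852e-09,
    4.56306672e-04, -1.74202546e-07,
    -5.91491269e-06,
    # pa^0, dT^1
    3.98374029e-01, 1.83945314e-04, -1.73754510e-04, -7.60781159e-07,
    3.77830287e-08, 5.43079673e-10,
    -2.00518269e-02, 8.92859837e-04, 3.45433048e-06, -3.77925774e-07,
    -1.69699377e-09,
    1.69992415e-04, -4.99204314e-05, 2.47417178e-07, 1.07596466e-08,
    8.49242932e-05, 1.35191328e-06, -6.21531254e-09,
    -4.99410301e-06, -1.89489258e-08,
    8.15300114e-08,
    # pa^0, dT^2
    7.55043090e-04, -5.65095215e-05, -4.52166564e-07, 2.46688878e-08,
    2.42674348e-10,
    1.54547250e-04, 5.24110970e-06, -8.75874982e-08, -1.50743064e-09,
    -1.56236307e-05, -1.33895614e-07, 2.49709824e-09,
    6.51711721e-07, 1.94960053e-09,
    -1.00361113e-08,
    # pa^0, dT^3
    -1.21206673e-05, -2.18203660e-07, 7.51269482e-09, 9.79063848e-11,
    1.25006734e-06, -1.81584736e-09, -3.52197671e-10,
    -3.36514630e-08, 1.35908359e-10,
    4.17032620e-10,
    # pa^0, dT^4
    -1.30369025e-09, 4.13908461e-10, 9.22652254e-12,
    -5.08220384e-09, -2.24730961e-11,
    1.17139133e-10,
    # pa^0, dT^5
    6.62154879e-10, 4.03863260e-13,
    1.95087203e-12,
    # pa^0, dT^6
    -4.73602469e-12,
    # pa^1, dT^0
    5.12733497e+00, -3.12788561e-01, -1.96701861e-02, 9.99690870e-04,
    9.51738512e-06, -4.66426341e-07,
    5.48050612e-01, -3.30552823e-03, -1.64119440e-03, -5.16670694e-06,
    9.52692432e-07,
    -4.29223622e-02, 5.00845667e-03, 1.00601257e-06, -1.81748644e-06,
    -1.25813502e-03, -1.79330391e-04, 2.34994441e-06,
    1.29735808e-04, 1.29064870e-06,
    -2.28558686e-06,
    # pa^1, dT^1
    -3.69476348e-02, 1.62325322e-03, -3.14279680e-05, 2.59835559e-06,
    -4.77136523e-08,
    8.64203390e-03, -6.87405181e-04, -9.13863872e-06, 5.15916806e-07,
    -3.59217476e-05, 3.28696511e-05, -7.10542454e-07,
    -1.24382300e-05, -7.38584400e-09,
    2.20609296e-07,
    # pa^1, dT^2
    -7.32469180e-04, -1.87381964e-05, 4.80925239e-06, -8.75492040e-08,
    2.77862930e-05, -5.06004592e-06, 1.14325367e-07,
    2.53016723e-06, -1.72857035e-08,
    -3.95079398e-08,
    # pa^1, dT^3
    -3.59413173e-07, 7.04388046e-07, -1.89309167e-08,
    -4.79768731e-07, 7.96079978e-09,
    1.62897058e-09,
    # pa^1, dT^4
    3.94367674e-08, -1.18566247e-09,
    3.34678041e-10,
    # pa^1, dT^5
    -1.15606447e-10,
    # pa^2, dT^0
    -2.80626406e+00, 5.48712484e-01, -3.99428410e-03, -9.54009191e-04,
    1.93090978e-05,
    -3.08806365e-01, 1.16952364e-02, 4.95271903e-04, -1.90710882e-05,
    2.10787756e-03, -6.98445738e-04, 2.30109073e-05,
    4.17856590e-04, -1.27043871e-05,
    -3.04620472e-06,
    # pa^2, dT^1
    5.14507424e-02, -4.32510997e-03, 8.99281156e-05, -7.14663943e-07,
    -2.66016305e-04, 2.63789586e-04, -7.01199003e-06,
    -1.06823306e-04, 3.61341136e-06,
    2.29748967e-07,
    # pa^2, dT^2
    3.04788893e-04, -6.42070836e-05, 1.16257971e-06,
    7.68023384e-06, -5.47446896e-07,
    -3.59937910e-08,
    # pa^2, dT^3
    -4.36497725e-06, 1.68737969e-07,
    2.67489271e-08,
    # pa^2, dT^4
    3.23926897e-09,
    # pa^3, dT^0
    -3.53874123e-02, -2.21201190e-01, 1.55126038e-02, -2.63917279e-04,
    4.53433455e-02, -4.32943862e-03, 1.45389826e-04,
    2.17508610e-04, -6.66724702e-05,
    3.33217140e-05,
    # pa^3, dT^1
    -2.26921615e-03, 3.80261982e-04, -5.45314314e-09,
    -7.96355448e-04, 2.53458034e-05,
    -6.31223658e-06,
    # pa^3, dT^2
    3.02122035e-04, -4.77403547e-06,
    1.73825715e-06,
    # pa^3, dT^3
    -4.09087898e-07,
    # pa^4, dT^0
    6.14155345e-01, -6.16755931e-02, 1.33374846e-03,
    3.55375387e-03, -5.13027851e-04,
    1.02449757e-04,
    # pa^4, dT^1
    -1.48526421e-03, -4.11469183e-05,
    -6.80434415e-06,
    # pa^4, dT^2
    -9.77675906e-06,
    # pa^5, dT^0
    8.82773108e-02, -3.01859306e-03,
    1.04452989e-03,
    # pa^5, dT^1
    2.47090539e-04,
    # pa^6
    1.48348065e-03,
]


def utci_exponents():
    """(i_ta, j_va, k_dtmrt, l_pa) per term, in coefficient order."""
    out = []
    for p in range(7):
        for d in range(7 - p):
            for j in range(7 - p - d):
                for i in range(7 - p - d - j):
                    out.append((i, j, d, p))
    return out


UTCI_EXP = utci_exponents()
assert len(UTCI_EXP) == 210
assert len(UTCI_COEFS) == 210


def utci_polynomial_c(ta_c, va, tmrt_c, e_hpa):
    """Raw polynomial offset approximation, deg C; no validity masking.
    va is the 10 m wind speed; e in hPa (converted to kPa internally)."""
    dt = tmrt_c - ta_c
    pa = e_hpa / 10.0  # kPa
    acc = 0.0
    for (i, j, d, p), c in zip(UTCI_EXP, UTCI_COEFS):
        acc += c * ta_c ** i * va ** j * dt ** d * pa ** p
    return ta_c + acc


# ---------------------------------------------------------------------------
# fixture generation
# ---------------------------------------------------------------------------


def write_csv(path, header, rows, fmt):
    with open(path, "w") as fh:
        fh.write(",".join(header) + "\n")
        for row in rows:
            fh.write(",".join(f % v for f, v in zip(fmt, row)) + "\n")
    print(f"wrote {path} ({os.path.getsize(path)} bytes)")


def main():
    outdir = os.path.join("inst", "extdata", "oracle")
    os.makedirs(outdir, exist_ok=True)
    n = 1000

    # --- heat index: Ta in [5, 45] C covers both NWS regimes, RH in [0, 100]
    s = qmc.LatinHypercube(d=2, seed=20260101)
    u = s.random(n)
    ta = np.round(5.0 + 40.0 * u[:, 0], 3)
    rh = np.round(100.0 * u[:, 1], 3)
    rows = [(a, r, heat_index_c(a, r)) for a, r in zip(ta, rh)]
    write_csv(
        os.path.join(outdir, "hi_lhs.csv"),
        ["ta_c", "rh_pct", "hi_c"],
        rows,
        ["%.3f", "%.3f", "%.5f"],
    )

    # --- Liljegren Tw/Tg: daytime domain
    s = qmc.LatinHypercube(d=7, seed=20260102)
    u = s.random(n)
    ta = np.round(15.0 + 30.0 * u[:, 0], 2)
    rh = np.round(5.0 + 93.0 * u[:, 1], 2)
    ps = np.round(80000.0 + 24000.0 * u[:, 2], 0)
    u10 = np.round(0.2 + 14.8 * u[:, 3], 2)
    ghi = np.round(5.0 + 1095.0 * u[:, 4], 1)
    fdir = np.round(0.85 * u[:, 5], 3)
    cza = np.round(0.10 + 0.90 * u[:, 6], 3)
    rows = []
    for k in range(n):
        tw, tg, _ = wbgt_liljegren(ta[k], rh[k], ps[k], u10[k], ghi[k], fdir[k], cza[k])
        rows.append((ta[k], rh[k], ps[k], u10[k], ghi[k], fdir[k], cza[k], tw, tg))
    write_csv(
        os.path.join(outdir, "wbgt_lhs.csv"),
        ["ta_c", "rh_pct", "ps_pa", "u10_ms", "ghi_wm2", "f_dir", "cos_zenith",
         "tw_c", "tg_c"],
        rows,
        ["%.2f", "%.2f", "%.0f", "%.2f", "%.1f", "%.3f", "%.3f", "%.4f", "%.4f"],
    )

    # --- mean radiant temperature
    s = qmc.LatinHypercube(d=6, seed=20260103)
    u = s.random(n)
    ghi = np.round(1000.0 * u[:, 0], 2)
    alb = 0.05 + 0.35 * u[:, 1]
    cza = np.round(u[:, 2], 4)
    dni = np.round(900.0 * u[:, 3], 2)
    ldown = np.round(250.0 + 200.0 * u[:, 4], 2)
    lnet = np.round(-120.0 + 150.0 * u[:, 5], 2)
    rows = []
    for k in range(n):
        nsw = round((1.0 - alb[k]) * ghi[k], 2)
        dnih = round(dni[k] * cza[k], 2)
        t = mean_radiant_temperature_c(ghi[k], nsw, dni[k], ldown[k], dnih, lnet[k], cza[k])
        rows.append((ghi[k], nsw, dni[k], dnih, ldown[k], lnet[k], cza[k], t))
    write_csv(
        os.path.join(outdir, "mrt_lhs.csv"),
        ["ghi_wm2", "net_sw_wm2", "dni_wm2", "dni_horiz_wm2", "ldown_wm2",
         "lnet_wm2", "cos_zenith", "tmrt_c"],
        rows,
        ["%.2f", "%.2f", "%.2f", "%.2f", "%.2f", "%.2f", "%.4f", "%.5f"],
    )

    # --- UTCI polynomial over the validated domain
    s = qmc.LatinHypercube(d=4, seed=20260104)
    u = s.random(n)
    ta = np.round(-40.0 + 85.0 * u[:, 0], 4)
    va = np.round(0.5 + 16.5 * u[:, 1], 4)
    tmrt = np.round(ta + (-25.0 + 90.0 * u[:, 2]), 4)
    rows = []
    for k in range(n):
        emax = min(0.95 * svp_buck(ta[k]), 45.0)
        e = round(0.05 + (emax - 0.05) * u[k, 3], 4)
        val = utci_polynomial_c(ta[k], va[k], tmrt[k], e)
        rows.append((ta[k], va[k], tmrt[k], e, val))
    write_csv(
        os.path.join(outdir, "utci_lhs.csv"),
        ["ta_c", "u10_ms", "tmrt_c", "e_hpa", "utci_c"],
        rows,
        ["%.4f", "%.4f", "%.4f", "%.4f", "%.7f"],
    )

    # --- emit the shared coefficient table for the R package
    with open(os.path.join("R", "utci_coefficients.R"), "w") as fh:
        fh.write(
            "# Coefficient table of the published sixth-order UTCI polynomial\n"
            "# approximation (offset from air temperature as a full degree-6\n"
            "# polynomial in Ta [degC], va [m/s], Tmrt - Ta [degC] and vapor\n"
            "# pressure [kPa]; 210 terms). Generated by\n"
            "# data-raw/oracle_reference.py -- do not edit by hand.\n\n"
        )
        fh.write(".utci_exponents <- matrix(c(\n")
        fh.write(
            ",\n".join(
                "  %dL, %dL, %dL, %dL" % (i, j, d, p) for (i, j, d, p) in UTCI_EXP
            )
        )
        fh.write(
            "\n), ncol = 4L, byrow = TRUE,\n"
            '  dimnames = list(NULL, c("ta", "va", "dtmrt", "pa")))\n\n'
        )
        fh.write(".utci_coefs <- c(\n")
        fh.write(",\n".join("  %.8e" % c for c in UTCI_COEFS))
        fh.write("\n)\n")
    print("wrote R/utci_coefficients.R")

    # --- anchor-value sanity checks -------------------------------------
    # NWS heat-index table: 96 F / 50 % -> 108 F (printed to the nearest
    # degree F); simple-regime value at 70 F / 50 %.
    hi_f = heat_index_c((96 - 32) * 5 / 9, 50.0) * 9 / 5 + 32
    print(f"HI(96F, 50%) = {hi_f:.2f} F (NWS table: 108)")
    assert abs(hi_f - 108.0) < 1.0
    # UTCI reference conditions: Ta 25 C, Tmrt 25 C, va 1 m/s, RH 50 %
    e25 = 0.5 * svp_buck(25.0)
    u_ref = utci_polynomial_c(25.0, 1.0, 25.0, e25)
    print(f"UTCI(25C, va 1, Tmrt 25, RH 50) = {u_ref:.3f} C (expect ~24.5-25)")
    assert 24.0 < u_ref < 25.5
    # Liljegren plausibility: hot sunny afternoon
    tw, tg, wb = wbgt_liljegren(35.0, 50.0, 101325.0, 2.0, 1000.0, 0.75, 0.9)
    print(f"Liljegren(35C,50%,sunny): Tw={tw:.2f} Tg={tg:.2f} WBGT={wb:.2f}")
    assert 24.0 < tw < 31.0 and 40.0 < tg < 60.0
    # MRT isotropic longwave equilibrium: Ldown = sigma*300^4, no shortwave
    t300 = mean_radiant_temperature_c(0, 0, 0, SIGMA_MRT * 300.0 ** 4, 0, 0.0, 0.0)
    print(f"MRT isothermal 300K check = {t300 + 273.15:.4f} K")
    assert abs(t300 + 273.15 - 300.0) < 1e-6


if __name__ == "__main__":
    main()
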