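#!/usr/bin/env python
"""Independent carbonate-system oracle.

Computes water pCO2 from the (pH_NBS, total alkalinity) input pair over a
grid of temperature / salinity / pH / TA spanning the observed ranges of
Mediterranean wetland waters, and writes the frozen reference table used by
the R test-suite (inst/extdata/carbonate_oracle_grid.csv).

This implementation is deliberately independent of the R package:
  * all internal arithmetic on the TOTAL hydrogen-ion scale (the package
    works on the NBS scale),
  * fluoride and bisulfate association handled explicitly,
  * pCO2 obtained via DIC and the CO2* ionization fraction (alpha0) rather
    than via the carbonate-alkalinity partition used in the package,
  * coefficients typed from the original publications in a second pass.

Constant choices match the package's declared options: Weiss (1974)
volumetric K0; Cai & Wang (1998) K1/K2 (native NBS, converted here to total);
Dickson (1990b) KB; Millero (1995) KW; Yao & Millero (1995) phosphate and
silicate; Dickson (1990a) KS; Dickson & Riley (1979) KF; Takahashi et
al. (1982) fH.  Concentrations are treated volumetrically (umol/L), as in the
package.

Run:  python data-raw/carbonate_oracle.py
"""

import csv
import math
import os

OUT = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata",
                   "carbonate_oracle_grid.csv")


def constants_total_scale(t_c, s):
    """All constants on the total hydrogen scale (except K0, KS-free, fH)."""
    tk = t_c + 273.15
    lnt = math.log(tk)
    sq = math.sqrt(s)
    ion = 19.924 * s / (1000.0 - 1.005 * s)
    sqi = math.sqrt(ion)

    k0 = math.exp(-58.0931 + 90.5069 * (100.0 / tk)
                  + 22.2940 * math.log(tk / 100.0)
                  + s * (0.027766 - 0.025888 * (tk / 100.0)
                         + 0.0050578 * (tk / 100.0) ** 2))

    fh = 1.2948 - 0.002036 * tk + (0.0004607 - 0.000001475 * tk) * s * s

    # totals (umol/L, volumetric bookkeeping)
    tb = 415.7 * s / 35.0
    ts = 28240.0 * s / 35.0
    tf = 70.0 * s / 35.0

    # bisulfate (free scale) and fluoride (free scale)
    lnks = (-4276.1 / tk + 141.328 - 23.093 * lnt
            + (-13856.0 / tk + 324.57 - 47.986 * lnt) * sqi
            + (35474.0 / tk - 771.54 + 114.723 * lnt) * ion
            - (2698.0 / tk) * sqi * ion + (1776.0 / tk) * ion * ion
            + math.log(1.0 - 0.001005 * s))
    ks = math.exp(lnks)  # mol-scale; totals below are umol so convert terms
    lnkf = 1590.2 / tk - 12.641 + 1.525 * sqi + math.log(1.0 - 0.001005 * s)
    kf = math.exp(lnkf)

    # scale-conversion factors (concentrations in mol units)
    ts_m = ts * 1e-6
    tf_m = tf * 1e-6
    sws_over_tot = (1.0 + ts_m / ks + tf_m / kf) / (1.0 + ts_m / ks)
    # [H]sws = [H]tot * sws_over_tot ; [H]nbs = fh * [H]sws

    # Cai & Wang (1998): native NBS -> total
    f1 = 200.1 / tk + 0.3220
    pk1 = (3404.71 / tk + 0.032786 * tk - 14.8435
           - 0.071692 * f1 * sq + 0.0021487 * s)
    f2 = -129.24 / tk + 1.4381
    pk2 = (2902.39 / tk + 0.02379 * tk - 6.4980
           - 0.3191 * f2 * sq + 0.0198 * s)
    nbs_to_tot = 1.0 / (fh * sws_over_tot)
    k1 = 10.0 ** (-pk1) * nbs_to_tot
    k2 = 10.0 ** (-pk2) * nbs_to_tot

    # Dickson (1990b) KB, native total scale
    lnkb = ((-8966.90 - 2890.53 * sq - 77.942 * s + 1.728 * s ** 1.5
             - 0.0996 * s * s) / tk
            + 148.0248 + 137.1942 * sq + 1.62142 * s
            - (24.4344 + 25.085 * sq + 0.2474 * s) * lnt
            + 0.053105 * sq * tk)
    kb = math.exp(lnkb)

    # Millero (1995) KW, seawater scale -> total
    lnkw = (148.9802 - 13847.26 / tk - 23.6521 * lnt
            + (118.67 / tk - 5.977 + 1.0495 * lnt) * sq - 0.01615 * s)
    kw = math.exp(lnkw) / sws_over_tot

    # Yao & Millero (1995), seawater scale -> total
    lnkp1 = (-4576.752 / tk + 115.54 - 18.453 * lnt
             + (-106.736 / tk + 0.69171) * sq + (-0.65643 / tk - 0.01844) * s)
    lnkp2 = (-8814.715 / tk + 172.1033 - 27.927 * lnt
             + (-160.340 / tk + 1.3566) * sq + (0.37335 / tk - 0.05778) * s)
    lnkp3 = (-3070.75 / tk - 18.126
             + (17.27039 / tk + 2.81197) * sq + (-44.99486 / tk - 0.09984) * s)
    lnksi = (-8904.2 / tk + 117.4 - 19.334 * lnt
             + (-458.79 / tk + 3.5913) * sqi + (188.74 / tk - 1.5998) * ion
             + (-12.1652 / tk + 0.07871) * ion * ion
             + math.log(1.0 - 0.001005 * s))
    kp1 = math.exp(lnkp1) / sws_over_tot
    kp2 = math.exp(lnkp2) / sws_over_tot
    kp3 = math.exp(lnkp3) / sws_over_tot
    ksi = math.exp(lnksi) / sws_over_tot

    return dict(k0=k0, k1=k1, k2=k2, kb=kb, kw=kw, kp1=kp1, kp2=kp2,
                kp3=kp3, ksi=ksi, ks=ks, kf=kf, fh=fh,
                tb=tb, ts=ts_m, tf=tf_m, sws_over_tot=sws_over_tot)


def speciate(t_c, s, ph_nbs, ta, po4, si):
    """pCO2 (uatm) and DIC (umol/L) from pH(NBS) + TA (umol/L)."""
    k = constants_total_scale(t_c, s)
    h_nbs = 10.0 ** (-ph_nbs)
    h = h_nbs / (k["fh"] * k["sws_over_tot"])  # total scale
    h_free = h / (1.0 + k["ts"] / k["ks"])

    borate = k["tb"] * k["kb"] / (k["kb"] + h)
    oh = k["kw"] / h * 1e6
    hso4 = k["ts"] * h_free / (k["ks"] + h_free) * 1e6
    hf = k["tf"] * h_free / (k["kf"] + h_free) * 1e6
    denom = (h ** 3 + k["kp1"] * h ** 2 + k["kp1"] * k["kp2"] * h
             + k["kp1"] * k["kp2"] * k["kp3"])
    phos = po4 * (k["kp1"] * k["kp2"] * h + 2 * k["kp1"] * k["kp2"] * k["kp3"]
                  - h ** 3) / denom
    sil = si * k["ksi"] / (k["ksi"] + h)

    ca = ta - borate - oh + h_free * 1e6 + hso4 + hf - phos - sil
    if ca <= 0:
        return float("nan"), float("nan")

    # DIC route: CA = DIC * (K1 h + 2 K1 K2) / (h^2 + K1 h + K1 K2)
    d = h * h + k["k1"] * h + k["k1"] * k["k2"]
    dic = ca * d / (k["k1"] * h + 2.0 * k["k1"] * k["k2"])
    alpha0 = h * h / d
    co2_star = dic * alpha0
    pco2 = co2_star / k["k0"]
    return pco2, dic


def main():
    temps = [10.0, 20.0, 30.0]
    sals = [0.0, 5.0, 18.0, 35.0]
    phs = [7.0, 8.0, 9.0]
    tas = [1800.0, 3000.0, 6000.0]
    po4, si = 2.84, 141.91

    rows = []
    for t in temps:
        for s in sals:
            for ph in phs:
                for ta in tas:
                    pco2, dic = speciate(t, s, ph, ta, po4, si)
                    k = constants_total_scale(t, s)
                    rows.append(dict(
                        temp_c=t, salinity=s, ph_nbs=ph, alk_umol_l=ta,
                        po4_umol_l=po4, sioh4_umol_l=si,
                        pco2_uatm=round(pco2, 6), dic_umol_l=round(dic, 6),
                        k0_mol_l_atm=round(k["k0"], 9)))

    os.makedirs(os.path.dirname(OUT), exist_ok=True)
    with open(OUT, "w", newline="") as fh:
        w = csv.DictWriter(fh, fieldnames=list(rows[0].keys()))
        w.writeheader()
        w.writerows(rows)
    print(f"wrote {len(rows)} rows to {OUT}")


if __name__ == "__main__":
    main()
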