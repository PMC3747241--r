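# Carbonate-system speciation from the pH-total alkalinity input pair.
#
# All equilibrium constants are expressed on the NBS pH scale, so that the
# hydrogen-ion term entering every mass-action expression is the activity
# 10^(-pH_NBS) read directly off an NBS-calibrated electrode.  Constants whose
# source formulations are on the seawater scale are converted with the
# activity-coefficient factor fH(T,S).  Concentrations are volumetric
# (umol L-1) throughout, matching how inland-water alkalinity and nutrient
# data are reported; the per-kg constants are used as printed, which for the
# salinities of interest (mostly S < 20) introduces well under a percent of
# error and at S = 35 at most ~2.5% in pCO2.

#' Equilibrium constants of the aquatic CO2 system
#'
#' Evaluates the full constant set needed to speciate the carbonate system of
#' an inland or estuarine water sample at in-situ temperature and salinity.
#'
#' Formulations: CO2 solubility \eqn{K_0} from Weiss (1974, volumetric
#' coefficients, mol L-1 atm-1); carbonic acid \eqn{K_1}, \eqn{K_2} from the
#' estuarine fit of Cai & Wang (1998), which is reported natively on the NBS
#' scale and remains valid down to salinity 0; boric acid from Dickson (1990b);
#' water from Millero (1995); phosphoric and silicic acids from Yao & Millero
#' (1995); bisulfate from Dickson (1990a, free scale, retained for scale
#' diagnostics); and the NBS activity factor fH from Takahashi et al. (1982).
#' Seawater-scale constants are multiplied by fH so that every dissociation
#' constant pairs with the NBS hydrogen-ion activity \code{10^-pH}.
#'
#' Total borate (Uppstrom 1974) and total sulfate (Morris & Riley 1966) scale
#' linearly with salinity and are zero in fresh water.
#'
#' @param temp_c Water temperature, degrees C.
#' @param salinity Practical salinity (dimensionless, >= 0).
#' @param pressure_dbar Pressure, dbar; only the surface value 0 is supported
#'   (no deep-water corrections are applied).
#' @param quiet Suppress the validity-envelope warning.
#'
#' @return A tibble with one row per input: `k0` (mol L-1 atm-1), `k1`, `k2`,
#'   `kb`, `kw`, `kp1`, `kp2`, `kp3`, `ksi` (NBS scale), `ks` (free scale),
#'   `fh`, `total_borate_umol_l`, `total_sulfate_umol_l`, plus the inputs.
#'
#' @examples
#' carbonate_constants(25, 0)$k0    # ~0.034 mol L-1 atm-1
#' carbonate_constants(25, 35)$k1 / carbonate_constants(25, 35)$k2
#' @export
carbonate_constants <- function(temp_c, salinity, pressure_dbar = 0, quiet = FALSE) {
  n <- max(length(temp_c), length(salinity))
  temp_c <- rep_len(temp_c, n)
  salinity <- rep_len(salinity, n)
  stopifnot(all(is.finite(temp_c)), all(is.finite(salinity)), all(salinity >= 0))

  if (!quiet && any(salinity > 40 | temp_c < 0 | temp_c > 35)) {
    warn(paste(
      "carbonate_constants(): some inputs fall outside the fitted validity",
      "envelope of the estuarine K1/K2 formulation (T 0-35 C, S 0-40);",
      "constants are extrapolated."
    ))
  }

  tk  <- temp_c + 273.15
  lnt <- log(tk)
  s   <- salinity
  sqs <- sqrt(s)

  # CO2 solubility, Weiss (1974), volumetric coefficients -> mol L-1 atm-1
  k0 <- exp(-58.0931 + 90.5069 * (100 / tk) + 22.2940 * log(tk / 100) +
              s * (0.027766 - 0.025888 * (tk / 100) + 0.0050578 * (tk / 100)^2))

  # NBS activity-coefficient factor, Takahashi et al. (1982)
  fh <- 1.2948 - 0.002036 * tk + (0.0004607 - 0.000001475 * tk) * s^2

  # Carbonic acid, Cai & Wang (1998) -- natively NBS scale
  f1  <- 200.1 / tk + 0.3220
  pk1 <- 3404.71 / tk + 0.032786 * tk - 14.8435 - 0.071692 * f1 * sqs + 0.0021487 * s
  f2  <- -129.24 / tk + 1.4381
  pk2 <- 2902.39 / tk + 0.02379 * tk - 6.4980 - 0.3191 * f2 * sqs + 0.0198 * s
  k1  <- 10^(-pk1)
  k2  <- 10^(-pk2)

  # Boric acid, Dickson (1990b), total scale -> NBS via fH
  # (without fluoride bookkeeping the total and seawater scales coincide)
  lnkb <- (-8966.90 - 2890.53 * sqs - 77.942 * s + 1.728 * s^1.5 - 0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqs + 1.62142 * s -
    (24.4344 + 25.085 * sqs + 0.2474 * s) * lnt + 0.053105 * sqs * tk
  kb <- exp(lnkb) * fh

  # Water, Millero (1995), seawater scale -> NBS
  lnkw <- 148.9802 - 13847.26 / tk - 23.6521 * lnt +
    (118.67 / tk - 5.977 + 1.0495 * lnt) * sqs - 0.01615 * s
  kw <- exp(lnkw) * fh

  # Phosphoric acid, Yao & Millero (1995), seawater scale -> NBS
  lnkp1 <- -4576.752 / tk + 115.54 - 18.453 * lnt +
    (-106.736 / tk + 0.69171) * sqs + (-0.65643 / tk - 0.01844) * s
  lnkp2 <- -8814.715 / tk + 172.1033 - 27.927 * lnt +
    (-160.340 / tk + 1.3566) * sqs + (0.37335 / tk - 0.05778) * s
  lnkp3 <- -3070.75 / tk - 18.126 +
    (17.27039 / tk + 2.81197) * sqs + (-44.99486 / tk - 0.09984) * s
  kp1 <- exp(lnkp1) * fh
  kp2 <- exp(lnkp2) * fh
  kp3 <- exp(lnkp3) * fh

  # Silicic acid, Yao & Millero (1995), ionic-strength form, seawater -> NBS
  ion <- 19.924 * s / (1000 - 1.005 * s)
  sqi <- sqrt(ion)
  lnksi <- -8904.2 / tk + 117.4 - 19.334 * lnt +
    (-458.79 / tk + 3.5913) * sqi + (188.74 / tk - 1.5998) * ion +
    (-12.1652 / tk + 0.07871) * ion^2 + log(1 - 0.001005 * s)
  ksi <- exp(lnksi) * fh

  # Bisulfate, Dickson (1990a), free scale
  lnks <- -4276.1 / tk + 141.328 - 23.093 * lnt +
    (-13856 / tk + 324.57 - 47.986 * lnt) * sqi +
    (35474 / tk - 771.54 + 114.723 * lnt) * ion -
    (2698 / tk) * sqi * ion + (1776 / tk) * ion^2 + log(1 - 0.001005 * s)
  ks <- exp(lnks)

  tibble(
    temp_c = temp_c, salinity = salinity, pressure_dbar = pressure_dbar,
    k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw,
    kp1 = kp1, kp2 = kp2, kp3 = kp3, ksi = ksi, ks = ks, fh = fh,
    total_borate_umol_l = 415.7 * s / 35,
    total_sulfate_umol_l = 28240 * s / 35
  )
}

#' Fill missing nutrient concentrations with data-set defaults
#'
#' Phosphate and silicate enter the alkalinity budget only through small
#' correction terms, so occasional missing determinations are replaced by
#' data-set average values rather than dropping the sample.  The provenance of
#' each value is recorded in `po4_source` / `si_source` columns
#' (`"measured"` or `"default"`).
#'
#' @param samples A data frame of water samples with (possibly `NA`, possibly
#'   absent) `po4_umol_l` and `sioh4_umol_l` columns.
#' @param po4_default,si_default Replacement concentrations, umol L-1.
#'
#' @return The input tibble with complete nutrient columns and provenance flags.
#' @examples
#' fill_missing_nutrients(tibble::tibble(po4_umol_l = c(1, NA),
#'                                       sioh4_umol_l = c(NA, NA)))
#' @export
fill_missing_nutrients <- function(samples, po4_default = 2.84, si_default = 141.91) {
  samples <- as_tibble(samples)
  if (!"po4_umol_l" %in% names(samples)) samples$po4_umol_l <- NA_real_
  if (!"sioh4_umol_l" %in% names(samples)) samples$sioh4_umol_l <- NA_real_
  samples %>%
    mutate(
      po4_source = ifelse(is.na(.data$po4_umol_l), "default", "measured"),
      si_source = ifelse(is.na(.data$sioh4_umol_l), "default", "measured"),
      po4_umol_l = ifelse(is.na(.data$po4_umol_l), po4_default, .data$po4_umol_l),
      sioh4_umol_l = ifelse(is.na(.data$sioh4_umol_l), si_default, .data$sioh4_umol_l)
    )
}

#' Non-carbonate contributions to total alkalinity
#'
#' Decomposes the non-carbonate part of total alkalinity at a given NBS
#' hydrogen-ion activity into its four component terms: borate, hydroxide
#' minus free hydrogen, phosphate (relative to H2PO4-: HPO4 counts +1, PO4 +2,
#' H3PO4 -1) and silicate.  The hydrogen term is the seawater-scale
#' concentration `h / fH`, which already includes the bisulfate association.
#'
#' @param h_nbs Hydrogen-ion activity, `10^-pH(NBS)`.
#' @param constants One row (or recycled rows) from [carbonate_constants()].
#' @param po4_umol_l,sioh4_umol_l Nutrient concentrations, umol L-1.
#'
#' @return A tibble with `borate_umol_l`, `hydroxide_minus_proton_umol_l`,
#'   `phosphate_umol_l`, `silicate_umol_l` and their sum `total_umol_l`.
#' @export
noncarbonate_alkalinity <- function(h_nbs, constants, po4_umol_l = 0, sioh4_umol_l = 0) {
  stopifnot(all(h_nbs > 0))
  k <- constants
  borate <- k$total_borate_umol_l * k$kb / (k$kb + h_nbs)
  oh_minus_h <- (k$kw / h_nbs - h_nbs / k$fh) * 1e6
  ph3 <- h_nbs^3 + k$kp1 * h_nbs^2 + k$kp1 * k$kp2 * h_nbs + k$kp1 * k$kp2 * k$kp3
  phosphate <- po4_umol_l *
    (k$kp1 * k$kp2 * h_nbs + 2 * k$kp1 * k$kp2 * k$kp3 - h_nbs^3) / ph3
  silicate <- sioh4_umol_l * k$ksi / (k$ksi + h_nbs)
  tibble(
    borate_umol_l = borate,
    hydroxide_minus_proton_umol_l = oh_minus_h,
    phosphate_umol_l = phosphate,
    silicate_umol_l = silicate,
    total_umol_l = borate + oh_minus_h + phosphate + silicate
  )
}

#' Speciate the carbonate system from pH and total alkalinity
#'
#' With the pH-TA input pair the system is closed-form: the hydrogen-ion
#' activity comes straight from the measured NBS pH, carbonate alkalinity is
#' total alkalinity minus the non-carbonate terms evaluated at that activity,
#' bicarbonate and carbonate partition carbonate alkalinity through
#' \eqn{K_2}, \eqn{CO_2^* = [HCO_3^-]\,h / K_1} and
#' \eqn{pCO_2 = CO_2^* / K_0}.
#'
#' Samples whose non-carbonate alkalinity exceeds the measured total
#' alkalinity (carbonate alkalinity <= 0) are flagged `speciation_ok = FALSE`
#' and carry `NA` species with the offending carbonate alkalinity retained for
#' diagnosis; they are never silently dropped.
#'
#' @param samples A data frame with columns `temp_c`, `salinity`, `ph_nbs`,
#'   `alk_umol_l` and complete `po4_umol_l`, `sioh4_umol_l` (see
#'   [fill_missing_nutrients()]).
#' @param constants Optional precomputed [carbonate_constants()] rows matching
#'   `samples`; computed from `temp_c`/`salinity` when `NULL`.
#' @param quiet Passed to [carbonate_constants()].
#'
#' @return The input tibble plus `co2_star_umol_l`, `hco3_umol_l`,
#'   `co3_umol_l`, `dic_umol_l`, `pco2_uatm`, `carb_alk_umol_l`,
#'   `nc_alk_umol_l` and `speciation_ok`.
#'
#' @examples
#' s <- tibble::tibble(temp_c = 20, salinity = 1, ph_nbs = 8,
#'                     alk_umol_l = 3000, po4_umol_l = 2.84,
#'                     sioh4_umol_l = 141.91)
#' speciate(s)$pco2_uatm
#' @export
speciate <- function(samples, constants = NULL, quiet = FALSE) {
  samples <- as_tibble(samples)
  need <- c("temp_c", "salinity", "ph_nbs", "alk_umol_l", "po4_umol_l", "sioh4_umol_l")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "speciate(): missing columns: ", paste(missing_cols, collapse = ", "),
      if (any(c("po4_umol_l", "sioh4_umol_l") %in% missing_cols))
        " (run fill_missing_nutrients() first)" else ""
    ))
  }
  if (anyNA(samples[need])) {
    abort("speciate(): NA values in required columns; fill nutrients and drop incomplete samples first.")
  }
  if (is.null(constants)) {
    constants <- carbonate_constants(samples$temp_c, samples$salinity, quiet = quiet)
  }

  h <- 10^(-samples$ph_nbs)
  nc <- noncarbonate_alkalinity(h, constants, samples$po4_umol_l, samples$sioh4_umol_l)
  carb_alk <- samples$alk_umol_l - nc$total_umol_l
  ok <- carb_alk > 0

  hco3 <- ifelse(ok, carb_alk / (1 + 2 * constants$k2 / h), NA_real_)
  co3 <- hco3 * constants$k2 / h
  co2_star <- hco3 * h / constants$k1
  dic <- co2_star + hco3 + co3
  pco2 <- co2_star / constants$k0

  if (!all(ok)) {
    warn(sprintf(
      "speciate(): %d sample(s) with non-carbonate alkalinity exceeding total alkalinity flagged invalid.",
      sum(!ok)
    ))
  }

  samples %>%
    mutate(
      co2_star_umol_l = co2_star, hco3_umol_l = hco3, co3_umol_l = co3,
      dic_umol_l = dic, pco2_uatm = pco2,
      carb_alk_umol_l = carb_alk, nc_alk_umol_l = nc$total_umol_l,
      k0_mol_l_atm = constants$k0,
      speciation_ok = ok
    )
}

#' Invert speciation: the NBS pH that reproduces a target pCO2
#'
#' Solves for the pH at which [speciate()] returns `pco2_uatm = pco2_target`
#' given alkalinity, temperature and salinity.  pCO2 is strictly decreasing in
#' pH at fixed TA, so the root is unique.  Used by the synthetic-data
#' generator to emit internally consistent (pH, TA) pairs.
#'
#' @param pco2_target Target water-side pCO2, uatm.
#' @param alk_umol_l,temp_c,salinity,po4_umol_l,sioh4_umol_l Sample conditions.
#' @param interval pH search interval.
#' @return The NBS pH (vectorized over the inputs).
#' @export
ph_for_pco2 <- function(pco2_target, alk_umol_l, temp_c, salinity,
                        po4_umol_l = 2.84, sioh4_umol_l = 141.91,
                        interval = c(4.2, 11.8)) {
  n <- max(lengths(list(pco2_target, alk_umol_l, temp_c, salinity)))
  args <- lapply(
    list(pco2_target = pco2_target, alk_umol_l = alk_umol_l, temp_c = temp_c,
         salinity = salinity, po4_umol_l = po4_umol_l, sioh4_umol_l = sioh4_umol_l),
    rep_len, n
  )
  purrr::pmap_dbl(args, function(pco2_target, alk_umol_l, temp_c, salinity,
                                 po4_umol_l, sioh4_umol_l) {
    k <- carbonate_constants(temp_c, salinity, quiet = TRUE)
    co2_star <- k$k0 * pco2_target          # umol L-1, fixed by the target
    f <- function(ph) {
      h <- 10^(-ph)
      hco3 <- co2_star * k$k1 / h
      co3 <- hco3 * k$k2 / h
      nc <- noncarbonate_alkalinity(h, k, po4_umol_l, sioh4_umol_l)$total_umol_l
      (hco3 + 2 * co3 + nc) - alk_umol_l    # strictly decreasing in h
    }
    uniroot(f, interval = interval, tol = 1e-10)$root
  })
}
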