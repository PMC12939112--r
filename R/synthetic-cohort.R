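#' Cohort specification
#'
#' Generative model for synthetic per-patient tables with the statistical
#' structure the cohort analysis assumes: a PH / no-PH mixture on mPAP
#' (log-normal within group, strictly separated at the 20 mmHg threshold so
#' that group membership is derivable from mPAP alone), hemodynamics with
#' group-specific locations, and morphometry readouts tied to mPAP through a
#' Gaussian copula (rank statistics depend only on the copula, so Spearman
#' targets are directly interpretable). The artery/vein labeling accuracy is
#' planted with an exact number of sub-threshold rows to exercise the
#' exclusion flow.
#'
#' @param n_patients Number of rows (>= 4).
#' @param prevalence Probability of PH per patient.
#' @param rho_ratio_mpap Target Spearman correlation between the 6-10 mm
#'   artery-to-vein ratio and mPAP.
#' @param link_scale Multiplier on all readout-hemodynamic copula links
#'   (0 = null model, 1 = calibrated).
#' @param n_low_accuracy Number of rows planted with labeling accuracy
#'   below 0.80; `NULL` for the default share (31.1% of rows, rounded).
#' @param missing_rate MCAR missingness applied to hemodynamic columns
#'   other than mPAP.
#' @param seed Integer RNG seed; the output is a pure function of
#'   (spec, seed).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 170, prevalence = 149 / 170,
                        rho_ratio_mpap = 0.41, link_scale = 1,
                        n_low_accuracy = NULL, missing_rate = 0,
                        seed = 1L) {
  if (n_patients < 4) stop("n_patients must be at least 4", call. = FALSE)
  if (is.null(n_low_accuracy))
    n_low_accuracy <- round(0.311 * n_patients)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 rho_ratio_mpap = rho_ratio_mpap,
                 link_scale = link_scale,
                 n_low_accuracy = as.integer(n_low_accuracy),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Spearman target -> Pearson correlation of the Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# group-conditional truncated log-normal quantile
qlnorm_trunc <- function(u, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + u * (phi - plo), meanlog, sdlog)
}

sdlog_from_iqr <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Generate a synthetic cohort table
#'
#' See [cohort_spec()] for the generative model. Marginals are matched to
#' typical PH-referral cohorts: no-PH mPAP median 17 mmHg (IQR 16-19),
#' PH median 38 (29-48); PVR 1.4 vs 5.5 WU; DMPA linear in mPAP with noise;
#' the 6-10 mm artery/vein ratio linked to mPAP at the target Spearman
#' correlation; vein 6-10 mm density weakly negatively linked, with the
#' arterial density emerging as ratio x vein density; segment totals around
#' 1840 with density = count / lung volume holding exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort tibble (see [cohort_columns()]) with derived
#'   `ph_status`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ls <- spec$link_scale

  # single monotone latent u drives both group membership and mPAP, so that
  # mPAP is a monotone map of u and group = (mPAP > 20) exactly
  u <- stats::runif(n)
  ph <- u > (1 - spec$prevalence)
  u_in_group <- ifelse(ph, (u - (1 - spec$prevalence)) / spec$prevalence,
                       u / (1 - spec$prevalence))
  mpap <- ifelse(ph,
                 qlnorm_trunc(u_in_group, log(38), sdlog_from_iqr(29, 48),
                              20.0001, 120),
                 qlnorm_trunc(u_in_group, log(17), sdlog_from_iqr(16, 19),
                              5, 20))
  z <- stats::qnorm(u)  # copula latent of mPAP

  link <- function(rho_s, scale = ls) {
    r <- spearman_to_pearson(rho_s) * scale
    r * z + sqrt(1 - r^2) * stats::rnorm(n)
  }
  to_u <- stats::pnorm

  grp_lnorm <- function(zlat, med0, iqr0, med1, iqr1) {
    uu <- to_u(zlat)
    ifelse(ph,
           stats::qlnorm(uu, log(med1), sdlog_from_iqr(iqr1[1], iqr1[2])),
           stats::qlnorm(uu, log(med0), sdlog_from_iqr(iqr0[1], iqr0[2])))
  }
  grp_norm <- function(zlat, m0, s0, m1, s1) {
    uu <- to_u(zlat)
    ifelse(ph, stats::qnorm(uu, m1, s1), stats::qnorm(uu, m0, s0))
  }

  pvr <- grp_lnorm(link(0.7), 1.4, c(1.0, 2.4), 5.5, c(3.3, 8.2))
  pawp <- grp_lnorm(link(0.3), 9, c(8, 10), 14, c(10, 18))
  ci <- grp_lnorm(link(-0.25), 2.34, c(2.08, 2.71), 2.30, c(1.90, 2.77))
  svo2 <- grp_norm(link(-0.3), 69, 6, 66, 7)
  rap <- grp_lnorm(link(0.4), 5, c(2, 7), 8, c(5, 11))
  age <- pmin(95, pmax(18, grp_norm(stats::rnorm(n), 59, 11, 69, 13)))
  bsa <- pmax(1.2, grp_norm(stats::rnorm(n), 2.12, 0.25, 1.87, 0.25))

  dmpa <- pmax(15, 23.15 + 0.25 * mpap + stats::rnorm(n, 0, 2.5))
  dao <- pmax(24, stats::rnorm(n, 33, 3))

  lung_vol <- stats::qlnorm(to_u(stats::rnorm(n)), log(4.3),
                            sdlog_from_iqr(3.5, 5.4))

  # readouts
  n_seg <- round(stats::qlnorm(to_u(stats::rnorm(n)), log(1843),
                               sdlog_from_iqr(1540, 2151)))
  ratio_6_10 <- stats::qlnorm(to_u(link(spec$rho_ratio_mpap)), log(1.2),
                              sdlog_from_iqr(0.85, 1.9))
  dens_vein_6_10 <- stats::qlnorm(to_u(link(-0.24)), log(6.3),
                                  sdlog_from_iqr(4.7, 7.8))
  count_vein_6_10 <- pmax(1, round(dens_vein_6_10 * lung_vol))
  count_artery_6_10 <- pmax(0, round(ratio_6_10 * count_vein_6_10))

  share_artery <- pmin(0.6, pmax(0.4, stats::rnorm(n, 0.505, 0.02)))
  count_artery_all <- round(n_seg * share_artery)
  count_vein_all <- n_seg - count_artery_all
  dens_artery_4_6 <- stats::qlnorm(to_u(link(0.15)), log(19), sdlog_from_iqr(15, 24))
  dens_vein_4_6 <- stats::qlnorm(to_u(link(-0.05)), log(20), sdlog_from_iqr(16, 24))
  count_artery_4_6 <- pmax(0, round(dens_artery_4_6 * lung_vol))
  count_vein_4_6 <- pmax(1, round(dens_vein_4_6 * lung_vol))
  count_artery_2_4 <- pmax(0, count_artery_all - count_artery_4_6 - count_artery_6_10)
  count_vein_2_4 <- pmax(1, count_vein_all - count_vein_4_6 - count_vein_6_10)

  soam_all <- pmax(0.05, grp_norm(link(-0.3), 0.15, 0.012, 0.14, 0.012))
  soam_art <- pmax(0.05, grp_norm(link(-0.3), 0.155, 0.012, 0.14, 0.012))
  soam_vein <- pmax(0.05, grp_norm(link(-0.3), 0.15, 0.012, 0.13, 0.012))

  vessel_vol <- stats::qlnorm(to_u(link(-0.2)), log(6e4), 0.25)

  # planted labeling accuracy: exactly n_low rows below the 0.80 threshold
  n_low <- min(spec$n_low_accuracy, n)
  acc <- 0.80 + 0.20 * stats::runif(n)
  low_rows <- sample.int(n, n_low)
  acc[low_rows] <- 0.40 + 0.395 * stats::runif(n_low)

  tab <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    mPAP = mpap, PVR = pvr, PAWP = pawp, CI = ci, SvO2 = svo2, RAP = rap,
    age = age, BSA = bsa, DMPA = dmpa, DAo = dao,
    lung_volume_L = lung_vol, av_accuracy = acc,
    n_segments_total = n_seg,
    vessel_volume_mm3 = vessel_vol,
    density_total = n_seg / lung_vol,
    normalized_vessel_volume = vessel_vol * 1e-6 / lung_vol,
    count_artery_2_4 = count_artery_2_4, count_artery_4_6 = count_artery_4_6,
    count_artery_6_10 = count_artery_6_10, count_artery_all = count_artery_all,
    count_vein_2_4 = count_vein_2_4, count_vein_4_6 = count_vein_4_6,
    count_vein_6_10 = count_vein_6_10, count_vein_all = count_vein_all,
    density_artery_2_4 = count_artery_2_4 / lung_vol,
    density_artery_4_6 = count_artery_4_6 / lung_vol,
    density_artery_6_10 = count_artery_6_10 / lung_vol,
    density_artery_all = count_artery_all / lung_vol,
    density_vein_2_4 = count_vein_2_4 / lung_vol,
    density_vein_4_6 = count_vein_4_6 / lung_vol,
    density_vein_6_10 = count_vein_6_10 / lung_vol,
    density_vein_all = count_vein_all / lung_vol,
    soam_median_artery = soam_art, soam_median_vein = soam_vein,
    soam_median_all = soam_all,
    density_diff_av_2_4 = (count_artery_2_4 - count_vein_2_4) / lung_vol,
    density_diff_av_4_6 = (count_artery_4_6 - count_vein_4_6) / lung_vol,
    density_diff_av_6_10 = (count_artery_6_10 - count_vein_6_10) / lung_vol,
    ratio_av_2_4 = count_artery_2_4 / count_vein_2_4,
    ratio_av_4_6 = count_artery_4_6 / count_vein_4_6,
    ratio_av_6_10 = count_artery_6_10 / count_vein_6_10
  )
  if (spec$missing_rate > 0) {
    for (col in c("PVR", "PAWP", "CI", "SvO2", "RAP", "age", "BSA")) {
      miss <- stats::runif(n) < spec$missing_rate
      tab[[col]][miss] <- NA_real_
    }
  }
  tab$ph_status <- ph_status(tab$mPAP)
  tab
}
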