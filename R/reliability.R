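#' Simulated rater-reliability protocol
#'
#' Emulates the reliability assessment used for manual 3D measurements:
#' a subsample of patients is re-measured by simulated raters, each
#' rater being an independent measurement pass with (a) jitter on the
#' margin-window fraction and (b) smooth landmark noise added to the
#' profile heights. Inter-observer ICC(A,1) compares rater 1's first
#' pass against rater 2; intra-observer ICC compares rater 1's two
#' passes. ICCs are reported per parameter: SCD and SD (sagittal depth
#' and diameter), CCD and CD (coronal).
#'
#' @param cohort a cohort tibble with a `mesh` list-column (see
#'   [generate_cohort()]).
#' @param n_patients_sampled patients to subsample (default 10, i.e. 50
#'   endplates).
#' @param jitter_margin half-width of the uniform jitter applied to the
#'   0.15 margin fraction per endplate and pass.
#' @param landmark_sd sd (mm) of the smooth landmark noise per pass.
#' @param seed integer seed.
#' @return A tibble with columns `parameter`, `plane`, `metric`,
#'   `icc_inter`, `icc_intra`; the per-pass measurements are in the
#'   `ratings` attribute.
#' @export
reliability_protocol <- function(cohort, n_patients_sampled = 10,
                                 jitter_margin = 0.02, landmark_sd = 0.02,
                                 seed = 1L) {
  patients <- unique(cohort$patient)
  if (length(patients) < n_patients_sampled) {
    stopf("cohort has %d patients but %d were requested",
          length(patients), n_patients_sampled, class = "epmorph_parameter_error")
  }
  chosen <- with_seed(derive_seed(seed, 0L, 99L),
                      sample(patients, n_patients_sampled))
  sub <- cohort[cohort$patient %in% chosen, ]

  measure_pass <- function(pass_id) {
    rows <- vector("list", nrow(sub) * 2L)
    z <- 0L
    for (i in seq_len(nrow(sub))) {
      for (pl in c("sagittal", "coronal")) {
        prof <- extract_profile(sub$mesh[[i]], pl)
        pseed <- derive_seed(seed + 7919L * pass_id, i, match(pl, c("sagittal", "coronal")))
        meas <- with_seed(pseed, {
          mf <- 0.15 + if (jitter_margin > 0) runif(1, -jitter_margin, jitter_margin) else 0
          h <- prof$h
          if (landmark_sd > 0) {
            h <- h + smooth_noise_1d(prof$s, diff(range(prof$s)), landmark_sd)
          }
          measure_profile(new_profile(prof$s, h, pl), margin_fraction = mf)
        })
        z <- z + 1L
        rows[[z]] <- tibble(patient = sub$patient[i], segment = sub$segment[i],
                            plane = pl, pass = pass_id,
                            depth = meas$concavity_depth, chord = meas$chord_length)
      }
    }
    dplyr::bind_rows(rows)
  }

  passes <- dplyr::bind_rows(lapply(1:3, measure_pass))  # 1,2: rater 1; 3: rater 2

  params <- tibble(parameter = c("SCD", "SD", "CCD", "CD"),
                   plane = c("sagittal", "sagittal", "coronal", "coronal"),
                   metric = c("depth", "chord", "depth", "chord"))
  out <- purrr::pmap_dfr(params, function(parameter, plane, metric) {
    wide <- tidyr::pivot_wider(
      passes[passes$plane == plane, c("patient", "segment", "pass", metric)],
      names_from = "pass", values_from = dplyr::all_of(metric), names_prefix = "pass")
    tibble(parameter = parameter, plane = plane, metric = metric,
           icc_inter = icc_absolute_agreement(cbind(wide$pass1, wide$pass3))$icc,
           icc_intra = icc_absolute_agreement(cbind(wide$pass1, wide$pass2))$icc)
  })
  attr(out, "ratings") <- passes
  out
}
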