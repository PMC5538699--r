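#' Compare circular, averaged and individualized reconstruction models
#'
#' Trains one reconstruction model per geometry kind (shared circular and
#' averaged models; one individualized model per subject), runs the tidal
#' ventilation pipeline on every subject recording, and scores each variant's
#' anteroposterior profile against the subject's ground-truth profile by
#' RMSE. The five profile variants follow the established naming: `vd1`
#' (circular), `vd2` (averaged), `vd3` (individual) with the 10%-of-maximum
#' threshold, and `vd2p`/`vd3p` where the threshold is replaced by the
#' subject's anatomical lung mask (carried into the averaged frame by
#' centroid/area alignment for `vd2p`).
#'
#' @param ch a [cohort()]
#' @param cfg reconstruction configuration (defaults to GREIT at the
#'   recommended settings: nf 0.15, ts 0.06, rw 0.15, weighted, TD)
#' @param target_elements reconstruction mesh size
#' @param nominal_period breath period (s) passed to phase detection
#' @return a `model_evaluation` list: `rmse` (tibble subject x variant),
#'   `profiles` (long tibble incl. the reference `CT` rows), `tidal`
#'   (per-subject list of tidal images), `models`
#' @export
evaluate_geometry_models <- function(ch, cfg = greit_config(),
                                     target_elements = 20000L,
                                     nominal_period = 10) {
  stopifnot(inherits(ch, "eit_cohort"))
  cfg1 <- cfg; cfg1$background <- "uniform"  # the circular model has no organs
  rm1 <- train_model(ch$circular, cfg1, target_elements)
  rm2 <- train_model(ch$averaged, cfg, target_elements)

  rows <- list(); profs <- list(); tidals <- list()
  for (i in seq_along(ch$subjects)) {
    sub <- ch$subjects[[i]]
    rm3 <- train_model(sub$geometry, cfg, target_elements)

    p1 <- ventilation_pipeline(sub$recording, rm1, nominal_period = nominal_period)
    p2 <- ventilation_pipeline(sub$recording, rm2, nominal_period = nominal_period)
    p3 <- ventilation_pipeline(sub$recording, rm3, nominal_period = nominal_period)

    # subject lung contours in the averaged frame (anatomical mask for vd2p)
    lungs_in_m2 <- align_contours(sub$geometry$lungs, sub$geometry, ch$averaged)
    g2masked <- thorax_geometry(ch$averaged$thorax, lungs = lungs_in_m2,
                                kind = "averaged")
    grid2ct <- rasterize(g2masked)

    variants <- list(
      vd1  = ap_profile(threshold_mask(p1$tidal), p1$tidal$grid$body_mask),
      vd2  = ap_profile(threshold_mask(p2$tidal), p2$tidal$grid$body_mask),
      vd3  = ap_profile(threshold_mask(p3$tidal), p3$tidal$grid$body_mask),
      vd2p = ap_profile(lung_select(p2$tidal, grid2ct), grid2ct$lung_mask),
      vd3p = ap_profile(lung_select(p3$tidal), p3$tidal$grid$lung_mask)
    )
    vd_ct <- sub$truth$vd_truth

    for (v in names(variants)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = i, variant = v,
        rmse = profile_rmse(variants[[v]], vd_ct))
      profs[[length(profs) + 1L]] <- tibble::tibble(
        subject = i, variant = v, band = variants[[v]]$band,
        vd = variants[[v]]$vd)
    }
    profs[[length(profs) + 1L]] <- tibble::tibble(
      subject = i, variant = "CT", band = vd_ct$band, vd = vd_ct$vd)
    tidals[[i]] <- list(vd1 = p1$tidal, vd2 = p2$tidal, vd3 = p3$tidal)
  }
  structure(list(
    rmse = dplyr::bind_rows(rows),
    profiles = dplyr::bind_rows(profs),
    tidal = tidals,
    models = list(circular = rm1, averaged = rm2),
    config = cfg
  ), class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("<model_evaluation>\n")
  sm <- dplyr::summarise(dplyr::group_by(x$rmse, .data$variant),
                         mean = mean(.data$rmse), sd = stats::sd(.data$rmse),
                         .groups = "drop")
  print(sm)
  invisible(x)
}

#' @rdname evaluate_geometry_models
#' @param x a `model_evaluation`
#' @param ... unused
#' @export
tidy.model_evaluation <- function(x, ...) x$rmse

#' @rdname evaluate_geometry_models
#' @export
glance.model_evaluation <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$rmse, .data$variant),
                   mean_rmse = mean(.data$rmse), sd_rmse = stats::sd(.data$rmse),
                   .groups = "drop")
}

#' Pool profile pairs for correlation / agreement analyses
#'
#' Joins the EIT profile bands of one variant with the reference (`CT`) bands
#' of the same subjects into the `(ref, eit)` pair table consumed by
#' [pooled_pearson()] and [bland_altman()].
#'
#' @param ev a `model_evaluation`
#' @param variant which EIT variant to pair against the reference
#' @return tibble with columns `subject`, `band`, `ref`, `eit`
#' @export
profile_pairs <- function(ev, variant = "vd3p") {
  ct <- dplyr::filter(ev$profiles, .data$variant == "CT")
  vv <- dplyr::filter(ev$profiles, .data$variant == !!variant)
  dplyr::transmute(
    dplyr::inner_join(ct, vv, by = c("subject", "band"),
                      suffix = c("_ref", "_eit")),
    subject = .data$subject, band = .data$band,
    ref = .data$vd_ref, eit = .data$vd_eit)
}
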