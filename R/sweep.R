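#' Default reduced sweep grid of reconstruction settings
#'
#' GREIT and one-step Gauss-Newton (Laplace prior), each over noise figures
#' `nf`, both voltage referencing methods and both backgrounds; GREIT keeps
#' the recommended target size and weighting radius fixed.
#'
#' @param nf noise figures to scan
#' @param ts,rw GREIT target size and weighting radius
#' @return list of `recon_config` objects
#' @export
sweep_settings <- function(nf = c(0.15, 0.3, 0.5), ts = 0.06, rw = 0.15) {
  grid <- expand.grid(nf = nf, reference = c("TD", "NTD"),
                      background = c("uniform", "weighted"),
                      algorithm = c("GREIT", "GN"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    if (r$algorithm == "GREIT") {
      greit_config(nf = r$nf, ts = ts, rw = rw, background = r$background,
                   reference = r$reference)
    } else {
      gn_config(nf = r$nf, prior = "Laplace", background = r$background,
                reference = r$reference)
    }
  })
}

#' Sweep reconstruction settings over a cohort
#'
#' For every (setting, subject) pair: train the individualized reconstruction
#' model, calibrate its regularization to the setting's noise figure, run the
#' tidal-image pipeline on the subject's recording and score the 2D Pearson
#' correlation against the subject's ground-truth tidal aeration image.
#' Settings are then ranked per subject by correlation (dense ranks, ties
#' averaged) and overall by mean rank. Failures in any stage are recorded on
#' the affected row and the sweep continues.
#'
#' Jacobians, training-target sets and channel-space eigendecompositions are
#' shared across settings that differ only in the noise figure, so the grid
#' cost is dominated by the per-subject forward models.
#'
#' @param ch a [cohort()] (the individualized geometries are used)
#' @param settings list of `recon_config`s, e.g. [sweep_settings()]
#' @param target_elements reconstruction mesh size
#' @param nominal_period breath period (s)
#' @return a `sweep_result`: list with `results` (one row per setting x
#'   subject) and `ranking` (settings ordered by mean rank)
#' @export
run_sweep <- function(ch, settings = sweep_settings(),
                      target_elements = 6000L, nominal_period = 10) {
  stopifnot(inherits(ch, "eit_cohort"), length(settings) >= 1L)
  scheme <- skip4_scheme()
  rows <- list()
  for (i in seq_along(ch$subjects)) {
    sub <- ch$subjects[[i]]
    mesh <- build_mesh(sub$geometry, target_elements = target_elements)
    grid <- rasterize(sub$geometry)
    jcache <- list(); trcache <- list()
    for (s in seq_along(settings)) {
      cfg <- settings[[s]]
      key_j <- cfg$background
      if (is.null(jcache[[key_j]])) {
        sigma <- weighted_background(mesh, cfg$background)
        jcache[[key_j]] <- jacobian_2d(eit_jacobian(mesh, sigma, scheme), mesh)
      }
      res <- tryCatch({
        key_t <- paste(cfg$algorithm, cfg$background, cfg$reference,
                       cfg$ts %||% "", cfg$rw %||% "", cfg$prior %||% "")
        if (is.null(trcache[[key_t]])) {
          J2 <- jcache[[key_j]]
          if (cfg$reference == "NTD") {
            v0 <- attr(J2, "v0")[attr(J2, "valid")]
            J2n <- J2 / v0
            attr(J2n, "valid") <- attr(J2, "valid")
            attr(J2n, "v0") <- attr(J2, "v0")
            J2 <- J2n
          }
          trcache[[key_t]] <- if (inherits(cfg, "greit_config")) {
            greit_trainer(make_training_targets(mesh, J2, grid, cfg))
          } else {
            gn_trainer(mesh, J2, grid, cfg)
          }
        }
        tr <- trcache[[key_t]]
        cal <- calibrate_nf(tr$nf_at, cfg$nf)
        rm <- tr$matrix_at(cal$lambda, achieved_nf = cal$nf)
        rm$mesh <- mesh
        pl <- ventilation_pipeline(sub$recording, rm,
                                   method = cfg$reference,
                                   nominal_period = nominal_period)
        r2d <- image_correlation_2d(pl$tidal, sub$truth$tidal)
        list(correlation = r2d, nf = cal$nf, lambda = cal$lambda, error = NA_character_)
      }, error = function(e) {
        list(correlation = NA_real_, nf = NA_real_, lambda = NA_real_,
             error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        setting = s, subject = i,
        algorithm = cfg$algorithm, nf = cfg$nf,
        background = cfg$background, reference = cfg$reference,
        ts = cfg$ts %||% NA_real_, rw = cfg$rw %||% NA_real_,
        prior = cfg$prior %||% NA_character_,
        correlation = res$correlation, achieved_nf = res$nf,
        lambda = res$lambda, error = res$error)
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(list(results = results, ranking = rank_settings(results),
                 settings = settings), class = "sweep_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank sweep settings by per-subject correlation
#'
#' Ranks settings within each subject by decreasing correlation (average rank
#' on ties, failed rows ranked last) and orders settings by the mean rank
#' across subjects.
#'
#' @param results a sweep `results` tibble (needs `setting`, `subject`,
#'   `correlation` plus setting descriptors)
#' @return ranking tibble, best setting first
#' @export
rank_settings <- function(results) {
  ranked <- dplyr::mutate(
    dplyr::group_by(results, .data$subject),
    rank = rank(-.data$correlation, ties.method = "average", na.last = "keep"))
  ranked <- dplyr::mutate(ranked,
    rank = ifelse(is.na(.data$rank), dplyr::n(), .data$rank))
  ranked <- dplyr::ungroup(ranked)
  out <- dplyr::summarise(
    dplyr::group_by(ranked, .data$setting, .data$algorithm, .data$nf,
                    .data$background, .data$reference, .data$ts, .data$rw,
                    .data$prior),
    mean_rank = mean(.data$rank),
    mean_correlation = mean(.data$correlation),
    n_failed = sum(!is.na(.data$error)),
    .groups = "drop")
  dplyr::arrange(out, .data$mean_rank)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d settings x %d subjects\n",
              length(unique(x$results$setting)),
              length(unique(x$results$subject))))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}

#' @rdname run_sweep
#' @param x a `sweep_result`
#' @param ... unused
#' @export
tidy.sweep_result <- function(x, ...) x$results

#' @rdname run_sweep
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(n_settings = length(unique(x$results$setting)),
                 n_subjects = length(unique(x$results$subject)),
                 n_failed = sum(!is.na(x$results$error)),
                 best_setting = x$ranking$setting[1L],
                 best_mean_rank = x$ranking$mean_rank[1L])
}
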